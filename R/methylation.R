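# Per-window CpG methylation from bisulfite counts.
#
# Windows (default 50 bp) aggregate CpG-level fractions by the unweighted
# site mean: each qualifying CpG contributes one methylation level, not one
# read. Windows without qualifying CpGs are missing (NA), never zero. A
# read-weighted alternative (total methylated / total reads) is available for
# sensitivity analysis.

#' Per-window CpG methylation fractions
#'
#' @param cpg data.frame with chrom, pos (1-based), methylated, total (and
#'   optionally sample_id; records from all samples are pooled -- call per
#'   sample for per-sample tracks).
#' @param region_chrom,region_start,region_end region in 0-based half-open
#'   coordinates; length must be divisible by `window_size`.
#' @param window_size window width (default 50).
#' @param min_coverage minimum total reads for a CpG to qualify (default 1).
#' @param weighted if TRUE use read-weighted aggregation (sum methylated /
#'   sum total) instead of the site mean.
#' @return numeric vector (one value per window, NA where no CpG qualifies).
#' @export
window_methylation <- function(cpg, region_chrom, region_start, region_end,
                               window_size = 50L, min_coverage = 1L,
                               weighted = FALSE) {
  len <- region_end - region_start
  .assert(len > 0 && len %% window_size == 0L,
          "region length must be divisible by window_size")
  .assert(all(cpg$total >= 1), "CpG with zero total reads")
  .assert(all(cpg$methylated <= cpg$total), "methylated exceeds total")
  nw <- len %/% window_size
  # 1-based CpG position p maps to 0-based coordinate p-1
  coord <- cpg$pos - 1L
  keep <- cpg$chrom == region_chrom & coord >= region_start & coord < region_end &
    cpg$total >= min_coverage
  s <- cpg[keep, , drop = FALSE]
  out <- rep(NA_real_, nw)
  if (nrow(s) == 0L) return(out)
  w <- (s$pos - 1L - region_start) %/% window_size + 1L
  if (weighted) {
    meth <- tapply(s$methylated, w, sum)
    tot <- tapply(s$total, w, sum)
    out[as.integer(names(meth))] <- meth / tot
  } else {
    frac <- tapply(s$methylated / s$total, w, mean)
    out[as.integer(names(frac))] <- frac
  }
  out
}

#' Stage trend of methylation summaries
#'
#' Identical contract to [stage_trend()]: OLS of a per-sample methylation
#' summary (e.g. region mean of window fractions) on the integer stage index.
#'
#' @inheritParams stage_trend
#' @return a `trend_result` (see [stage_trend()]).
#' @export
methylation_trend <- function(values, stage, conf = 0.95) {
  stage_trend(values, stage, conf = conf)
}

#' Correlation between accessibility and methylation
#'
#' Pearson correlation between mean TPM and mean methylation per cell
#' subtype/group cell; same contract as [region_correlation()].
#'
#' @param tpm,methylation paired per-cell means.
#' @return list: r, p_value, n, ci.
#' @export
meth_access_correlation <- function(tpm, methylation) {
  region_correlation(methylation, tpm)
}
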