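# Window-based quantification of region activity.
#
# A region is tiled left-to-right into fixed-width windows (default 50 bp).
# The tag count in each window is scaled to tags-per-million (TPM):
# TPM = count * 1e6 / library_size. Summaries (ECDF, Q3), developmental-stage
# trend regressions, length-matched background sampling, and Pearson
# region-region correlation follow.

#' Count tags in fixed-width windows
#'
#' Windows tile `[region_start, region_end)`; a tag belongs to the half-open
#' window containing its position (positions are interpreted as the tag
#' 5' end, same coordinate system as the region).
#'
#' @param positions tag positions.
#' @param region_start,region_end region bounds; length must be divisible by
#'   `window_size`.
#' @param window_size window width in bp (default 50).
#' @return integer vector of per-window counts.
#' @export
window_counts <- function(positions, region_start, region_end, window_size = 50L) {
  len <- region_end - region_start
  .assert(len > 0 && len %% window_size == 0L,
          "region length must be positive and divisible by window_size")
  nw <- len %/% window_size
  inside <- positions >= region_start & positions < region_end
  idx <- (positions[inside] - region_start) %/% window_size + 1L
  tabulate(idx, nbins = nw)
}

#' Tags-per-million scaling of window counts
#'
#' @param counts per-window tag counts (or a matrix, windows x samples).
#' @param library_size total tags per sample (scalar, or vector matching the
#'   matrix columns).
#' @return TPM values with the same shape as `counts`.
#' @export
window_tpm <- function(counts, library_size) {
  .assert(all(library_size > 0), "zero or negative library size")
  if (is.matrix(counts)) {
    .assert(length(library_size) %in% c(1L, ncol(counts)),
            "library_size must be scalar or per-column")
    sweep(counts, 2, library_size, function(c, l) c * 1e6 / l)
  } else {
    .assert(length(library_size) == 1L, "library_size must be scalar for a vector")
    counts * 1e6 / library_size
  }
}

#' ECDF and quartile summary
#'
#' Right-continuous empirical CDF plus quartiles by linear interpolation
#' between order statistics (R's default type-7 quantile).
#'
#' @param values numeric vector (length >= 1, no NAs).
#' @return list: `ecdf` (a function), `quartiles` (named Q1/median/Q3), `q3`.
#' @export
ecdf_summary <- function(values) {
  .assert(length(values) >= 1 && !anyNA(values), "need >= 1 non-missing value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(ecdf = stats::ecdf(values),
       quartiles = c(q1 = q[1], median = q[2], q3 = q[3]),
       q3 = q[3])
}

#' Stage trend: regression of a summary on developmental stage
#'
#' OLS of per-sample summary values on the integer stage index (e.g. rN=0,
#' T3=1, SM=2, DN=3), typically run separately within the case and control
#' groups. Exactly constant values give slope 0 and p = 1.
#'
#' @param values per-sample summary values (e.g. region Q3 TPM).
#' @param stage integer stage indices matching `values`.
#' @param conf confidence level for the slope interval (default 0.95).
#' @return list of class `trend_result`: slope, se, ci (length 2), p_value,
#'   n, intercept.
#' @export
stage_trend <- function(values, stage, conf = 0.95) {
  .assert(length(values) == length(stage) && length(values) >= 2,
          "need matched values and stages (n >= 2)")
  .assert(length(unique(stage)) >= 2, "need >= 2 distinct stages")
  if (stats::sd(values) == 0) {
    # exactly constant input: slope 0 by convention, no evidence of trend
    return(structure(list(slope = 0, se = 0, ci = c(0, 0), p_value = 1,
                          n = length(values), intercept = values[1]),
                     class = "trend_result"))
  }
  fit <- stats::lm(values ~ stage)
  # summary.lm warns on residual-free fits; the se == 0 branch handles them
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co["stage", "Estimate"]
  se <- co["stage", "Std. Error"]
  df <- fit$df.residual
  if (!is.finite(se) || se == 0) {
    p <- if (abs(slope) < 1e-12) 1 else .Machine$double.xmin
    ci <- c(slope, slope)
  } else {
    p <- co["stage", "Pr(>|t|)"]
    ci <- slope + c(-1, 1) * stats::qt(1 - (1 - conf) / 2, df) * se
  }
  structure(list(slope = unname(slope), se = unname(se), ci = ci,
                 p_value = unname(p), n = length(values),
                 intercept = unname(co["(Intercept)", "Estimate"])),
            class = "trend_result")
}

#' Length-matched background sampling
#'
#' Draws `n_draws` regions of the query's length uniformly from the same
#' chromosome, excluding the query itself and any further exclusion
#' intervals, summarizes each draw with `summary_fun` applied to its window
#' TPM vector, and reports the add-one empirical p-value
#' `(1 + #\{draws >= observed\}) / (n_draws + 1)`.
#'
#' @param positions genome-wide tag positions on the chromosome.
#' @param chrom_length chromosome length in bp.
#' @param region_start,region_end the query region.
#' @param library_size tags per million scaling denominator.
#' @param n_draws number of background draws (default 1000).
#' @param seed RNG seed for the draws.
#' @param exclude optional data.frame (start, end) of extra intervals the
#'   draws must avoid (the query region is always avoided).
#' @param window_size window width (default 50).
#' @param summary_fun summary of a TPM vector (default Q3).
#' @return list: observed, background (vector of draw summaries), p_value,
#'   draws (data.frame start/end).
#' @export
background_sample <- function(positions, chrom_length, region_start, region_end,
                              library_size, n_draws = 1000L, seed = 1L,
                              exclude = NULL, window_size = 50L,
                              summary_fun = function(x) stats::quantile(x, 0.75, names = FALSE)) {
  len <- region_end - region_start
  .assert(len > 0 && len %% window_size == 0L, "bad query region")
  avoid <- data.frame(start = region_start, end = region_end)
  if (!is.null(exclude)) avoid <- rbind(avoid, exclude[, c("start", "end")])
  ok_start <- function(s) {
    all(pmin(s + len, avoid$end) <= pmax(s, avoid$start)) && s + len <= chrom_length
  }
  observed <- summary_fun(window_tpm(
    window_counts(positions, region_start, region_end, window_size), library_size))
  with_seed(seed, {
    starts <- integer(n_draws)
    for (i in seq_len(n_draws)) {
      for (tries in 1:10000) {
        s <- as.integer(floor(stats::runif(1, 0, chrom_length - len)))
        if (ok_start(s)) break
        if (tries == 10000) stop("infeasible exclusions: cannot place background draw")
      }
      starts[i] <- s
    }
    bg <- vapply(starts, function(s) {
      summary_fun(window_tpm(window_counts(positions, s, s + len, window_size),
                             library_size))
    }, numeric(1))
    list(observed = observed, background = bg,
         p_value = (1 + sum(bg >= observed)) / (n_draws + 1),
         draws = data.frame(start = starts, end = starts + len))
  })
}

#' Pearson correlation between two region summaries
#'
#' @param x,y paired mean values (e.g. per cell-subtype mean TPM of two
#'   regions); length >= 3, both with nonzero variance.
#' @return list: r, p_value, n, ci (95% interval from the z-transform when
#'   n >= 4).
#' @export
region_correlation <- function(x, y) {
  .assert(length(x) == length(y) && length(x) >= 3, "need >= 3 paired points")
  .assert(stats::sd(x) > 0 && stats::sd(y) > 0, "constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       ci = if (length(x) >= 4) as.numeric(ct$conf.int) else c(NA_real_, NA_real_))
}
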