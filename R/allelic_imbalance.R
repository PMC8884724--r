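# Allelic-imbalance testing.
#
# The allelic ratio (AR) at a heterozygous SNP is the fraction of reads
# supporting the alt allele. Case/control AI is tested per SNP by ordinary
# least squares of AR on the 0/1 disease code; with a single binary regressor
# the slope is the difference of group means and its t-test is algebraically
# the equal-variance two-sample t-test. Per-dataset p-values are combined with
# Fisher's method and a SNP is validated reciprocally: nominal p < 0.05 in
# every dataset and combined p < 0.01, within a matched cell-state stratum.

#' Allelic ratio
#'
#' `alt / (ref + alt)`, the fraction of reads covering the alt allele. The
#' orientation is fixed to the record's alt allele across samples and
#' datasets, so betas are sign-consistent.
#'
#' @param ref_depth,alt_depth non-negative read counts (vectorised).
#' @return numeric vector in \[0,1\].
#' @export
allelic_ratio <- function(ref_depth, alt_depth) {
  .assert(all(ref_depth >= 0) && all(alt_depth >= 0), "depths must be non-negative")
  tot <- ref_depth + alt_depth
  .assert(all(tot > 0), "zero total depth")
  alt_depth / tot
}

#' Test allelic imbalance between cases and controls
#'
#' OLS of AR on the group code (control = 0, case = 1). The slope equals
#' `mean(AR case) - mean(AR control)`; its two-sided t-test p-value (df =
#' n - 2, pooled variance) is returned together with group means and a 95%
#' confidence interval for the slope. If the residual variance is exactly zero
#' and the slope is zero the test is degenerate and p = 1.
#'
#' @param ar allelic ratios.
#' @param group 0/1 vector matching `ar`.
#' @param min_per_group minimum samples required in each group (default 2;
#'   the recurrence filter upstream guarantees 3).
#' @return list of class `ai_test`: beta, p_value, n_case, n_control,
#'   mean_ar_case, mean_ar_control, se, ci95 (length-2).
#' @export
ai_test <- function(ar, group, min_per_group = 2L) {
  .assert(length(ar) == length(group), "ar and group lengths differ")
  .assert(all(group %in% c(0L, 1L)), "group must be coded 0/1")
  n0 <- sum(group == 0L); n1 <- sum(group == 1L)
  .assert(n0 >= min_per_group && n1 >= min_per_group,
          "need at least min_per_group samples in each group")
  m0 <- mean(ar[group == 0L]); m1 <- mean(ar[group == 1L])
  beta <- m1 - m0
  df <- n0 + n1 - 2L
  ss <- sum((ar[group == 0L] - m0)^2) + sum((ar[group == 1L] - m1)^2)
  s2 <- ss / df
  se <- sqrt(s2 * (1 / n0 + 1 / n1))
  if (se == 0) {
    p <- if (beta == 0) 1 else .Machine$double.xmin  # all-identical degenerate case
    ci <- c(beta, beta)
  } else {
    t <- beta / se
    p <- 2 * stats::pt(-abs(t), df)
    ci <- beta + c(-1, 1) * stats::qt(0.975, df) * se
  }
  structure(list(beta = beta, p_value = max(p, .Machine$double.xmin),
                 n_case = n1, n_control = n0,
                 mean_ar_case = m1, mean_ar_control = m0,
                 se = se, ci95 = ci),
            class = "ai_test")
}

#' Combine p-values with Fisher's method
#'
#' `X2 = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom. A single p-value is returned unchanged.
#'
#' @param p_values vector of p-values in (0, 1\].
#' @return combined p-value.
#' @export
fisher_combine <- function(p_values) {
  .assert(length(p_values) >= 1, "no p-values to combine")
  .assert(all(p_values > 0 & p_values <= 1), "p-values must lie in (0,1]")
  if (length(p_values) == 1L) return(p_values)
  x2 <- -2 * sum(log(p_values))
  stats::pchisq(x2, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Run AI tests for every testable SNP
#'
#' Applies [ai_test()] per (SNP, dataset, cell state) stratum of a testable
#' het-call table (output of [recurrence_filter()]).
#'
#' @param calls het calls with snp_id, dataset_id, cell_state, group,
#'   ref_depth, alt_depth columns.
#' @return data.frame: snp_id, dataset_id, cell_state, n_case, n_control,
#'   beta, se, ci_lo, ci_hi, mean_ar_case, mean_ar_control, p_value.
#' @export
ai_test_all <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(snp_id = character(0), dataset_id = character(0),
                      cell_state = character(0), n_case = integer(0),
                      n_control = integer(0), beta = numeric(0), se = numeric(0),
                      ci_lo = numeric(0), ci_hi = numeric(0),
                      mean_ar_case = numeric(0), mean_ar_control = numeric(0),
                      p_value = numeric(0)))
  }
  calls$ar <- allelic_ratio(calls$ref_depth, calls$alt_depth)
  key <- paste(calls$snp_id, calls$dataset_id, calls$cell_state, sep = "\r")
  res <- lapply(split(calls, key), function(d) {
    t <- ai_test(d$ar, d$group, min_per_group = 2L)
    data.frame(snp_id = d$snp_id[1], dataset_id = d$dataset_id[1],
               cell_state = d$cell_state[1],
               n_case = t$n_case, n_control = t$n_control,
               beta = t$beta, se = t$se, ci_lo = t$ci95[1], ci_hi = t$ci95[2],
               mean_ar_case = t$mean_ar_case, mean_ar_control = t$mean_ar_control,
               p_value = t$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reciprocal validation across datasets
#'
#' A SNP passes iff (within a matched cell-state stratum) it was testable in
#' all datasets, every per-dataset p-value is below `alpha_nominal`, and the
#' Fisher-combined p-value is below `alpha_combined`. Benjamini-Hochberg FDR
#' on the combined p-values is reported alongside but never used for gating.
#'
#' @param results data.frame from [ai_test_all()] spanning >= 2 datasets.
#' @param alpha_nominal per-dataset nominal threshold (default 0.05).
#' @param alpha_combined combined threshold (default 0.01).
#' @return data.frame: snp_id, cell_state, n_datasets, per-dataset p summary,
#'   p_combined, fdr, pass.
#' @export
reciprocal_validate <- function(results, alpha_nominal = 0.05, alpha_combined = 0.01) {
  .assert(nrow(results) > 0, "empty result set")
  n_ds <- length(unique(results$dataset_id))
  .assert(n_ds >= 2, "reciprocal validation needs >= 2 datasets")
  key <- paste(results$snp_id, results$cell_state, sep = "\r")
  rows <- lapply(split(results, key), function(d) {
    testable <- length(unique(d$dataset_id)) == n_ds
    p_comb <- if (testable) fisher_combine(d$p_value) else NA_real_
    data.frame(snp_id = d$snp_id[1], cell_state = d$cell_state[1],
               n_datasets = length(unique(d$dataset_id)),
               max_p_dataset = max(d$p_value),
               p_combined = p_comb,
               pass = testable && all(d$p_value < alpha_nominal) &&
                 !is.na(p_comb) && p_comb < alpha_combined,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- NA_real_
  has_p <- !is.na(out$p_combined)
  out$fdr[has_p] <- stats::p.adjust(out$p_combined[has_p], method = "BH")
  out[order(out$p_combined), ]
}

#' Compare RNA-level allelic ratios between groups
#'
#' The same linear model as [ai_test()], applied to RNA-derived ARs and
#' reported per cell state, for checking whether chromatin-level AI replicates
#' at the transcript level.
#'
#' @param ar allelic ratios from RNA data.
#' @param group 0/1 group codes.
#' @param cell_state optional per-sample states; one test per state.
#' @return a data.frame with one row per cell state (columns as
#'   [ai_test_all()] minus dataset).
#' @export
rna_ai_compare <- function(ar, group, cell_state = NULL) {
  if (is.null(cell_state)) cell_state <- rep("all", length(ar))
  .assert(length(ar) == length(group) && length(ar) == length(cell_state),
          "input lengths differ")
  res <- lapply(split(seq_along(ar), cell_state), function(i) {
    t <- ai_test(ar[i], group[i], min_per_group = 2L)
    data.frame(cell_state = cell_state[i][1], n_case = t$n_case,
               n_control = t$n_control, beta = t$beta,
               mean_ar_case = t$mean_ar_case, mean_ar_control = t$mean_ar_control,
               ci_lo = t$ci95[1], ci_hi = t$ci95[2], p_value = t$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
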