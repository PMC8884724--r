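# Genetic association: single-marker log-additive logistic models with
# covariates, conditional adjustment for index SNPs, two-SNP EM haplotype
# estimation and association, and LD r2.
#
# Dosages count copies of the effect allele (0/1/2); the per-allele odds
# ratio is exp(beta) from the logistic fit, with Wald 95% intervals.
# Individuals with missing data at any model variable are dropped
# (complete-case).

.complete_cases <- function(...) {
  m <- do.call(cbind, lapply(list(...), function(x) {
    if (is.null(x)) return(NULL)
    as.matrix(x)
  }))
  stats::complete.cases(m)
}

.check_separation <- function(fit) {
  p <- fit$fitted.values
  if (!fit$converged || any(p < 1e-10) || any(p > 1 - 1e-10)) {
    stop("complete or quasi-complete separation detected in logistic fit",
         call. = FALSE)
  }
}

#' Single-marker log-additive logistic association
#'
#' Maximum-likelihood logistic regression of case status on effect-allele
#' dosage plus covariates. Returns the per-allele odds ratio, Wald 95% CI and
#' p-value. Complete or quasi-complete separation raises an error rather than
#' returning a silently diverged estimate.
#'
#' @param dosage 0/1/2 effect-allele counts (NA = missing, dropped).
#' @param phenotype 0/1 case status.
#' @param covariates optional data.frame or matrix of covariates.
#' @param snp_id label recorded in the result.
#' @param adjusted_for character vector recorded in the result (used by
#'   [conditional_adjust()]).
#' @return list of class `assoc_result`: snp_id, beta, se, or, ci95 (on the OR
#'   scale), p_value, n, adjusted_for.
#' @export
additive_logistic <- function(dosage, phenotype, covariates = NULL,
                              snp_id = "snp", adjusted_for = character(0)) {
  .assert(length(dosage) == length(phenotype), "dosage and phenotype lengths differ")
  .assert(all(stats::na.omit(phenotype) %in% c(0L, 1L)), "phenotype must be 0/1")
  .assert(all(stats::na.omit(dosage) %in% 0:2), "dosage must be 0, 1 or 2")
  cc <- .complete_cases(dosage, phenotype, covariates)
  dosage <- dosage[cc]; phenotype <- phenotype[cc]
  if (!is.null(covariates)) covariates <- as.data.frame(covariates)[cc, , drop = FALSE]
  .assert(sum(phenotype == 1L) >= 1 && sum(phenotype == 0L) >= 1,
          "need at least one case and one control")
  .assert(stats::var(dosage) > 0, "zero dosage variance")
  dat <- data.frame(.y = phenotype, .d = dosage)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  # glm's 0/1-fitted-probability warning is superseded by the explicit
  # separation check below
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  .check_separation(fit)
  co <- summary(fit)$coefficients
  beta <- co[".d", "Estimate"]; se <- co[".d", "Std. Error"]
  structure(list(snp_id = snp_id, beta = unname(beta), se = unname(se),
                 or = exp(unname(beta)),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p_value = unname(co[".d", "Pr(>|z|)"]),
                 n = length(phenotype), adjusted_for = adjusted_for),
            class = "assoc_result")
}

#' Conditional association adjusted for index SNPs
#'
#' Refits [additive_logistic()] with the dosages of the index SNPs appended
#' to the covariates. Near-collinearity between the test SNP and any index
#' SNP (r2 > `collinearity_r2`) raises an error.
#'
#' @inheritParams additive_logistic
#' @param index_dosages matrix or data.frame of index-SNP dosages (columns
#'   named by SNP).
#' @param collinearity_r2 tolerance above which the test SNP is declared
#'   collinear with an index SNP (default 0.99).
#' @return an `assoc_result` with `adjusted_for` set to the index SNP names.
#' @export
conditional_adjust <- function(dosage, phenotype, covariates = NULL,
                               index_dosages, snp_id = "snp",
                               collinearity_r2 = 0.99) {
  idx <- as.data.frame(index_dosages)
  if (is.null(names(idx)) || any(!nzchar(names(idx))))
    names(idx) <- paste0("index", seq_along(idx))
  for (j in seq_along(idx)) {
    cc <- stats::complete.cases(dosage, idx[[j]])
    if (stats::var(idx[[j]][cc]) > 0 && stats::var(dosage[cc]) > 0) {
      r2 <- stats::cor(dosage[cc], idx[[j]][cc])^2
      .assert(r2 <= collinearity_r2,
              sprintf("test SNP collinear with index SNP '%s' (r2 = %.3f)",
                      names(idx)[j], r2))
    }
  }
  cov2 <- if (is.null(covariates)) idx else cbind(as.data.frame(covariates), idx)
  additive_logistic(dosage, phenotype, covariates = cov2, snp_id = snp_id,
                    adjusted_for = names(idx))
}

# haplotype order used throughout: "11", "10", "01", "00" where the first
# digit is the allele (1 = effect/alt) at SNP1 and the second at SNP2
HAP_LABELS <- c("11", "10", "01", "00")

# expected haplotype-count contribution of each unambiguous genotype combo
.hap_pairs <- list(
  "2_2" = c("11", "11"), "2_1" = c("11", "10"), "2_0" = c("10", "10"),
  "1_2" = c("11", "01"), "1_0" = c("10", "00"),
  "0_2" = c("01", "01"), "0_1" = c("01", "00"), "0_0" = c("00", "00"))

#' Two-SNP haplotype frequencies by EM
#'
#' Estimates the four haplotype frequencies from unphased 0/1/2 dosages at
#' two biallelic SNPs. Only double heterozygotes are phase-ambiguous: they
#' carry haplotypes (11,00) with posterior `p11*p00 / (p11*p00 + p10*p01)`
#' and (10,01) otherwise. Iterates until the largest frequency change falls
#' below `tol` or `max_iter` is reached; the observed-data log-likelihood is
#' recorded each iteration (it is non-decreasing).
#'
#' @param d1,d2 dosages at SNP1 and SNP2 (NA pairs dropped).
#' @param tol convergence tolerance on frequencies (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list of class `em_hap`: freq (named 11/10/01/00, sums to 1),
#'   loglik (per-iteration vector), iterations, converged,
#'   posterior_cis (per double-het probability of the cis (11,00) pair),
#'   expected_dosages (n x 4 matrix of expected haplotype counts per
#'   individual, rows sum to 2), n.
#' @export
em_haplotypes_2snp <- function(d1, d2, tol = 1e-8, max_iter = 1000L) {
  .assert(length(d1) == length(d2), "dosage vectors differ in length")
  cc <- stats::complete.cases(d1, d2)
  d1 <- as.integer(d1[cc]); d2 <- as.integer(d2[cc])
  .assert(all(d1 %in% 0:2) && all(d2 %in% 0:2), "dosages must be 0, 1 or 2")
  n <- length(d1)
  .assert(n >= 1, "no informative individuals")
  combo <- paste(d1, d2, sep = "_")
  dh <- combo == "1_1"
  # fixed haplotype counts from unambiguous individuals
  base <- stats::setNames(numeric(4), HAP_LABELS)
  for (k in names(.hap_pairs)) {
    nk <- sum(combo == k)
    if (nk > 0) for (h in .hap_pairs[[k]]) base[h] <- base[h] + nk
  }
  ndh <- sum(dh)
  p <- rep(0.25, 4); names(p) <- HAP_LABELS
  loglik <- numeric(0)
  ll <- function(p) {
    lp <- log(pmax(p, 1e-300))
    l <- 0
    for (k in names(.hap_pairs)) {
      nk <- sum(combo == k)
      if (nk > 0) {
        hp <- .hap_pairs[[k]]
        l <- l + nk * (lp[hp[1]] + lp[hp[2]] + if (hp[1] != hp[2]) log(2) else 0)
      }
    }
    if (ndh > 0) l <- l + ndh * log(2 * p["11"] * p["00"] + 2 * p["10"] * p["01"])
    unname(l)
  }
  w <- 0.5
  iter <- 0L; converged <- FALSE
  repeat {
    iter <- iter + 1L
    denom <- p["11"] * p["00"] + p["10"] * p["01"]
    w <- if (ndh > 0 && denom > 0) unname(p["11"] * p["00"] / denom) else 0.5
    cnt <- base
    if (ndh > 0) {
      cnt["11"] <- cnt["11"] + ndh * w; cnt["00"] <- cnt["00"] + ndh * w
      cnt["10"] <- cnt["10"] + ndh * (1 - w); cnt["01"] <- cnt["01"] + ndh * (1 - w)
    }
    p_new <- cnt / (2 * n)
    loglik <- c(loglik, ll(p_new))
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # expected haplotype counts per individual
  H <- matrix(0, n, 4, dimnames = list(NULL, HAP_LABELS))
  for (k in names(.hap_pairs)) {
    i <- combo == k
    if (any(i)) for (h in .hap_pairs[[k]]) H[i, h] <- H[i, h] + 1
  }
  if (ndh > 0) {
    H[dh, "11"] <- w; H[dh, "00"] <- w
    H[dh, "10"] <- 1 - w; H[dh, "01"] <- 1 - w
  }
  structure(list(freq = p, loglik = loglik, iterations = iter,
                 converged = converged, posterior_cis = w,
                 expected_dosages = H, n = n),
            class = "em_hap")
}

#' Haplotype association by posterior-weighted logistic regression
#'
#' Logistic regression of case status on expected haplotype dosages (each
#' individual's four expected counts sum to 2), with odds ratios reported
#' against a baseline haplotype. The default baseline is the most frequent
#' haplotype; the convention of using the haplotype carrying the
#' reduced-risk alleles can be requested explicitly via `baseline`.
#'
#' @param em an [em_haplotypes_2snp()] fit.
#' @param phenotype 0/1 case status (same individuals, same order as the
#'   complete-case dosages given to the EM).
#' @param covariates optional covariate data.frame.
#' @param baseline haplotype label ("11", "10", "01" or "00"); default the
#'   most frequent.
#' @return list of class `hap_assoc`: baseline, table (haplotype, freq, or,
#'   ci_lo, ci_hi, p_value; baseline row has OR 1), n.
#' @export
haplotype_association <- function(em, phenotype, covariates = NULL,
                                  baseline = NULL) {
  stopifnot(inherits(em, "em_hap"))
  .assert(em$converged, "EM did not converge")
  .assert(length(phenotype) == em$n, "phenotype length does not match EM individuals")
  if (is.null(baseline)) baseline <- names(which.max(em$freq))
  .assert(baseline %in% HAP_LABELS, "unknown baseline haplotype")
  .assert(em$freq[baseline] > 0, "baseline haplotype has zero frequency")
  others <- setdiff(HAP_LABELS, baseline)
  present <- others[em$freq[others] > 1e-10]
  X <- as.data.frame(em$expected_dosages[, present, drop = FALSE])
  names(X) <- paste0("hap", present)
  dat <- data.frame(.y = phenotype)
  dat <- cbind(dat, X)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  .check_separation(fit)
  co <- summary(fit)$coefficients
  tab <- data.frame(haplotype = c(baseline, present),
                    freq = unname(em$freq[c(baseline, present)]),
                    or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  tab$or[1] <- 1
  for (h in present) {
    nm <- paste0("hap", h)
    b <- co[nm, "Estimate"]; s <- co[nm, "Std. Error"]
    i <- tab$haplotype == h
    tab$or[i] <- exp(b)
    tab$ci_lo[i] <- exp(b - stats::qnorm(0.975) * s)
    tab$ci_hi[i] <- exp(b + stats::qnorm(0.975) * s)
    tab$p_value[i] <- co[nm, "Pr(>|z|)"]
  }
  structure(list(baseline = baseline, table = tab, n = em$n),
            class = "hap_assoc")
}

#' Linkage-disequilibrium r2 between two SNPs
#'
#' `r2 = D^2 / (pA qA pB qB)` with `D = p11 - pA*pB` taken from EM haplotype
#' frequencies (`method = "em"`), from supplied haplotype frequencies
#' (`hap_freq`, ordered 11/10/01/00), or as the squared Pearson correlation
#' of dosages (`method = "dosage"`; equal to the EM value when no individual
#' is phase-ambiguous).
#'
#' @param d1,d2 dosage vectors (not needed when `hap_freq` is given).
#' @param method "em" or "dosage".
#' @param hap_freq optional length-4 haplotype frequency vector
#'   (11, 10, 01, 00).
#' @return r2 in \[0,1\].
#' @export
ld_r2 <- function(d1 = NULL, d2 = NULL, method = c("em", "dosage"),
                  hap_freq = NULL) {
  method <- match.arg(method)
  if (!is.null(hap_freq)) {
    .assert(length(hap_freq) == 4 && abs(sum(hap_freq) - 1) < 1e-6,
            "hap_freq must be 4 frequencies summing to 1")
    p <- as.numeric(hap_freq)
    pA <- p[1] + p[2]; pB <- p[1] + p[3]
    .assert(pA > 0 && pA < 1 && pB > 0 && pB < 1, "monomorphic SNP")
    D <- p[1] - pA * pB
    return(min(D^2 / (pA * (1 - pA) * pB * (1 - pB)), 1))
  }
  cc <- stats::complete.cases(d1, d2)
  d1 <- d1[cc]; d2 <- d2[cc]
  .assert(stats::var(d1) > 0 && stats::var(d2) > 0, "monomorphic SNP")
  if (method == "dosage") return(stats::cor(d1, d2)^2)
  ld_r2(hap_freq = em_haplotypes_2snp(d1, d2)$freq)
}
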