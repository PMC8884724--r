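# Association: logistic OR against the contingency oracle, separation and
# collinearity flags, EM haplotypes, haplotype association, LD r2 identities.

test_that("additive_logistic matches the allele-count contingency oracle", {
  cfg <- sim_config(seed = 23L, n_individuals = 4000L, maf = 0.3,
                    assoc_effect = 0.4)
  g <- gen_genotypes(cfg)
  a <- additive_logistic(g$dosage[, 1], g$phenotype)
  # 2x2 allele-count table gives the same per-allele OR estimate up to
  # small-sample ML differences
  alleles_case <- c(sum(g$dosage[g$phenotype == 1, 1]),
                    2 * sum(g$phenotype == 1) - sum(g$dosage[g$phenotype == 1, 1]))
  alleles_ctrl <- c(sum(g$dosage[g$phenotype == 0, 1]),
                    2 * sum(g$phenotype == 0) - sum(g$dosage[g$phenotype == 0, 1]))
  or_table <- (alleles_case[1] / alleles_case[2]) /
    (alleles_ctrl[1] / alleles_ctrl[2])
  expect_equal(a$or, or_table, tolerance = 0.05)
  expect_true(a$ci95[1] < a$or && a$or < a$ci95[2])
  expect_lt(a$p_value, 0.05)
})

test_that("additive_logistic agrees with a generic ML optimiser", {
  # the closed contract: beta matches direct likelihood maximisation to 1e-6
  for (seed in 1:20) {
    with_seed(seed, {
      n <- 300L
      d <- stats::rbinom(n, 2, 0.3)
      y <- stats::rbinom(n, 1, stats::plogis(-0.2 + 0.3 * d))
      if (stats::var(d) == 0 || length(unique(y)) < 2) return(invisible(NULL))
      a <- tryCatch(additive_logistic(d, y), error = function(e) NULL)
      if (is.null(a)) return(invisible(NULL))
      nll <- function(b) -sum(stats::dbinom(y, 1, stats::plogis(b[1] + b[2] * d),
                                            log = TRUE))
      o <- stats::optim(c(0, 0), nll, method = "BFGS")
      expect_equal(a$beta, o$par[2], tolerance = 1e-5)
    })
  }
})

test_that("degenerate logistic inputs raise errors", {
  d <- c(0, 0, 1, 1, 2, 2)
  expect_error(additive_logistic(d, c(1, 1, 1, 1, 1, 1)), "case and a? ?control|one case")
  expect_error(additive_logistic(rep(1, 6), c(0, 1, 0, 1, 0, 1)), "variance")
  # complete separation: phenotype determined by genotype class
  with_seed(2, {
    dd <- stats::rbinom(200, 2, 0.5)
    expect_error(additive_logistic(dd, as.integer(dd == 2)), "separation")
  })
})

test_that("conditional adjustment appends index SNPs and flags collinearity", {
  cfg <- sim_config(seed = 29L, n_individuals = 3000L, maf = 0.3,
                    assoc_effect = 0.3)
  g <- gen_genotypes(cfg)
  with_seed(5, idx <- data.frame(rsX = stats::rbinom(3000, 2, 0.2)))
  un <- additive_logistic(g$dosage[, 1], g$phenotype)
  ad <- conditional_adjust(g$dosage[, 1], g$phenotype, index_dosages = idx)
  expect_equal(ad$adjusted_for, "rsX")
  # orthogonal index SNP: estimate barely moves
  expect_equal(ad$beta, un$beta, tolerance = 0.05)
  expect_error(conditional_adjust(g$dosage[, 1], g$phenotype,
                                  index_dosages = data.frame(dup = g$dosage[, 1])),
               "collinear")
})

test_that("adjusting for a mediating index SNP attenuates the signal", {
  # phenotype driven entirely by the index SNP; test SNP correlated via LD
  cfg <- sim_config(seed = 31L, n_individuals = 4000L, maf = 0.3,
                    assoc_effect = 0)
  g <- gen_genotypes(cfg, ld_r2 = 0.5)
  with_seed(7, {
    y <- stats::rbinom(4000, 1, stats::plogis(-0.3 + 0.5 * g$dosage[, 2]))
  })
  un <- additive_logistic(g$dosage[, 1], y)
  ad <- conditional_adjust(g$dosage[, 1], y,
                           index_dosages = data.frame(idx = g$dosage[, 2]))
  expect_gt(abs(un$beta) , abs(ad$beta))
})

test_that("EM haplotype frequencies: unambiguous counting and symmetry fixed point", {
  # doubly homozygous individuals: frequencies are direct counts / 2n
  d1 <- c(2, 2, 0, 0, 0); d2 <- c(2, 0, 2, 0, 0)
  em <- em_haplotypes_2snp(d1, d2)
  expect_equal(unname(em$freq), c(2, 2, 2, 4) / 10)
  expect_true(em$converged)
  # only double heterozygotes: uniform start is stationary at 1/4 each
  em2 <- em_haplotypes_2snp(rep(1, 50), rep(1, 50))
  expect_equal(unname(em2$freq), rep(0.25, 4))
  expect_error(em_haplotypes_2snp(numeric(0), numeric(0)), "no informative")
  expect_error(em_haplotypes_2snp(c(0, 3), c(0, 1)), "0, 1 or 2")
})

test_that("EM recovers known haplotype frequencies and loglik never decreases", {
  truth <- c(0.5, 0.3, 0.15, 0.05)
  ests <- matrix(NA_real_, 30, 4)
  for (r in 1:30) {
    with_seed(1000 + r, {
      h <- matrix(sample(4L, 2L * 800L, replace = TRUE, prob = truth), ncol = 2)
      d1 <- matrix(c(1L, 1L, 0L, 0L)[h], ncol = 2)
      d2 <- matrix(c(1L, 0L, 1L, 0L)[h], ncol = 2)
      em <- em_haplotypes_2snp(rowSums(d1), rowSums(d2))
      expect_true(all(diff(em$loglik) >= -1e-8))
      expect_equal(sum(em$freq), 1, tolerance = 1e-9)
      ests[r, ] <- em$freq
    })
  }
  se <- apply(ests, 2, stats::sd) / sqrt(nrow(ests))
  expect_true(all(abs(colMeans(ests) - truth) < 3 * se + 1e-3))
})

test_that("haplotype association: dosage-sum invariant, null ORs, planted risk", {
  cfg <- sim_config(seed = 37L, n_individuals = 2000L, maf = 0.3,
                    assoc_effect = 0)
  g <- gen_genotypes(cfg, ld_r2 = 0.2)
  em <- em_haplotypes_2snp(g$dosage[, 1], g$dosage[, 2])
  expect_equal(unname(rowSums(em$expected_dosages)), rep(2, em$n))
  ha <- haplotype_association(em, g$phenotype)
  expect_true(all(abs(log(ha$table$or[-1])) < 0.5))
  expect_true(all(ha$table$p_value[-1] > 0.001))
  # planted risk haplotype: phenotype depends on "11" expected dosage
  with_seed(11, {
    y <- stats::rbinom(em$n, 1,
                       stats::plogis(-0.5 + 0.5 * em$expected_dosages[, "11"]))
  })
  ha2 <- haplotype_association(em, y, baseline = "00")
  row11 <- ha2$table[ha2$table$haplotype == "11", ]
  expect_gt(row11$or, 1)
  expect_lt(row11$p_value, 0.05)
  expect_error(haplotype_association(em, y, baseline = "XX"), "unknown baseline")
})

test_that("ld_r2: independence, identity, frozen haplotype oracle, method agreement", {
  expect_equal(ld_r2(hap_freq = c(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(ld_r2(hap_freq = c(0.5, 0, 0, 0.5)), 1)   # D = 0.25, pA = pB = 0.5
  with_seed(3, {
    d <- stats::rbinom(500, 2, 0.4)
    expect_equal(ld_r2(d, d, method = "dosage"), 1)
  })
  expect_error(ld_r2(hap_freq = c(1, 0, 0, 0)), "monomorphic")
  # phase-unambiguous data: dosage-based equals EM-based to 1e-6
  for (seed in 1:10) {
    with_seed(seed, {
      dh <- doubled_haploids(400, c(0.4, 0.2, 0.1, 0.3))
      expect_equal(ld_r2(dh$d1, dh$d2, method = "dosage"),
                   ld_r2(dh$d1, dh$d2, method = "em"), tolerance = 1e-6)
    })
  }
})
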