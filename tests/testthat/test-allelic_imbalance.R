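# AI statistics: AR identities, the OLS-equals-t-test identity, Fisher
# combination against chi-square oracles, orientation invariance, and
# reciprocal validation gating.

test_that("allelic_ratio computes alt/(ref+alt) and rejects zero depth", {
  expect_equal(allelic_ratio(5, 5), 0.5)
  expect_equal(allelic_ratio(0, 10), 1.0)
  expect_equal(allelic_ratio(6, 2), 0.25)
  expect_equal(allelic_ratio(c(5, 0), c(5, 10)), c(0.5, 1.0))
  expect_error(allelic_ratio(0, 0), "zero total depth")
  expect_error(allelic_ratio(-1, 5), "non-negative")
})

test_that("ai_test equals the equal-variance two-sample t-test", {
  # the worked example: beta is the mean difference, p the pooled-t p-value
  ctrl <- c(0.4, 0.5, 0.6); case <- c(0.7, 0.8, 0.9)
  r <- ai_test(c(case, ctrl), c(1, 1, 1, 0, 0, 0))
  expect_equal(r$beta, 0.3)
  oracle <- stats::t.test(case, ctrl, var.equal = TRUE)
  expect_equal(r$p_value, oracle$p.value, tolerance = 1e-12)
  # property: identity holds across random inputs to 1e-10
  for (seed in 1:25) {
    with_seed(seed, {
      n0 <- sample(3:12, 1); n1 <- sample(3:12, 1)
      ar <- stats::runif(n0 + n1)
      grp <- rep(c(0L, 1L), c(n0, n1))
      r <- ai_test(ar, grp)
      o <- stats::t.test(ar[grp == 1], ar[grp == 0], var.equal = TRUE)
      expect_equal(r$p_value, o$p.value, tolerance = 1e-10)
      expect_equal(r$beta, mean(ar[grp == 1]) - mean(ar[grp == 0]), tolerance = 1e-12)
      expect_equal(r$ci95, as.numeric(o$conf.int), tolerance = 1e-10)
    })
  }
})

test_that("ai_test degenerate and error cases", {
  expect_equal(ai_test(rep(0.5, 6), rep(c(0, 1), each = 3))$p_value, 1)
  r <- ai_test(c(0.2, 0.2, 0.2, 0.8, 0.8, 0.8), rep(c(0, 1), each = 3))
  expect_equal(r$beta, 0.6)
  expect_lt(r$p_value, 1e-10)  # zero residual variance, nonzero slope
  expect_error(ai_test(c(0.5, 0.6, 0.7), c(1, 1, 1)), "each group")
})

test_that("allele-orientation swap maps AR to 1-AR and flips beta only", {
  with_seed(7, {
    refd <- stats::rpois(20, 30) + 1L
    altd <- stats::rpois(20, 30) + 1L
    grp <- rep(c(0L, 1L), each = 10)
    a <- ai_test(allelic_ratio(refd, altd), grp)
    b <- ai_test(allelic_ratio(altd, refd), grp)   # ref/alt labels swapped
    expect_equal(b$beta, -a$beta, tolerance = 1e-12)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  })
})

test_that("fisher_combine matches chi-square oracles and is monotone", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.05), 0.05)
  # frozen oracle values: pchisq(11.9829, 4) and pchisq(13.4509, 4) tails
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.017479, tolerance = 1e-3)
  expect_equal(fisher_combine(c(0.03, 0.04)), 0.009271, tolerance = 1e-3)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0,1\\]")
  expect_error(fisher_combine(numeric(0)), "no p-values")
  # monotone: decreasing any input never increases the combination
  with_seed(3, {
    for (i in 1:20) {
      p <- stats::runif(3, 0.01, 1)
      j <- sample(3, 1)
      q <- p; q[j] <- p[j] / 2
      expect_lte(fisher_combine(q), fisher_combine(p))
    }
  })
})

test_that("reciprocal validation gates on per-dataset and combined alphas", {
  mk <- function(snp, p1, p2, state = "rN") {
    data.frame(snp_id = snp, dataset_id = c("DS1", "DS2"), cell_state = state,
               n_case = 5L, n_control = 5L, beta = 0.1, se = 0.02,
               ci_lo = 0, ci_hi = 0.2, mean_ar_case = 0.6,
               mean_ar_control = 0.5, p_value = c(p1, p2))
  }
  res <- rbind(mk("a", 0.03, 0.04),       # combined 0.0093 -> pass
               mk("b", 0.03, 0.20),       # fails nominal in DS2
               mk("c", 0.04, 0.049),      # nominal ok, combined 0.0129 -> fail
               mk("d", 0.01, 0.02)[1, ])  # testable in one dataset only
  v <- reciprocal_validate(res)
  expect_equal(v$pass[match(c("a", "b", "c", "d"), v$snp_id)],
               c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$p_combined[v$snp_id == "a"], 0.009271, tolerance = 1e-3)
  expect_true(is.na(v$p_combined[v$snp_id == "d"]))
  expect_error(reciprocal_validate(res[0, ]), "empty")
  expect_error(reciprocal_validate(mk("a", .5, .5)[1, , drop = FALSE]), ">= 2 datasets")
})

test_that("validation is stratified by cell state", {
  r1 <- data.frame(snp_id = "a", dataset_id = c("DS1", "DS2"),
                   cell_state = c("rN", "Non-rN"), n_case = 5L, n_control = 5L,
                   beta = 0.1, se = 0.02, ci_lo = 0, ci_hi = 0.2,
                   mean_ar_case = .6, mean_ar_control = .5,
                   p_value = c(0.001, 0.001))
  v <- reciprocal_validate(r1)
  # nominally significant in both datasets but in different strata: no pass
  expect_false(any(v$pass))
})

test_that("ai_test_all runs per (snp, dataset, state) stratum", {
  calls <- rbind(make_calls(c(.7, .8, .9), c(.4, .5, .6), snp_id = "s1"),
                 make_calls(c(.5, .5, .5), c(.5, .5, .5), snp_id = "s2"))
  r <- ai_test_all(calls)
  expect_equal(nrow(r), 2L)
  expect_equal(r$beta[r$snp_id == "s1"], 0.3, tolerance = 1e-12)
  expect_equal(r$p_value[r$snp_id == "s2"], 1)
  expect_equal(nrow(ai_test_all(calls[0, ])), 0L)
})

test_that("rna_ai_compare mirrors ai_test per cell state", {
  expect_equal(rna_ai_compare(rep(0.5, 8), rep(c(0, 1), 4))$p_value, 1)
  with_seed(12, {
    ar <- c(stats::rbeta(10, 65, 35), stats::rbeta(10, 50, 50))
    grp <- rep(c(1L, 0L), each = 10)
    r <- rna_ai_compare(ar, grp)
    expect_gt(r$beta, 0)
  })
  expect_error(rna_ai_compare(c(0.4, 0.6), c(0, 1)), "each group")
})
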