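# Generator contracts: determinism, validation, and the moments the
# downstream statistics rely on.

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(null_allelic_fraction = 1.2), "fraction")
  expect_error(sim_config(region_length = 7001), "divisible")
  expect_error(sim_config(planted_ai = data.frame(snp = 999, case_af = .6,
                                                  control_af = .5),
                          n_snps = 10), "out of range")
  expect_error(sim_config(planted_ai = data.frame(snp = 1, case_af = 1.6,
                                                  control_af = .5)), "\\[0,1\\]")
  expect_error(sim_config(planted_se = data.frame(start = c(0, 100),
                                                  length = c(200, 50))),
               "overlap")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42L, n_snps = 5L, n_case = 4L, n_control = 4L,
                    planted_se = data.frame(start = 5000, length = 3200))
  expect_identical(gen_allelic_dataset(cfg), gen_allelic_dataset(cfg))
  expect_identical(gen_segmentation(cfg), gen_segmentation(cfg))
  expect_identical(gen_window_counts(cfg), gen_window_counts(cfg))
  expect_identical(gen_methylation(cfg), gen_methylation(cfg))
  expect_identical(gen_genotypes(cfg, ld_r2 = 0.4), gen_genotypes(cfg, ld_r2 = 0.4))
  # and they do not disturb the session RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(gen_allelic_dataset(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("null allelic counts are balanced and planted AI shifts group means", {
  cfg <- sim_config(seed = 11L, n_snps = 400L, n_datasets = 1L,
                    cell_states = "rN", rho = 0, depth_dispersion = Inf,
                    planted_ai = data.frame(snp = 1, case_af = 0.65,
                                            control_af = 0.50))
  d <- gen_allelic_dataset(cfg)
  v <- d$variants[d$variants$genotype == "het" &
                    d$variants$ref_depth + d$variants$alt_depth > 0, ]
  ar <- allelic_ratio(v$ref_depth, v$alt_depth)
  null_ar <- ar[v$snp_id != "snp00001"]
  mc_se <- stats::sd(null_ar) / sqrt(length(null_ar))
  expect_lt(abs(mean(null_ar) - 0.5), 3 * mc_se)
  # planted SNP: cases above controls
  ann <- d$annotations
  pl <- v[v$snp_id == "snp00001", ]
  grp <- ann$group[match(pl$sample_id, ann$sample_id)]
  par <- allelic_ratio(pl$ref_depth, pl$alt_depth)
  expect_gt(mean(par[grp == 1]), mean(par[grp == 0]))
})

test_that("beta-binomial moments match the closed form within 3 MC SE", {
  n <- 10000L; size <- 50L; f <- 0.5; rho <- 0.05
  x <- with_seed(5L, rbetabinom(n, size, f, rho))
  v_theory <- size * f * (1 - f) * (1 + (size - 1) * rho)
  expect_lt(abs(mean(x) - size * f), 3 * sqrt(v_theory / n))
  # variance of the sample variance ~ 2*sigma^4/(n-1) for near-normal counts
  expect_lt(abs(stats::var(x) - v_theory), 4 * v_theory * sqrt(2 / (n - 1)))
  expect_identical(with_seed(5L, rbetabinom(5, 10, 0.3, 0)),
                   with_seed(5L, stats::rbinom(5, 10, 0.3)))
})

test_that("direction flip mirrors planted fractions in flipped states", {
  cfg <- sim_config(seed = 3L, n_snps = 2L, n_datasets = 1L, n_case = 200L,
                    n_control = 200L, rho = 0,
                    cell_states = c("rN", "Non-rN"), flip_states = "rN",
                    planted_ai = data.frame(snp = 1, case_af = 0.70,
                                            control_af = 0.50))
  d <- gen_allelic_dataset(cfg)
  v <- d$variants[d$variants$snp_id == "snp00001", ]
  ann <- d$annotations
  v$group <- ann$group[match(v$sample_id, ann$sample_id)]
  v$state <- ann$cell_state[match(v$sample_id, ann$sample_id)]
  ar <- allelic_ratio(v$ref_depth, v$alt_depth)
  beta_nonrn <- mean(ar[v$group == 1 & v$state == "Non-rN"]) -
    mean(ar[v$group == 0 & v$state == "Non-rN"])
  beta_rn <- mean(ar[v$group == 1 & v$state == "rN"]) -
    mean(ar[v$group == 0 & v$state == "rN"])
  expect_gt(beta_nonrn, 0.1)
  expect_lt(beta_rn, -0.1)
})

test_that("segmentation tiles the chromosome and plants exact enhancer runs", {
  cfg <- sim_config(seed = 8L, chrom_length = 100000L,
                    planted_se = data.frame(start = c(10000, 50000),
                                            length = c(3500, 2900)))
  seg <- gen_segmentation(cfg)
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], 100000)
  expect_true(all(utils::head(seg$end, -1) == utils::tail(seg$start, -1)))
  expect_true(all(seg$end > seg$start))
  se <- call_superenhancers(seg)
  expect_equal(nrow(se), 1L)          # 2900 bp run is below the 3 kb floor
  expect_equal(se$start, 10000)
  expect_equal(se$length_bp, 3500)
})

test_that("window counts carry the planted case trend and controls stay flat", {
  cfg0 <- sim_config(seed = 21L, trend_slope = 0)
  tr0 <- gen_window_counts(cfg0, n_per_stage = 10L)
  tpm <- window_tpm(tr0$counts, tr0$library_sizes)
  m <- colMeans(tpm)
  ann <- tr0$annotations
  t_case <- stage_trend(m[ann$group == 1], ann$stage_index[ann$group == 1])
  expect_lt(abs(t_case$slope), 3 * t_case$se + 1e-12)
  cfg1 <- sim_config(seed = 21L, trend_slope = 0.5)
  tr1 <- gen_window_counts(cfg1, n_per_stage = 10L)
  m1 <- colMeans(window_tpm(tr1$counts, tr1$library_sizes))
  ann1 <- tr1$annotations
  expect_gt(stage_trend(m1[ann1$group == 1], ann1$stage_index[ann1$group == 1])$slope, 0)
  t_ctrl <- stage_trend(m1[ann1$group == 0], ann1$stage_index[ann1$group == 0])
  expect_lt(abs(t_ctrl$slope), 3 * t_ctrl$se + 1e-12)
})

test_that("methylation generator respects bounds and planted decline", {
  cfg <- sim_config(seed = 31L, meth_slope = -0.15)
  m <- gen_methylation(cfg, n_per_stage = 3L)
  expect_true(all(m$cpg$methylated <= m$cpg$total))
  expect_true(all(m$cpg$total >= 1))
  frac <- tapply(m$cpg$methylated / m$cpg$total, m$cpg$sample_id, mean)
  ann <- m$annotations
  i <- ann$group == 1
  expect_lt(stage_trend(frac[ann$sample_id[i]], ann$stage_index[i])$slope, 0)
  # degenerate fully methylated world
  cfg1 <- sim_config(seed = 31L, base_methylation = 1, meth_slope = 0)
  m1 <- gen_methylation(cfg1, n_per_stage = 2L)
  expect_true(all(m1$cpg$methylated == m1$cpg$total))
})

test_that("genotypes follow HWE at the configured maf and requested LD", {
  cfg <- sim_config(seed = 41L, n_individuals = 20000L, maf = 0.3,
                    assoc_effect = 0)
  g <- gen_genotypes(cfg, ld_r2 = 0.25)
  af <- mean(g$dosage[, 1]) / 2
  expect_lt(abs(af - 0.3), 3 * sqrt(0.3 * 0.7 / (2 * 20000)))
  # haplotype-frequency oracle for the realised r2
  h <- g$haplotypes
  p11 <- mean(h == 1L); pA <- mean(h %in% c(1L, 2L)); pB <- mean(h %in% c(1L, 3L))
  r2_hat <- (p11 - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
  expect_lt(abs(r2_hat - 0.25), 0.03)
  # null effect: fitted OR CI covers 1
  a <- additive_logistic(g$dosage[, 1], g$phenotype)
  expect_true(a$ci95[1] < 1 && 1 < a$ci95[2] || abs(a$or - 1) < 0.05)
})
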