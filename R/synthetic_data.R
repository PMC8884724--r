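# Synthetic-data generators.
#
# Every generator consumes a SimConfig and is deterministic under the
# configured seed. The generators emulate the statistical structure the
# downstream analysis assumes -- beta-binomial allelic counts at heterozygous
# SNPs with group-dependent allelic fraction, chromHMM-style segment runs with
# planted enhancer clusters, Poisson window tag tracks with stage-dependent
# trends in cases, binomial CpG methylation declining across stages, and
# Hardy-Weinberg case/control genotypes with a log-additive disease effect.

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data module in one validated list.
#' Defaults mirror the designs the pipeline targets: two ATAC-style
#' case/control datasets, resting-naive vs activated B-cell states for the
#' allelic analysis, the rN/T3/SM/DN developmental ordering for stage trends,
#' and a 7 kb region split into 50 bp windows for quantification.
#'
#' @param seed integer RNG seed; identical configs give byte-identical output.
#' @param n_case,n_control samples per group (per dataset and cell state).
#' @param n_datasets number of independent datasets for reciprocal validation.
#' @param n_snps number of SNP sites per dataset.
#' @param depth_mean,depth_dispersion negative-binomial model for total read
#'   depth at a het site (`depth_dispersion = Inf` gives Poisson depth).
#' @param null_allelic_fraction allelic fraction of unplanted SNPs (default
#'   0.5, the balanced null).
#' @param planted_ai `NULL` or a data.frame with columns `snp` (1-based index),
#'   `case_af`, `control_af`; planted SNPs use the group-specific fractions.
#' @param rho beta-binomial intra-class correlation in \[0,1); 0 recovers the
#'   binomial. Default 0.01: real allelic ATAC counts are mildly overdispersed.
#' @param cell_states cell states for the allelic datasets (each state gets its
#'   own case/control samples and its own AI stratum).
#' @param flip_states subset of `cell_states` in which the planted allelic
#'   fractions are mirrored (`f -> 1 - f`), emulating a direction flip of AI
#'   between resting-naive and activated B cells.
#' @param stage_labels ordered developmental stages for window/methylation
#'   tracks.
#' @param trend_slope per-stage multiplicative increase of mean window signal
#'   in cases (controls stay flat).
#' @param meth_slope per-stage additive change of methylation fraction in
#'   cases (negative = stage-wise demethylation; controls stay flat).
#' @param assoc_effect per-allele log-odds of disease for the association
#'   generator.
#' @param maf effect-allele frequency for genotype simulation.
#' @param n_individuals individuals for the association generator.
#' @param library_size tags per sample used for TPM scaling (default 1e7).
#' @param region_length,window_size quantified region geometry; the region
#'   length must be divisible by the window size.
#' @param chrom,chrom_length name and length of the synthetic chromosome.
#' @param window_base_rate mean tag count per window at stage 0.
#' @param base_methylation stage-0 methylation fraction.
#' @param het_rate probability a sample is heterozygous at a site.
#' @param dbsnp_rate probability a site carries a dbSNP id.
#' @param planted_se `NULL` or data.frame with columns `start`, `length`:
#'   non-overlapping enhancer-state runs to plant in the segmentation.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case = 10L, n_control = 10L,
                       n_datasets = 2L, n_snps = 100L,
                       depth_mean = 50, depth_dispersion = 10,
                       null_allelic_fraction = 0.5,
                       planted_ai = NULL,
                       rho = 0.01,
                       cell_states = c("rN", "Non-rN"),
                       flip_states = character(0),
                       stage_labels = c("rN", "T3", "SM", "DN"),
                       trend_slope = 0.5,
                       meth_slope = -0.1,
                       assoc_effect = 0,
                       maf = 0.25,
                       n_individuals = 2000L,
                       library_size = 1e7,
                       region_length = 7000L,
                       window_size = 50L,
                       chrom = "chrS",
                       chrom_length = 1000000L,
                       window_base_rate = 5,
                       base_methylation = 0.8,
                       het_rate = 1,
                       dbsnp_rate = 1,
                       planted_se = NULL) {
  cfg <- list(seed = as.integer(seed),
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_datasets = as.integer(n_datasets), n_snps = as.integer(n_snps),
              depth_mean = depth_mean, depth_dispersion = depth_dispersion,
              null_allelic_fraction = null_allelic_fraction,
              planted_ai = planted_ai, rho = rho,
              cell_states = cell_states, flip_states = flip_states,
              stage_labels = stage_labels,
              trend_slope = trend_slope, meth_slope = meth_slope,
              assoc_effect = assoc_effect, maf = maf,
              n_individuals = as.integer(n_individuals),
              library_size = library_size,
              region_length = as.integer(region_length),
              window_size = as.integer(window_size),
              chrom = chrom, chrom_length = as.integer(chrom_length),
              window_base_rate = window_base_rate,
              base_methylation = base_methylation,
              het_rate = het_rate, dbsnp_rate = dbsnp_rate,
              planted_se = planted_se)
  # JSON configs deliver plant tables as named lists of columns
  for (f in c("planted_ai", "planted_se")) {
    if (!is.null(cfg[[f]]) && !is.data.frame(cfg[[f]]))
      cfg[[f]] <- as.data.frame(cfg[[f]])
  }
  .assert(cfg$n_case >= 1 && cfg$n_control >= 1, "need at least one sample per group")
  .assert(cfg$n_datasets >= 1 && cfg$n_snps >= 1, "n_datasets and n_snps must be positive")
  .assert(cfg$depth_mean > 0, "depth_mean must be positive")
  .assert(cfg$null_allelic_fraction >= 0 && cfg$null_allelic_fraction <= 1,
          "null_allelic_fraction must lie in [0,1]")
  .assert(cfg$rho >= 0 && cfg$rho < 1, "rho must lie in [0,1)")
  .assert(cfg$maf > 0 && cfg$maf < 1, "maf must lie in (0,1)")
  .assert(cfg$het_rate >= 0 && cfg$het_rate <= 1, "het_rate must lie in [0,1]")
  .assert(cfg$base_methylation >= 0 && cfg$base_methylation <= 1,
          "base_methylation must lie in [0,1]")
  .assert(cfg$library_size > 0, "library_size must be positive")
  .assert(cfg$region_length %% cfg$window_size == 0L,
          "region_length must be divisible by window_size")
  .assert(all(cfg$flip_states %in% cfg$cell_states),
          "flip_states must be a subset of cell_states")
  if (!is.null(cfg$planted_ai)) {
    p <- cfg$planted_ai
    .assert(is.data.frame(p) && all(c("snp", "case_af", "control_af") %in% names(p)),
            "planted_ai needs columns snp, case_af, control_af")
    .assert(all(p$snp >= 1 & p$snp <= cfg$n_snps), "planted_ai snp index out of range")
    .assert(all(p$case_af >= 0 & p$case_af <= 1) && all(p$control_af >= 0 & p$control_af <= 1),
            "planted allelic fractions must lie in [0,1]")
    .assert(!anyDuplicated(p$snp), "duplicated planted snp index")
  }
  if (!is.null(cfg$planted_se)) {
    p <- cfg$planted_se
    .assert(is.data.frame(p) && all(c("start", "length") %in% names(p)),
            "planted_se needs columns start, length")
    .assert(all(p$start >= 0) && all(p$length > 0), "planted_se intervals must be valid")
    p <- p[order(p$start), , drop = FALSE]
    .assert(all(p$start + p$length <= cfg$chrom_length), "planted_se runs exceed chromosome")
    if (nrow(p) > 1) {
      .assert(all(utils::head(p$start + p$length, -1) <= utils::tail(p$start, -1)),
              "planted_se runs overlap")
    }
    cfg$planted_se <- p
  }
  class(cfg) <- "sim_config"
  cfg
}

.nb_depth <- function(n, mu, size) {
  if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate allelic read-count datasets
#'
#' Emits per-sample variant records for `cfg$n_datasets` case/control datasets
#' sharing the same SNP sites (the reciprocal-validation design). At each
#' heterozygous (SNP, sample) pair the total depth is negative-binomial and the
#' alt count beta-binomial with intra-class correlation `cfg$rho`. Unplanted
#' SNPs use `cfg$null_allelic_fraction` in both groups; planted SNPs use the
#' group-specific fractions, mirrored in any state listed in
#' `cfg$flip_states`. Site and genotype QC fields default to passing values
#' and can be overridden downstream to exercise the filter cascade.
#'
#' @param cfg a [sim_config()].
#' @return list with `variants` (long data.frame: one row per dataset, SNP and
#'   sample, carrying site QC fields `mq`, `qd`, `fs`, the genotype, allelic
#'   depths and genotype quality) and `annotations` (sample_id, group,
#'   cell_state, dataset_id, assay).
#' @export
gen_allelic_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed + 101L, {
    pos <- 1000L * seq_len(cfg$n_snps)      # >= 11 bp apart: never cluster-filtered
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, cfg$n_snps, replace = TRUE)
    alt <- unname(vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1)))
    snp_id <- sprintf("snp%05d", seq_len(cfg$n_snps))
    dbsnp <- ifelse(stats::runif(cfg$n_snps) < cfg$dbsnp_rate,
                    paste0("rs", pos), NA_character_)

    planted_af <- function(i, group, state) {
      # group: 0 control / 1 case; returns the allelic fraction for SNP i
      if (!is.null(cfg$planted_ai)) {
        j <- match(i, cfg$planted_ai$snp)
        if (!is.na(j)) {
          f <- if (group == 1L) cfg$planted_ai$case_af[j] else cfg$planted_ai$control_af[j]
          if (state %in% cfg$flip_states) f <- 1 - f
          return(f)
        }
      }
      cfg$null_allelic_fraction
    }

    ann <- list(); var <- list()
    for (d in seq_len(cfg$n_datasets)) {
      ds <- sprintf("DS%d", d)
      for (state in cfg$cell_states) {
        st <- gsub("[^A-Za-z0-9]", "", state)
        ids <- c(sprintf("%s_%s_case%02d", ds, st, seq_len(cfg$n_case)),
                 sprintf("%s_%s_ctrl%02d", ds, st, seq_len(cfg$n_control)))
        grp <- rep(c(1L, 0L), c(cfg$n_case, cfg$n_control))
        ann[[length(ann) + 1L]] <- data.frame(
          sample_id = ids, group = grp, cell_state = state,
          dataset_id = ds, assay = "ATAC", stringsAsFactors = FALSE)
        ns <- length(ids)
        for (i in seq_len(cfg$n_snps)) {
          het <- stats::runif(ns) < cfg$het_rate
          depth <- .nb_depth(ns, cfg$depth_mean, cfg$depth_dispersion)
          f <- vapply(grp, function(g) planted_af(i, g, state), numeric(1))
          altd <- integer(ns)
          altd[het] <- rbetabinom(sum(het), depth[het], f[het], cfg$rho)
          refd <- ifelse(het, depth - altd, depth)
          altd[!het] <- 0L
          var[[length(var) + 1L]] <- data.frame(
            dataset_id = ds, chrom = cfg$chrom, pos = pos[i],
            snp_id = snp_id[i], ref = ref[i], alt = alt[i],
            mq = 60, qd = 10, fs = 5, dbsnp = dbsnp[i],
            sample_id = ids,
            genotype = ifelse(het, "het", "hom_ref"),
            ref_depth = as.integer(refd), alt_depth = as.integer(altd),
            gq = 99L, stringsAsFactors = FALSE)
        }
      }
    }
    list(variants = do.call(rbind, var), annotations = do.call(rbind, ann))
  })
}

#' Core 15-state chromHMM mnemonics
#'
#' State labels of the core 15-state model; states 6 (`6_EnhG`) and 7
#' (`7_Enh`) are the enhancer states used for super-enhancer calling.
#' @export
CHROMHMM_STATES <- c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk",
                     "6_EnhG", "7_Enh", "8_ZNF/Rpts", "9_Het", "10_TssBiv",
                     "11_BivFlnk", "12_EnhBiv", "13_ReprPC", "14_ReprPCWk",
                     "15_Quies")

#' Simulate a chromHMM-style segmentation
#'
#' Tiles the synthetic chromosome with sorted, non-overlapping, gap-free
#' segments in 200 bp multiples (the chromHMM bin size). Background segments
#' draw from the 13 non-enhancer states; each planted run is emitted as
#' contiguous state 6/7 segments of exactly the requested length, so the
#' super-enhancer caller must recover it exactly.
#'
#' @param cfg a [sim_config()]; planted runs come from `cfg$planted_se`.
#' @param epigenome_id label recorded on every segment.
#' @return data.frame (chrom, start, end, state, epigenome_id) with 0-based
#'   half-open coordinates.
#' @export
gen_segmentation <- function(cfg, epigenome_id = "E_SYN") {
  stopifnot(inherits(cfg, "sim_config"))
  bin <- 200L
  bg_states <- setdiff(CHROMHMM_STATES, c("6_EnhG", "7_Enh"))
  planted <- cfg$planted_se
  with_seed(cfg$seed + 202L, {
    starts <- integer(0); ends <- integer(0); states <- character(0)
    fill_bg <- function(from, to) {
      while (from < to) {
        len <- min(bin * sample.int(5L, 1L), to - from)
        starts <<- c(starts, from); ends <<- c(ends, from + len)
        states <<- c(states, sample(bg_states, 1L))
        from <- from + len
      }
    }
    cur <- 0L
    if (!is.null(planted)) {
      for (k in seq_len(nrow(planted))) {
        s <- as.integer(planted$start[k]); L <- as.integer(planted$length[k])
        fill_bg(cur, s)
        # split the run into >=1 abutting enhancer segments, alternating states
        cuts <- unique(c(seq(0L, L, by = 2L * bin), L))
        for (j in seq_len(length(cuts) - 1L)) {
          starts <- c(starts, s + cuts[j]); ends <- c(ends, s + cuts[j + 1L])
          states <- c(states, if (j %% 2L == 1L) "6_EnhG" else "7_Enh")
        }
        cur <- s + L
      }
    }
    fill_bg(cur, cfg$chrom_length)
    data.frame(chrom = cfg$chrom, start = starts, end = ends, state = states,
               epigenome_id = epigenome_id, stringsAsFactors = FALSE)
  })
}

#' Simulate per-window tag counts across developmental stages
#'
#' One sample per (group, stage, replicate). Case window counts are Poisson
#' with mean `window_base_rate * (1 + trend_slope * stage_index)`; control
#' means stay flat at `window_base_rate`. Library sizes are constant at
#' `cfg$library_size`, so TPM trends reflect the planted slope.
#'
#' @param cfg a [sim_config()].
#' @param n_per_stage replicates per group and stage.
#' @return list of class `window_track`: `region` (chrom/start/end), `counts`
#'   (windows x samples), `library_sizes`, `annotations` (sample_id, group,
#'   stage, stage_index), `window_size`.
#' @export
gen_window_counts <- function(cfg, n_per_stage = 5L) {
  stopifnot(inherits(cfg, "sim_config"))
  .assert(cfg$library_size > 0, "non-positive library size")
  nw <- cfg$region_length %/% cfg$window_size
  stages <- cfg$stage_labels
  with_seed(cfg$seed + 303L, {
    ann <- expand.grid(rep = seq_len(n_per_stage),
                       stage_index = seq_along(stages) - 1L,
                       group = c(0L, 1L), KEEP.OUT.ATTRS = FALSE)
    ann$stage <- stages[ann$stage_index + 1L]
    ann$sample_id <- sprintf("%s_%s_s%d_r%02d",
                             ifelse(ann$group == 1L, "case", "ctrl"),
                             ann$stage, ann$stage_index, ann$rep)
    counts <- vapply(seq_len(nrow(ann)), function(j) {
      mu <- cfg$window_base_rate *
        (1 + if (ann$group[j] == 1L) cfg$trend_slope * ann$stage_index[j] else 0)
      stats::rpois(nw, max(mu, 0))
    }, numeric(nw))
    colnames(counts) <- ann$sample_id
    structure(list(region = list(chrom = cfg$chrom, start = 10000L,
                                 end = 10000L + cfg$region_length),
                   window_size = cfg$window_size,
                   counts = counts,
                   library_sizes = stats::setNames(rep(cfg$library_size, nrow(ann)),
                                                   ann$sample_id),
                   annotations = ann[c("sample_id", "group", "stage", "stage_index")]),
              class = "window_track")
  })
}

#' Simulate per-CpG bisulfite methylation counts
#'
#' CpG sites are placed on a regular grid across the region; methylated counts
#' are binomial with fraction `base_methylation + meth_slope * stage_index`
#' (clamped to \[0,1\]) in cases and flat `base_methylation` in controls.
#'
#' @param cfg a [sim_config()].
#' @param n_per_stage replicates per group and stage.
#' @param cpg_spacing bp between consecutive CpG sites.
#' @param coverage mean read coverage per CpG (Poisson, floored at 1).
#' @return list: `cpg` (chrom, pos, methylated, total, sample_id),
#'   `annotations`, `region`.
#' @export
gen_methylation <- function(cfg, n_per_stage = 5L, cpg_spacing = 20L, coverage = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  region_start <- 10000L
  pos <- seq(region_start + 1L, region_start + cfg$region_length, by = cpg_spacing)
  stages <- cfg$stage_labels
  with_seed(cfg$seed + 404L, {
    ann <- expand.grid(rep = seq_len(n_per_stage),
                       stage_index = seq_along(stages) - 1L,
                       group = c(0L, 1L), KEEP.OUT.ATTRS = FALSE)
    ann$stage <- stages[ann$stage_index + 1L]
    ann$sample_id <- sprintf("%s_%s_m%02d",
                             ifelse(ann$group == 1L, "case", "ctrl"),
                             ann$stage, ann$rep)
    recs <- lapply(seq_len(nrow(ann)), function(j) {
      pi <- cfg$base_methylation +
        if (ann$group[j] == 1L) cfg$meth_slope * ann$stage_index[j] else 0
      pi <- min(max(pi, 0), 1)
      tot <- pmax(stats::rpois(length(pos), coverage), 1L)
      data.frame(chrom = cfg$chrom, pos = pos,
                 methylated = stats::rbinom(length(pos), tot, pi),
                 total = tot, sample_id = ann$sample_id[j],
                 stringsAsFactors = FALSE)
    })
    list(cpg = do.call(rbind, recs),
         annotations = ann[c("sample_id", "group", "stage", "stage_index")],
         region = list(chrom = cfg$chrom, start = region_start,
                       end = region_start + cfg$region_length))
  })
}

#' Simulate case/control genotypes with a log-additive disease effect
#'
#' Genotypes follow Hardy-Weinberg proportions at `cfg$maf`. Disease status is
#' Bernoulli with logit `alpha + assoc_effect * dosage + covariate terms`;
#' `alpha` is chosen so the expected case fraction is ~0.5 at the configured
#' effect. Optionally a second SNP is generated in specified LD with the first
#' (via the implied haplotype frequencies), for haplotype and r2 analyses.
#'
#' @param cfg a [sim_config()].
#' @param ld_r2 `NULL` or target r2 between the two SNPs (requires a feasible
#'   D for the configured allele frequencies).
#' @param maf2 effect-allele frequency of the second SNP (default `cfg$maf`).
#' @param with_covariates if TRUE, a binary sex covariate and one standard
#'   normal "PC" with zero effect are included.
#' @return list: `dosage` (n x 1 or n x 2 matrix), `phenotype` (0/1),
#'   `covariates` (data.frame or NULL), `haplotypes` (n x 2 matrix per SNP
#'   pair, only when `ld_r2` is set), `hap_freq` (the true 11/10/01/00
#'   haplotype frequencies, when `ld_r2` is set).
#' @export
gen_genotypes <- function(cfg, ld_r2 = NULL, maf2 = NULL, with_covariates = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  pA <- cfg$maf
  with_seed(cfg$seed + 505L, {
    out <- list()
    if (is.null(ld_r2)) {
      d1 <- stats::rbinom(n, 2L, pA)
      dosage <- matrix(d1, ncol = 1, dimnames = list(NULL, "snp1"))
    } else {
      pB <- maf2 %||% pA
      Dmax <- min(pA * (1 - pB), (1 - pA) * pB)
      D <- sqrt(ld_r2 * pA * (1 - pA) * pB * (1 - pB))
      .assert(D <= Dmax + 1e-12, "requested ld_r2 infeasible at these allele frequencies")
      hf <- c(`11` = pA * pB + D, `10` = pA * (1 - pB) - D,
              `01` = (1 - pA) * pB - D, `00` = (1 - pA) * (1 - pB) + D)
      .assert(all(hf >= -1e-12), "negative haplotype frequency")
      hf <- pmax(hf, 0); hf <- hf / sum(hf)
      haps <- matrix(sample(4L, 2L * n, replace = TRUE, prob = hf), ncol = 2)
      a1 <- matrix(c(1L, 1L, 0L, 0L)[haps], ncol = 2)  # allele at SNP1 per haplotype
      a2 <- matrix(c(1L, 0L, 1L, 0L)[haps], ncol = 2)
      dosage <- cbind(snp1 = rowSums(a1), snp2 = rowSums(a2))
      out$haplotypes <- haps
      out$hap_freq <- hf
    }
    covar <- NULL
    eta_cov <- 0
    if (with_covariates) {
      covar <- data.frame(sex = stats::rbinom(n, 1L, 0.5), pc1 = stats::rnorm(n))
      eta_cov <- 0 * covar$sex          # covariates carry no effect by default
    }
    alpha <- -cfg$assoc_effect * 2 * pA  # centres the linear predictor near 0
    eta <- alpha + cfg$assoc_effect * dosage[, 1] + eta_cov
    phenotype <- stats::rbinom(n, 1L, stats::plogis(eta))
    out$dosage <- dosage
    out$phenotype <- phenotype
    out$covariates <- covar
    out
  })
}
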