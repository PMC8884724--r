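# Two-stage workflow orchestration: discovery (variant QC -> per-dataset AI
# tests -> reciprocal validation) and annotation (super-enhancer calling,
# window quantification with stage trends and background p, methylation
# trends and correlations, genetic association). Every output carries the
# config hash; an audit log records each threshold and the record counts
# before and after every filter.

#' Pipeline configuration
#'
#' Thresholds default to the values the analysis is built around: nominal
#' per-dataset alpha 0.05 and combined alpha 0.01 for reciprocal validation,
#' >= 3 het samples per group, genotype quality >= 15 and allelic depth >= 8,
#' super-enhancers >= 3 kb from states 6-7, 50 bp windows.
#'
#' @param alpha_nominal,alpha_combined validation thresholds.
#' @param min_per_group recurrence threshold per group.
#' @param min_gq,min_depth het-call thresholds.
#' @param site site-filter thresholds, a [site_thresholds()] list.
#' @param se_min_length minimum super-enhancer span (bp).
#' @param enhancer_states chromHMM state numbers treated as enhancer.
#' @param window window size (bp).
#' @param stage_order developmental stage ordering used for trend coding.
#' @param seed pipeline seed (background sampling etc.).
#' @param out_dir output directory or NULL for in-memory results only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_nominal = 0.05, alpha_combined = 0.01,
                            min_per_group = 3L, min_gq = 15, min_depth = 8,
                            site = site_thresholds(),
                            se_min_length = 3000L, enhancer_states = c(6L, 7L),
                            window = 50L,
                            stage_order = c("rN", "T3", "SM", "DN"),
                            seed = 1L, out_dir = NULL) {
  .assert(alpha_nominal > 0 && alpha_combined > 0, "alphas must be positive")
  .assert(min_per_group > 0 && min_gq >= 0 && min_depth >= 0,
          "thresholds must be positive")
  .assert(se_min_length > 0 && window > 0, "lengths must be positive")
  .assert(length(stage_order) >= 2, "stage order needs >= 2 entries")
  structure(list(alpha_nominal = alpha_nominal, alpha_combined = alpha_combined,
                 min_per_group = as.integer(min_per_group),
                 min_gq = min_gq, min_depth = min_depth, site = site,
                 se_min_length = as.integer(se_min_length),
                 enhancer_states = as.integer(enhancer_states),
                 window = as.integer(window), stage_order = stage_order,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), c(known, "site"))
  .assert(length(bad) == 0, paste("unknown config fields:", paste(bad, collapse = ", ")))
  if (!is.null(raw$site)) raw$site <- do.call(site_thresholds, as.list(raw$site))
  do.call(pipeline_config, raw)
}

.log_line <- function(log, fmt, ...) c(log, sprintf(fmt, ...))

#' Run the discovery stage
#'
#' Per dataset: site filters, het extraction, recurrence filter, AI tests per
#' (SNP, cell state); then reciprocal validation across datasets within each
#' cell-state stratum. When `config$out_dir` is set, writes
#' `ai_results.tsv`, `validated_snps.tsv` and `discovery_audit.log` (every
#' applied threshold plus record counts per step, stamped with the config
#' hash).
#'
#' @param variants long variant table (or path to its TSV).
#' @param annotations sample annotation table (or path).
#' @param config a [pipeline_config()].
#' @return list: results (per SNP/dataset/state AI tests), validated
#'   (reciprocal-validation table), audit (character vector), config_hash.
#' @export
run_discovery <- function(variants, annotations, config = pipeline_config()) {
  if (is.character(variants)) variants <- read_variants_tsv(variants)
  if (is.character(annotations)) annotations <- read_annotations_tsv(annotations)
  .assert(nrow(variants) > 0, "no variant records")
  .assert(length(unique(variants$dataset_id)) >= 2,
          "discovery needs >= 2 datasets for reciprocal validation")
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  log <- sprintf("config_hash=%s", hash)
  log <- .log_line(log,
                   "thresholds: min_mq=%g min_qd=%g max_fs=%g cluster_k=%d cluster_bp=%d min_gq=%g min_depth=%g min_per_group=%d alpha_nominal=%g alpha_combined=%g",
                   config$site$min_mq, config$site$min_qd, config$site$max_fs,
                   config$site$cluster_k, config$site$cluster_bp,
                   config$min_gq, config$min_depth, config$min_per_group,
                   config$alpha_nominal, config$alpha_combined)
  log <- .log_line(log, "input records=%d sites=%d datasets=%d",
                   nrow(variants), length(unique(.site_key(variants))),
                   length(unique(variants$dataset_id)))
  filtered <- apply_site_filters(variants, config$site)
  audit_sites <- attr(filtered, "audit")
  for (r in unique(audit_sites$rule)) {
    log <- .log_line(log, "site_filter rule=%s removed_sites=%d",
                     r, sum(audit_sites$rule == r))
  }
  log <- .log_line(log, "after site_filters records=%d", nrow(filtered))
  hets <- extract_heterozygotes(filtered, min_gq = config$min_gq,
                                min_depth = config$min_depth)
  log <- .log_line(log, "after het_extraction calls=%d", nrow(hets))
  testable <- recurrence_filter(hets, annotations,
                                min_per_group = config$min_per_group)
  log <- .log_line(log, "after recurrence_filter calls=%d testable_snps=%d",
                   nrow(testable),
                   length(unique(paste(testable$snp_id, testable$cell_state))))
  results <- ai_test_all(testable)
  log <- .log_line(log, "ai_tests n=%d", nrow(results))
  validated <- reciprocal_validate(results, config$alpha_nominal,
                                   config$alpha_combined)
  log <- .log_line(log, "validated_snps pass=%d of %d",
                   sum(validated$pass), nrow(validated))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_tsv(results, file.path(config$out_dir, "ai_results.tsv"))
    .write_tsv(validated, file.path(config$out_dir, "validated_snps.tsv"))
    writeLines(log, file.path(config$out_dir, "discovery_audit.log"))
  }
  list(results = results, validated = validated, audit = log,
       config_hash = hash)
}

#' Run the annotation/quantification stage
#'
#' Each section runs only when its input is supplied: super-enhancer calling
#' and specificity (`segments`), window-TPM quantification with per-group
#' stage trends (`track`, a `window_track`), methylation window trends
#' (`meth`, a [gen_methylation()]-style list), and single-marker association
#' (`geno`, a [gen_genotypes()]-style list). Writes one TSV per section plus
#' `annotation_summary.json` when `config$out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @param segments optional segmentation data.frame.
#' @param track optional window-count track.
#' @param meth optional methylation input.
#' @param geno optional genotype input.
#' @param snp_list optional character vector of validated SNPs to carry into
#'   the report.
#' @return list with the populated sections and the audit log.
#' @export
run_annotation <- function(config = pipeline_config(), segments = NULL,
                           track = NULL, meth = NULL, geno = NULL,
                           snp_list = character(0)) {
  hash <- config_hash(unclass(config)[setdiff(names(config), "out_dir")])
  log <- sprintf("config_hash=%s", hash)
  out <- list(snp_list = snp_list, audit = NULL, config_hash = hash)
  if (!is.null(segments)) {
    se <- call_superenhancers(segments, config$enhancer_states,
                              config$se_min_length)
    log <- .log_line(log, "se_call min_length=%d states=%s n_se=%d",
                     config$se_min_length,
                     paste(config$enhancer_states, collapse = ","), nrow(se))
    out$superenhancers <- se
  }
  if (!is.null(track)) {
    tpm <- window_tpm(track$counts, track$library_sizes)
    q3 <- apply(tpm, 2, function(v) stats::quantile(v, 0.75, names = FALSE))
    ann <- track$annotations
    trends <- lapply(split(seq_len(nrow(ann)), ann$group), function(i) {
      t <- stage_trend(q3[i], ann$stage_index[i])
      data.frame(group = ann$group[i][1], slope = t$slope, ci_lo = t$ci[1],
                 ci_hi = t$ci[2], p_value = t$p_value, n = t$n)
    })
    out$tpm_trends <- do.call(rbind, trends)
    log <- .log_line(log, "tpm_trend window=%d groups=%d", config$window,
                     nrow(out$tpm_trends))
  }
  if (!is.null(meth)) {
    ann <- meth$annotations
    reg <- meth$region
    means <- vapply(split(meth$cpg, meth$cpg$sample_id), function(d) {
      mean(window_methylation(d, reg$chrom, reg$start, reg$end,
                              window_size = config$window), na.rm = TRUE)
    }, numeric(1))
    means <- means[ann$sample_id]
    trends <- lapply(split(seq_len(nrow(ann)), ann$group), function(i) {
      t <- methylation_trend(means[i], ann$stage_index[i])
      data.frame(group = ann$group[i][1], slope = t$slope, ci_lo = t$ci[1],
                 ci_hi = t$ci[2], p_value = t$p_value, n = t$n)
    })
    out$methylation_trends <- do.call(rbind, trends)
    log <- .log_line(log, "methylation_trend window=%d groups=%d",
                     config$window, nrow(out$methylation_trends))
  }
  if (!is.null(geno)) {
    res <- additive_logistic(geno$dosage[, 1], geno$phenotype, geno$covariates)
    out$association <- data.frame(snp_id = res$snp_id, or = res$or,
                                  ci_lo = res$ci95[1], ci_hi = res$ci95[2],
                                  p_value = res$p_value, n = res$n)
    log <- .log_line(log, "association n=%d or=%.3f p=%.3g", res$n, res$or,
                     res$p_value)
  }
  out$audit <- log
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("superenhancers", "tpm_trends", "methylation_trends",
                 "association")) {
      if (!is.null(out[[nm]]))
        .write_tsv(out[[nm]], file.path(config$out_dir, paste0(nm, ".tsv")))
    }
    writeLines(log, file.path(config$out_dir, "annotation_audit.log"))
    jsonlite::write_json(
      list(config_hash = hash, sections = names(out)[!vapply(out, is.null, TRUE)]),
      file.path(config$out_dir, "annotation_summary.json"), auto_unbox = TRUE)
  }
  out
}
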