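# Variant QC: the site- and sample-level filter cascade that yields the set
# of testable heterozygous SNPs.
#
# Site-level rules (defaults as applied by the pipeline):
#   * mapping quality MQ < 20        -> removed
#   * quality-by-depth QD < 2        -> removed
#   * strand-bias score FS > 50      -> removed (FS is consumed as a caller
#     annotation, never recomputed here)
#   * SNP clusters: any chain of >= 3 SNPs in which consecutive members lie
#     within 10 bp of each other -> every member removed
# Sample-level rules: heterozygous genotype, genotype quality >= 15 and
# allelic depth sum >= 8; optionally restricted to dbSNP-annotated sites.
# Recurrence: a SNP is testable in a dataset only if it has >= 3 qualifying
# het samples in cases AND >= 3 in controls.

.site_key <- function(x) paste(x$dataset_id %||% "", x$chrom, x$pos, sep = ":")

#' Default site-filter thresholds
#' @return named list (min_mq, min_qd, max_fs, cluster_k, cluster_bp).
#' @export
site_thresholds <- function(min_mq = 20, min_qd = 2, max_fs = 50,
                            cluster_k = 3L, cluster_bp = 10L) {
  .assert(min_mq >= 0 && min_qd >= 0 && max_fs >= 0, "thresholds must be non-negative")
  .assert(cluster_k >= 2 && cluster_bp >= 1, "cluster rule needs k >= 2, bp >= 1")
  list(min_mq = min_mq, min_qd = min_qd, max_fs = max_fs,
       cluster_k = as.integer(cluster_k), cluster_bp = as.integer(cluster_bp))
}

# chain-based SNP cluster rule: positions must be sorted; returns logical
# "member of a removed cluster" per position
.cluster_members <- function(pos, k, bp) {
  n <- length(pos)
  if (n == 0L) return(logical(0))
  gap_link <- c(FALSE, diff(pos) <= bp)      # TRUE: linked to previous
  chain <- cumsum(!gap_link)
  sizes <- table(chain)
  chain %in% as.integer(names(sizes)[sizes >= k])
}

#' Apply site-level variant filters
#'
#' Removes sites failing the MQ/QD/FS thresholds and every member of any SNP
#' cluster (chains of `cluster_k` or more SNPs in which consecutive members
#' are at most `cluster_bp` apart, evaluated per chromosome and dataset).
#' Multiallelic sites (several alt alleles at one position) are dropped with a
#' warning. Input row order is preserved; an `audit` attribute records the
#' rule responsible for every excluded site.
#'
#' @param records data.frame with at least chrom, pos, mq, qd, fs (long
#'   per-sample tables are fine: rules are evaluated once per site and applied
#'   to all of its rows). Must be sorted by (chrom, pos) within dataset.
#' @param thresholds a [site_thresholds()] list.
#' @return the retained records, with attribute `audit` (a data.frame of
#'   excluded sites and the rule that removed each).
#' @export
apply_site_filters <- function(records, thresholds = site_thresholds()) {
  need <- c("chrom", "pos", "mq", "qd", "fs")
  .assert(all(need %in% names(records)), "records lack required site columns")
  if (nrow(records) == 0L) {
    attr(records, "audit") <- data.frame(site = character(0), rule = character(0))
    return(records)
  }
  key <- .site_key(records)
  first <- !duplicated(key)
  sites <- records[first, , drop = FALSE]
  skey <- key[first]
  grp <- paste(sites$dataset_id %||% "", sites$chrom, sep = ":")
  for (g in unique(grp)) {
    p <- sites$pos[grp == g]
    .assert(!is.unsorted(p), "records must be sorted by (chrom, pos)")
  }
  # multiallelic: same (dataset, chrom, pos) site key with differing alt allele
  multi <- rep(FALSE, nrow(sites))
  if ("alt" %in% names(records)) {
    nalt <- tapply(records$alt, key, function(a) length(unique(a)))
    multi <- unname(nalt[skey] > 1L)
  }
  if ("n_alt" %in% names(sites)) multi <- multi | sites$n_alt > 1L
  if (any(multi)) warning(sprintf("dropping %d multiallelic site(s)", sum(multi)))
  rule <- rep(NA_character_, nrow(sites))
  rule[multi] <- "multiallelic"
  rule[is.na(rule) & sites$mq < thresholds$min_mq] <- "low_mapping_quality"
  rule[is.na(rule) & sites$qd < thresholds$min_qd] <- "low_quality_by_depth"
  rule[is.na(rule) & sites$fs > thresholds$max_fs] <- "strand_bias"
  for (g in unique(grp)) {
    idx <- which(grp == g)
    cl <- .cluster_members(sites$pos[idx], thresholds$cluster_k, thresholds$cluster_bp)
    hit <- idx[cl & is.na(rule[idx])]
    rule[hit] <- "snp_cluster"
  }
  bad_sites <- skey[!is.na(rule)]
  keep <- !(key %in% bad_sites)
  out <- records[keep, , drop = FALSE]
  attr(out, "audit") <- data.frame(site = skey[!is.na(rule)],
                                   rule = rule[!is.na(rule)],
                                   stringsAsFactors = FALSE)
  out
}

#' Extract qualifying heterozygous calls
#'
#' Keeps (SNP, sample) pairs that are heterozygous with genotype quality
#' `>= min_gq` and allelic depth sum `>= min_depth` (the depth rule uses
#' ref_depth + alt_depth, the same counts the allelic ratio is built from).
#'
#' @param records site-filtered long records with genotype, gq, ref_depth,
#'   alt_depth columns.
#' @param min_gq minimum phred-scaled genotype quality (default 15).
#' @param min_depth minimum allelic depth sum (default 8).
#' @param require_dbsnp if TRUE, drop records without a dbSNP id.
#' @return the qualifying het-call rows.
#' @export
extract_heterozygotes <- function(records, min_gq = 15, min_depth = 8,
                                  require_dbsnp = FALSE) {
  .assert(min_gq >= 0 && min_depth >= 0, "thresholds must be non-negative")
  need <- c("genotype", "gq", "ref_depth", "alt_depth")
  .assert(all(need %in% names(records)), "records lack genotype columns")
  keep <- records$genotype == "het" &
    records$gq >= min_gq &
    (records$ref_depth + records$alt_depth) >= min_depth
  if (require_dbsnp) {
    .assert("dbsnp" %in% names(records), "no dbsnp column present")
    keep <- keep & !is.na(records$dbsnp)
  }
  records[keep, , drop = FALSE]
}

#' Recurrence filter: SNPs testable in both groups
#'
#' Retains SNPs heterozygous in at least `min_per_group` case samples AND
#' `min_per_group` control samples, evaluated within each dataset and cell
#' state (the stratum in which the AI test will run).
#'
#' @param calls het-call rows from [extract_heterozygotes()].
#' @param annotations sample annotation table (sample_id, group, cell_state,
#'   dataset_id).
#' @param min_per_group minimum het samples per group (default 3).
#' @return het-call rows for testable SNPs, with `cell_state` and `group`
#'   columns merged in.
#' @export
recurrence_filter <- function(calls, annotations, min_per_group = 3L) {
  .assert(all(c("sample_id", "group") %in% names(annotations)),
          "annotations need sample_id and group")
  if (nrow(calls) == 0L) return(cbind(calls, group = integer(0), cell_state = character(0)))
  .assert(all(calls$sample_id %in% annotations$sample_id), "unknown sample id in calls")
  ann <- annotations[!duplicated(annotations$sample_id), ]
  i <- match(calls$sample_id, ann$sample_id)
  calls$group <- ann$group[i]
  calls$cell_state <- if ("cell_state" %in% names(ann)) ann$cell_state[i] else "all"
  stratum <- paste(calls$dataset_id %||% "", calls$cell_state, calls$snp_id, sep = "\r")
  ncase <- tapply(calls$group == 1L, stratum, sum)
  nctrl <- tapply(calls$group == 0L, stratum, sum)
  ok <- names(ncase)[ncase >= min_per_group & nctrl >= min_per_group]
  calls[stratum %in% ok, , drop = FALSE]
}
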