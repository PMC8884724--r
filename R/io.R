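# Readers and writers for the plain-text formats the pipeline exchanges:
# variant TSV (a flat VCF-like dialect), sample annotation TSV, BED4
# segmentations, bedGraph window tracks, CpG TSV and dosage TSV. Writers emit
# exactly what the readers consume.

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Write / read the long variant table
#' @param variants variant records (see [gen_allelic_dataset()]).
#' @param path file path.
#' @return the path (writer) or the table (reader).
#' @export
write_variants_tsv <- function(variants, path) .write_tsv(variants, path)

#' @rdname write_variants_tsv
#' @export
read_variants_tsv <- function(path) .read_tsv(path)

#' Write / read sample annotations
#' @param annotations annotation table (sample_id, group, cell_state,
#'   dataset_id, assay).
#' @param path file path.
#' @export
write_annotations_tsv <- function(annotations, path) .write_tsv(annotations, path)

#' @rdname write_annotations_tsv
#' @export
read_annotations_tsv <- function(path) .read_tsv(path)

#' Write a segmentation as dense BED4
#' @param segments segmentation data.frame (chrom, start, end, state).
#' @param path file path.
#' @export
write_segmentation_bed <- function(segments, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", segments$chrom, segments$start,
                     segments$end, segments$state), path)
  invisible(path)
}

#' Write / read per-CpG methylation counts
#' @param cpg CpG table (chrom, pos, methylated, total, sample_id).
#' @param path file path.
#' @export
write_cpg_tsv <- function(cpg, path) .write_tsv(cpg, path)

#' @rdname write_cpg_tsv
#' @export
read_cpg_tsv <- function(path) .read_tsv(path)

#' Write / read a dosage matrix with phenotype
#' @param geno list from [gen_genotypes()].
#' @param path file path.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(phenotype = geno$phenotype, geno$dosage)
  if (!is.null(geno$covariates)) df <- cbind(df, geno$covariates)
  .write_tsv(df, path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  df <- .read_tsv(path)
  snp_cols <- grep("^snp", names(df), value = TRUE)
  list(dosage = as.matrix(df[snp_cols]),
       phenotype = df$phenotype,
       covariates = {
         rest <- setdiff(names(df), c("phenotype", snp_cols))
         if (length(rest)) df[rest] else NULL
       })
}

#' Write a window-count track as bedGraph (one file per sample) or TSV
#'
#' The TSV layout is windows x samples with chrom/start/end columns first.
#'
#' @param track a `window_track` (see [gen_window_counts()]).
#' @param path file path.
#' @export
write_window_counts_tsv <- function(track, path) {
  nw <- nrow(track$counts)
  ws <- track$window_size
  df <- data.frame(chrom = track$region$chrom,
                   start = track$region$start + (seq_len(nw) - 1L) * ws,
                   end = track$region$start + seq_len(nw) * ws)
  .write_tsv(cbind(df, as.data.frame(track$counts)), path)
}

#' Read variant records from a VCF file
#'
#' Uses VariantAnnotation (if installed) to read a VCF 4.x with GT/AD/GQ
#' genotype fields and MQ/QD/FS INFO fields into the long variant-table
#' layout the QC cascade consumes. Multiallelic rows are kept (and later
#' dropped by [apply_site_filters()]).
#'
#' @param path VCF path.
#' @param dataset_id dataset label stamped on all records.
#' @return long variant data.frame (see [gen_allelic_dataset()]).
#' @export
read_variants_vcf <- function(path, dataset_id = "DS1") {
  .assert(requireNamespace("VariantAnnotation", quietly = TRUE),
          "VariantAnnotation is required to read VCF input")
  vcf <- VariantAnnotation::readVcf(path)
  info <- VariantAnnotation::info(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  gq <- VariantAnnotation::geno(vcf)$GQ
  samples <- colnames(gt)
  nv <- nrow(gt)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ids <- rownames(gt) %||% sprintf("var%06d", seq_len(nv))
  alt_list <- VariantAnnotation::alt(vcf)
  refs <- as.character(VariantAnnotation::ref(vcf))
  icol <- function(nm) if (nm %in% names(info)) info[[nm]] else rep(NA_real_, nv)
  mqv <- icol("MQ"); qdv <- icol("QD"); fsv <- icol("FS")
  ad_pair <- function(i, j) {
    a <- if (length(dim(ad)) == 3) ad[i, j, ] else ad[i, j]
    if (is.list(a)) a <- a[[1]]
    as.integer(a)
  }
  rows <- lapply(seq_len(nv), function(i) {
    alts <- as.character(alt_list[[i]])
    g <- gt[i, ]
    geno <- ifelse(g %in% c("0/1", "1/0", "0|1", "1|0"), "het",
                   ifelse(g %in% c("1/1", "1|1"), "hom_alt",
                          ifelse(g %in% c("0/0", "0|0"), "hom_ref", "missing")))
    adm <- vapply(seq_along(samples), function(j) {
      a <- ad_pair(i, j)
      c(if (length(a) >= 1) a[1] else NA_integer_,
        if (length(a) >= 2) a[2] else NA_integer_)
    }, integer(2))
    data.frame(dataset_id = dataset_id,
               chrom = chrom[i], pos = pos[i], snp_id = ids[i],
               ref = refs[i], alt = alts[1],
               mq = mqv[i], qd = qdv[i], fs = fsv[i],
               dbsnp = if (grepl("^rs", ids[i])) ids[i] else NA_character_,
               sample_id = samples,
               genotype = geno,
               ref_depth = adm[1, ], alt_depth = adm[2, ],
               gq = as.integer(gq[i, ]),
               n_alt = length(alts),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
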