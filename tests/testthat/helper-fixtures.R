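# Fixture builders shared across test files. All randomness is seeded by the
# caller; nothing here touches disk.

# one site-level variant row with passing defaults, overridable field by field
make_site <- function(chrom = "chrS", pos = 1000L, mq = 60, qd = 10, fs = 5,
                      alt = "T", dataset_id = "DS1") {
  data.frame(dataset_id = dataset_id, chrom = chrom, pos = pos,
             snp_id = sprintf("s%d", pos), ref = "A", alt = alt,
             mq = mq, qd = qd, fs = fs, dbsnp = paste0("rs", pos),
             sample_id = "S1", genotype = "het",
             ref_depth = 10L, alt_depth = 10L, gq = 99L,
             stringsAsFactors = FALSE)
}

make_sites <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# het-call table for one SNP across case/control samples with given ARs
make_calls <- function(ar_case, ar_control, depth = 100L, snp_id = "s1",
                       dataset_id = "DS1", cell_state = "rN") {
  ar <- c(ar_case, ar_control)
  grp <- rep(c(1L, 0L), c(length(ar_case), length(ar_control)))
  alt <- round(ar * depth)
  data.frame(dataset_id = dataset_id, snp_id = snp_id,
             sample_id = sprintf("%s_%s_S%02d", dataset_id, cell_state, seq_along(ar)),
             cell_state = cell_state, group = grp,
             ref_depth = as.integer(depth - alt), alt_depth = as.integer(alt),
             stringsAsFactors = FALSE)
}

# segmentation rows from a compact spec list: list(c(start, end, state), ...)
make_segments <- function(..., chrom = "chrS", epigenome_id = "E1") {
  rows <- list(...)
  data.frame(chrom = chrom,
             start = vapply(rows, function(r) as.integer(r[[1]]), integer(1)),
             end = vapply(rows, function(r) as.integer(r[[2]]), integer(1)),
             state = vapply(rows, function(r) as.character(r[[3]]), character(1)),
             epigenome_id = epigenome_id, stringsAsFactors = FALSE)
}

# independent brute-force SE oracle: expand a gap-free segmentation to
# per-bin state numbers and use rle to find enhancer runs
brute_force_se <- function(segments, enhancer_states = c(6L, 7L),
                           min_length = 3000L, bin = 100L) {
  stopifnot(all(segments$start %% bin == 0), all(segments$end %% bin == 0))
  segments <- segments[order(segments$start), ]
  nbin <- max(segments$end) %/% bin
  st <- integer(nbin)
  for (i in seq_len(nrow(segments))) {
    idx <- (segments$start[i] %/% bin + 1L):(segments$end[i] %/% bin)
    st[idx] <- as.integer(sub("^E?([0-9]+).*$", "\\1", segments$state[i]))
  }
  r <- rle(st %in% enhancer_states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * bin >= min_length
  data.frame(start = (starts[keep] - 1L) * bin, end = ends[keep] * bin,
             length_bp = r$lengths[keep] * bin)
}

# random gap-free segmentation in `bin` multiples (states drawn from all 15)
random_segmentation <- function(n_segments = 30L, bin = 100L,
                                max_len_bins = 12L) {
  lens <- bin * sample.int(max_len_bins, n_segments, replace = TRUE)
  ends <- cumsum(lens)
  data.frame(chrom = "chrS", start = c(0L, utils::head(ends, -1L)), end = ends,
             state = sample(aise::CHROMHMM_STATES, n_segments, replace = TRUE),
             epigenome_id = "E1", stringsAsFactors = FALSE)
}

# doubled-haploid genotypes: every individual is two copies of one haplotype,
# so phase is unambiguous and dosage-based LD equals haplotype-based LD
doubled_haploids <- function(n, hap_freq) {
  h <- sample(4L, n, replace = TRUE, prob = hap_freq)
  list(d1 = 2L * c(1L, 1L, 0L, 0L)[h], d2 = 2L * c(1L, 0L, 1L, 0L)[h])
}
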