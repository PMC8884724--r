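# Super-enhancer calling from chromHMM 15-state segmentations.
#
# A super-enhancer (SE) is a maximal run of exactly-abutting segments whose
# state belongs to the enhancer states (6_EnhG, 7_Enh in the core 15-state
# model) spanning >= 3 kb. Coordinates are BED-style: 0-based, half-open.

# numeric state index from a mnemonic ("7_Enh") or bare ("E7") label; NA if
# unparseable
.state_number <- function(state) {
  out <- rep(NA_integer_, length(state))
  ok <- grepl("^(E[0-9]+$|[0-9]+_)", state)
  out[ok] <- suppressWarnings(as.integer(sub("^E?([0-9]+).*$", "\\1", state[ok])))
  out
}

#' Parse a chromHMM segmentation BED
#'
#' Reads dense 4-column BED (chrom, start, end, state), validates intervals
#' and state labels (both the `7_Enh` mnemonic and bare `E7` dialects parse),
#' and returns segments sorted by (chrom, start) with a warning if the input
#' was out of order.
#'
#' @param path file path, or a character vector of BED lines.
#' @param epigenome_id label attached to the parsed segments.
#' @return data.frame: chrom, start, end, state, epigenome_id.
#' @export
parse_segmentation <- function(path, epigenome_id = NA_character_) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, "empty segmentation")
  parts <- strsplit(lines, "[ \t]+")
  .assert(all(lengths(parts) >= 4L), "malformed BED line (need 4 columns)")
  seg <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
                    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
                    state = vapply(parts, `[`, "", 4L),
                    epigenome_id = epigenome_id, stringsAsFactors = FALSE)
  .assert(!anyNA(seg$start) && !anyNA(seg$end), "non-numeric coordinates")
  .assert(all(seg$end > seg$start), "segment with end <= start")
  num <- .state_number(seg$state)
  .assert(!anyNA(num) && all(num >= 1 & num <= 15), "unknown chromatin state label")
  o <- order(seg$chrom, seg$start)
  if (!identical(o, seq_len(nrow(seg)))) {
    warning("segmentation lines out of order; sorting")
    seg <- seg[o, , drop = FALSE]
    rownames(seg) <- NULL
  }
  seg
}

#' Call super-enhancers from a segmentation
#'
#' Scans each chromosome (per epigenome) for maximal runs of enhancer-state
#' segments whose intervals abut exactly (`next start == previous end`); any
#' intervening non-enhancer segment or coordinate gap breaks the run. A run is
#' promoted to a super-enhancer iff its total span is at least `min_length`.
#'
#' @param segments sorted segmentation (as from [parse_segmentation()] or
#'   [gen_segmentation()]).
#' @param enhancer_states integer state numbers counted as enhancer (default
#'   6 and 7, i.e. 6_EnhG and 7_Enh).
#' @param min_length minimum SE span in bp (default 3000).
#' @return data.frame: chrom, start, end, length_bp, n_segments, epigenome_id.
#' @export
call_superenhancers <- function(segments, enhancer_states = c(6L, 7L),
                                min_length = 3000L) {
  .assert(all(c("chrom", "start", "end", "state") %in% names(segments)),
          "segments lack required columns")
  if (!"epigenome_id" %in% names(segments)) segments$epigenome_id <- NA_character_
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      length_bp = integer(0), n_segments = integer(0),
                      epigenome_id = character(0))
  if (nrow(segments) == 0L) return(empty)
  num <- .state_number(segments$state)
  out <- list()
  grp <- paste(segments$epigenome_id, segments$chrom, sep = "\r")
  for (g in unique(grp)) {
    s <- segments[grp == g, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    .assert(all(utils::head(s$end, -1) <= utils::tail(s$start, -1)),
            "overlapping segments")
    enh <- .state_number(s$state) %in% enhancer_states
    # run breaks: state change to/from enhancer, or a coordinate gap
    abut <- c(TRUE, utils::head(s$end, -1) == utils::tail(s$start, -1))
    run_id <- cumsum(!(enh & abut & c(FALSE, utils::head(enh, -1))))
    for (r in split(which(enh), run_id[enh])) {
      span <- s$end[r[length(r)]] - s$start[r[1]]
      if (span >= min_length) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = s$chrom[1], start = s$start[r[1]], end = s$end[r[length(r)]],
          length_bp = span, n_segments = length(r),
          epigenome_id = s$epigenome_id[1], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res[order(res$epigenome_id, res$chrom, res$start), , drop = FALSE]
}

#' Total enhancer-state length overlapping a region
#'
#' Sums, over all enhancer-state segments, the length of their intersection
#' with `[region_start, region_end)` on `region_chrom`.
#'
#' @param segments segmentation data.frame.
#' @param region_chrom,region_start,region_end the query interval (0-based,
#'   half-open).
#' @inheritParams call_superenhancers
#' @return total overlap in bp.
#' @export
enhancer_length_in_region <- function(segments, region_chrom, region_start,
                                      region_end, enhancer_states = c(6L, 7L)) {
  .assert(region_end > region_start, "malformed region")
  s <- segments[segments$chrom == region_chrom &
                  .state_number(segments$state) %in% enhancer_states, , drop = FALSE]
  if (nrow(s) == 0L) return(0L)
  ov <- pmin(s$end, region_end) - pmax(s$start, region_start)
  sum(pmax(ov, 0L))
}

#' Cross-epigenome specificity of enhancer activity in a region
#'
#' Ranks epigenomes by their enhancer-state length within a region and reports
#' the query epigenome's rank and the fraction of epigenomes with any
#' enhancer there (the "43 of 127 = 33.9%"-style summary).
#'
#' @param lengths data.frame with columns epigenome_id and length (bp of
#'   enhancer state in the region, one row per epigenome).
#' @param query_epigenome epigenome id to rank.
#' @return list: `table` (sorted by decreasing length, with rank),
#'   `query_rank`, `n_with_enhancer`, `fraction_with_enhancer`.
#' @export
specificity_profile <- function(lengths, query_epigenome) {
  .assert(all(c("epigenome_id", "length") %in% names(lengths)),
          "lengths needs epigenome_id and length columns")
  .assert(nrow(lengths) >= 1, "no epigenomes")
  .assert(query_epigenome %in% lengths$epigenome_id, "query epigenome absent")
  tab <- lengths[order(-lengths$length, lengths$epigenome_id), , drop = FALSE]
  tab$rank <- rank(-tab$length, ties.method = "min")
  rownames(tab) <- NULL
  list(table = tab,
       query_rank = tab$rank[tab$epigenome_id == query_epigenome][1],
       n_with_enhancer = sum(tab$length > 0),
       fraction_with_enhancer = mean(tab$length > 0))
}
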