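# Cleavage-site calling from strand-paired fragment-end count tracks.
#
# The pairing rule: a staggered duplex cut at top bond i leaves a top-strand
# 3' end at reference position i and a bottom-strand 3' end at reference
# position i - 1 (2-nt 3' overhang). A site is called iff both strands
# support it, and the two supports are summed into the site weight.

#' Call cleavage sites from a pair of end-count tracks
#'
#' Emits a site at top-strand bond `i` iff the top track has at least
#' `min_support` reads at position `i` and the bottom track at least
#' `min_support` at position `i - 1`. The weight of a called site is the sum
#' of the two supports. Segment-terminal end positions (top at L, bottom at
#' 1) are excluded: they are library preparation artifacts, as shown by
#' uncleaved control libraries.
#'
#' @param top_track,bottom_track [end_count_track()]s of the same segment.
#' @param min_support Minimum read count required on each strand (default 1).
#' @return A `called_sites` data frame: `segment_id`, `i_top`,
#'   `top_support`, `bottom_support`, `weight`, sorted by coordinate.
#' @export
call_sites <- function(top_track, bottom_track, min_support = 1L) {
  stopifnot(inherits(top_track, "end_count_track"),
            inherits(bottom_track, "end_count_track"),
            top_track$strand == "top", bottom_track$strand == "bottom",
            min_support >= 1L)
  if (!identical(top_track$segment_id, bottom_track$segment_id) ||
      top_track$length != bottom_track$length) {
    stop("tracks belong to different segments")
  }
  L <- top_track$length
  # candidate bonds: i in 3..L-1 (i = 2 pairs with the bottom terminus at 1;
  # i = L is the top terminus; i - 1 < 1 is skipped by construction)
  cand <- seq.int(3L, L - 1L)
  ok <- top_track$counts[cand] >= min_support &
    bottom_track$counts[cand - 1L] >= min_support
  i <- cand[ok]
  out <- data.frame(
    segment_id = rep(top_track$segment_id, length(i)),
    i_top = i,
    top_support = top_track$counts[i],
    bottom_support = bottom_track$counts[i - 1L],
    stringsAsFactors = FALSE
  )
  out$weight <- out$top_support + out$bottom_support
  class(out) <- c("called_sites", "data.frame")
  out
}

#' Fraction of end reads at segment termini
#'
#' The control statistic for end-capture libraries: the proportion of all
#' counted ends that fall on a segment-terminal 3'-end position (top-strand
#' track at position L, bottom-strand track at position 1; six positions for
#' a three-segment genome). Uncleaved control libraries put nearly all their
#' reads there; digested libraries very few.
#'
#' @param tracks List of per-segment track pairs as returned in
#'   `simulate_end_capture()$tracks` (each element a list with `top` and
#'   `bottom` [end_count_track()]s).
#' @return Proportion in `[0, 1]`.
#' @export
terminus_fraction <- function(tracks) {
  total <- 0
  term <- 0
  for (tr in tracks) {
    stopifnot(inherits(tr$top, "end_count_track"),
              inherits(tr$bottom, "end_count_track"))
    total <- total + sum(tr$top$counts) + sum(tr$bottom$counts)
    term <- term + tr$top$counts[tr$top$length] + tr$bottom$counts[1L]
  }
  if (total == 0) stop("no end counts in any track")
  term / total
}

#' Weighted sequence-window instances for called sites
#'
#' One window per called site, centred on its bond, carrying the site weight
#' (the summed per-strand read support). These weighted instances are the
#' positive set for discriminative motif discovery; truncated windows are
#' flagged.
#'
#' @param sites A `called_sites` data frame (or any data frame with
#'   `segment_id`, `i_top`, `weight`).
#' @param segments Named list of [ds_segment()]s covering all site segments.
#' @param width Window width (even, >= 4); default 14.
#' @return Data frame: `segment_id`, `i_top`, `sequence`, `bond_offset`,
#'   `truncated_left`, `truncated_right`, `weight`.
#' @export
weighted_instances <- function(sites, segments, width = 14L) {
  stopifnot(is.data.frame(sites),
            all(c("segment_id", "i_top", "weight") %in% names(sites)))
  if (inherits(segments, "ds_segment")) segments <- list(segments)
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    names(segments) <- vapply(segments, `[[`, character(1L), "id")
  }
  missing <- setdiff(unique(sites$segment_id), names(segments))
  if (length(missing) > 0L) {
    stop(sprintf("no reference segment for: %s", paste(missing, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(sites)), function(k) {
    w <- site_window(segments[[sites$segment_id[k]]], sites$i_top[k], width)
    data.frame(
      segment_id = sites$segment_id[k], i_top = sites$i_top[k],
      sequence = w$sequence, bond_offset = w$bond_offset,
      truncated_left = w$truncated_left, truncated_right = w$truncated_right,
      weight = sites$weight[k], stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(segment_id = character(0), i_top = integer(0),
               sequence = character(0), bond_offset = integer(0),
               truncated_left = logical(0), truncated_right = logical(0),
               weight = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a called-site table to TSV
#' @param sites A `called_sites` data frame.
#' @param path Output file.
#' @param meta Extra metadata lines (see [run_metadata()]).
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path, meta = run_metadata()) {
  write_tsv_table(as.data.frame(sites), path, meta = meta)
}

#' Read a called-site table written by [write_site_table()]
#' @param path TSV file.
#' @return A `called_sites` data frame.
#' @export
read_site_table <- function(path) {
  out <- read_tsv_table(path)
  class(out) <- c("called_sites", "data.frame")
  out
}
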