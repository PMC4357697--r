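# Coordinate system and cut-geometry algebra for staggered duplex cleavage.
#
# Conventions used throughout the package:
#   * Residue positions are 1-based and inclusive.
#   * A scissile bond is named by the residue immediately 5' of it, in the
#     numbering of the strand on which it is named ("bond i" sits between
#     residues i and i+1 of that strand).
#   * Only the top strand of a duplex is stored; the bottom strand is its
#     exact reverse complement, numbered 5'->3' in its own frame, so bottom
#     residue b corresponds to reference (top-strand) position L - b + 1.
#   * Overhangs are signed: positive = 3' overhang, negative = 5', 0 = blunt.

RNA_BASES <- c("A", "C", "G", "U")

# full IUPAC complement table (RNA alphabet)
IUPAC_COMPLEMENT <- c(
  A = "U", C = "G", G = "C", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Reverse complement of an RNA sequence
#'
#' Strict RNA alphabet (`A`, `C`, `G`, `U`) by default; with `iupac = TRUE`
#' degenerate IUPAC letters are complemented through their standard pairings
#' (e.g. `R` <-> `Y`), which is what motif scanning of the opposite strand
#' requires.
#'
#' @param seq A single character string, 5'->3'.
#' @param iupac Allow degenerate IUPAC letters.
#' @return The reverse complement, 5'->3'.
#' @examples
#' reverse_complement("ACCU")  # "AGGU"
#' @export
reverse_complement <- function(seq, iupac = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (nchar(seq) == 0L) return("")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  allowed <- if (iupac) names(IUPAC_COMPLEMENT) else RNA_BASES
  bad <- which(!(chars %in% allowed))
  if (length(bad) > 0L) {
    stop(sprintf(
      "non-alphabet character(s) %s at position(s) %s",
      paste(sQuote(chars[bad]), collapse = ", "),
      paste(bad, collapse = ", ")
    ))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Construct a double-stranded RNA reference segment
#'
#' A perfect linear duplex: the top strand is stored 5'->3' and the bottom
#' strand is always its exact reverse complement (no bulges or mismatches).
#'
#' @param id Segment label.
#' @param top_sequence Top-strand RNA sequence, 5'->3'.
#' @return An object of class `ds_segment` with fields `id`, `top_sequence`,
#'   `length`.
#' @export
ds_segment <- function(id, top_sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(top_sequence), length(top_sequence) == 1L)
  chars <- strsplit(top_sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% RNA_BASES))
  if (length(bad) > 0L) {
    stop(sprintf(
      "segment '%s': non-RNA character(s) %s at position(s) %s",
      id, paste(sQuote(chars[bad]), collapse = ", "),
      paste(utils::head(bad, 5L), collapse = ", ")
    ))
  }
  structure(
    list(id = id, top_sequence = top_sequence, length = nchar(top_sequence)),
    class = "ds_segment"
  )
}

#' @export
print.ds_segment <- function(x, ...) {
  cat(sprintf(
    "<ds_segment> %s: %d bp duplex (top strand %s...)\n",
    x$id, x$length, substr(x$top_sequence, 1L, min(12L, x$length))
  ))
  invisible(x)
}

#' Bottom-strand sequence of a segment
#' @param segment A `ds_segment`.
#' @return The bottom strand, 5'->3' in its own frame.
#' @export
bottom_sequence <- function(segment) {
  stopifnot(inherits(segment, "ds_segment"))
  reverse_complement(segment$top_sequence)
}

.check_bond <- function(i, length, what = "bond index") {
  if (!is.numeric(i) || length(i) != 1L || is.na(i) || i != round(i)) {
    stop(sprintf("%s must be a single integer", what))
  }
  if (i < 1L || i > length - 1L) {
    stop(sprintf("%s %d outside valid range [1, %d]", what, i, length - 1L))
  }
  as.integer(i)
}

#' Bottom-strand bond paired with a top-strand cut
#'
#' For a duplex of `length` bp cut after top-strand residue `i_top` by an
#' enzyme leaving a 3' overhang of `overhang` nt, the paired bottom-strand
#' cut falls after bottom residue `length - i_top + overhang` (bottom-strand
#' numbering). The canonical Mini-III geometry (`overhang = 2`) maps a cut
#' between top residues 14|15 of a 30-bp duplex to the bond between bottom
#' residues 18|19.
#'
#' @param i_top Top-strand bond index (residue 5' of the cut).
#' @param length Duplex length in bp.
#' @param overhang Signed overhang (positive = 3'); default 2.
#' @return Bottom-strand bond index.
#' @export
bottom_bond_from_top <- function(i_top, length, overhang = 2L) {
  length <- as.integer(length)
  i_top <- .check_bond(i_top, length, "top bond index")
  b <- length - i_top + as.integer(overhang)
  if (b < 1L || b > length - 1L) {
    stop(sprintf(
      "cut at top bond %d with overhang %d falls outside the duplex (bottom bond %d not in [1, %d])",
      i_top, overhang, b, length - 1L
    ))
  }
  b
}

#' Inverse of [bottom_bond_from_top()]
#' @param b_bottom Bottom-strand bond index.
#' @inheritParams bottom_bond_from_top
#' @return Top-strand bond index.
#' @export
top_bond_from_bottom <- function(b_bottom, length, overhang = 2L) {
  length <- as.integer(length)
  b_bottom <- .check_bond(b_bottom, length, "bottom bond index")
  i <- length - b_bottom + as.integer(overhang)
  if (i < 1L || i > length - 1L) {
    stop(sprintf(
      "cut at bottom bond %d with overhang %d falls outside the duplex (top bond %d not in [1, %d])",
      b_bottom, overhang, i, length - 1L
    ))
  }
  i
}

#' Infer the overhang from a pair of cut positions
#'
#' Given the two observed bond indices of a staggered duplex cut (each in its
#' own strand's numbering), returns the signed overhang
#' `i_top + b_bottom - length`: positive values are 3' overhangs, negative 5',
#' zero blunt. The 14|15 + 18|19 cut of a 30-bp duplex gives +2.
#'
#' @param i_top Top-strand bond index.
#' @param b_bottom Bottom-strand bond index.
#' @param length Duplex length in bp.
#' @return Signed overhang in nt.
#' @export
infer_overhang <- function(i_top, b_bottom, length) {
  length <- as.integer(length)
  i_top <- .check_bond(i_top, length, "top bond index")
  b_bottom <- .check_bond(b_bottom, length, "bottom bond index")
  as.integer(i_top + b_bottom - length)
}

#' A duplex cut site
#'
#' @param segment_id Segment label.
#' @param i_top Top-strand bond index.
#' @param length Segment length (bp).
#' @param overhang Signed overhang, default 2.
#' @return A `duplex_cut_site` with the derived bottom bond index.
#' @export
duplex_cut_site <- function(segment_id, i_top, length, overhang = 2L) {
  b <- bottom_bond_from_top(i_top, length, overhang)
  structure(
    list(segment_id = segment_id, i_top = as.integer(i_top),
         overhang = as.integer(overhang), b_bottom = b),
    class = "duplex_cut_site"
  )
}

#' Sequence window centred on a cleavage bond
#'
#' Extracts up to `width` nt of the top strand centred on bond `i_top`:
#' `width/2 - 1` residues 5' of the bonded residue and `width/2` residues 3'
#' of it, i.e. reference positions `i_top - (width/2 - 1)` ...
#' `i_top + width/2`. Windows whose site lies closer than that to a segment
#' end are truncated with flags set, and `bond_offset` (index of the residue
#' 5' of the bond within the window) adjusted.
#'
#' @param segment A `ds_segment`.
#' @param i_top Bond index.
#' @param width Full window width in nt (even, >= 4); default 14.
#' @return A `site_window`: `sequence`, `bond_offset`, `start`, `end`,
#'   `truncated_left`, `truncated_right`.
#' @export
site_window <- function(segment, i_top, width = 14L) {
  stopifnot(inherits(segment, "ds_segment"))
  if (!is.numeric(width) || width < 4L || width %% 2L != 0L) {
    stop("width must be an even integer >= 4")
  }
  width <- as.integer(width)
  i_top <- .check_bond(i_top, segment$length, "bond index")
  want_start <- i_top - (width %/% 2L - 1L)
  want_end <- i_top + width %/% 2L
  start <- max(1L, want_start)
  end <- min(segment$length, want_end)
  structure(
    list(
      sequence = substr(segment$top_sequence, start, end),
      bond_offset = i_top - start + 1L,
      start = as.integer(start), end = as.integer(end),
      truncated_left = want_start < 1L,
      truncated_right = want_end > segment$length
    ),
    class = "site_window"
  )
}

#' Map a strong primer-extension termination to a scissile bond
#'
#' A strong reverse-transcription stop at residue `k` of the template strand
#' marks that strand's cleavage-generated 5'-terminal residue, so the bond is
#' `k - 1 | k` in the template strand's own numbering. Weaker stops one
#' residue beyond arise from non-templated addition by the reverse
#' transcriptase and are ignored by this analysis.
#'
#' @param template_strand `"top"` or `"bottom"`.
#' @param strong_termination_pos Residue index of the strong stop (>= 2), in
#'   the template strand's own 5'->3' numbering.
#' @return A list (`strand`, `index`) naming the bond on the template strand.
#' @export
termination_to_bond <- function(template_strand, strong_termination_pos) {
  template_strand <- match.arg(template_strand, c("top", "bottom"))
  stopifnot(is.numeric(strong_termination_pos), strong_termination_pos >= 2L)
  list(strand = template_strand, index = as.integer(strong_termination_pos) - 1L)
}

#' Convert a bottom-strand residue position to reference coordinates
#' @param pos Bottom-strand position (own 5'->3' numbering).
#' @param length Segment length.
#' @return Reference (top-strand) position `length - pos + 1`.
#' @export
bottom_pos_to_ref <- function(pos, length) {
  as.integer(length) - as.integer(pos) + 1L
}
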