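# File formats: FASTA segments (Biostrings), strand-split BedGraph end
# tracks (rtracklayer), and TSV tables with '#' metadata headers.
#
# External BedGraph coordinates are 0-based half-open; internal positions are
# 1-based residue-inclusive, so internal position p corresponds to the
# interval [p-1, p). rtracklayer performs that conversion (GRanges are
# 1-based); the boundary cases are unit-tested.

#' Read dsRNA reference segments from FASTA
#'
#' @param path FASTA file.
#' @param dna_to_rna If `TRUE`, transliterate `T` -> `U` (for DNA-alphabet
#'   input). Off by default: an RNA alphabet is required.
#' @return A named list of [ds_segment()] objects.
#' @export
read_segments_fasta <- function(path, dna_to_rna = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  segs <- lapply(seq_along(ss), function(k) {
    seq <- toupper(as.character(ss[[k]]))
    if (dna_to_rna) seq <- chartr("T", "U", seq)
    # keep only the first word of the FASTA header as the id
    id <- strsplit(names(ss)[k], "\\s+")[[1L]][1L]
    ds_segment(id, seq)
  })
  names(segs) <- vapply(segs, `[[`, character(1L), "id")
  segs
}

#' Write dsRNA reference segments to FASTA
#' @param segments List of [ds_segment()] objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_segments_fasta <- function(segments, path) {
  if (inherits(segments, "ds_segment")) segments <- list(segments)
  seqs <- Biostrings::BStringSet(
    vapply(segments, `[[`, character(1L), "top_sequence")
  )
  names(seqs) <- vapply(segments, `[[`, character(1L), "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Per-strand fragment 3'-end count track
#'
#' Counts of mapped fragment 3'-end positions on one strand of one segment,
#' indexed by reference (top-strand) coordinates: position p on the top track
#' means a top-strand fragment whose 3'-terminal residue is reference
#' position p; position q on the bottom track means a bottom-strand fragment
#' whose 3'-terminal residue sits at reference position q.
#'
#' @param segment_id Segment label.
#' @param strand `"top"` or `"bottom"`.
#' @param length Segment length (nt).
#' @param counts Either a full-length non-negative integer vector, or a
#'   sparse two-column data frame (`pos`, `count`).
#' @return An `end_count_track`.
#' @export
end_count_track <- function(segment_id, strand, length, counts) {
  strand <- match.arg(strand, c("top", "bottom"))
  length <- as.integer(length)
  if (is.data.frame(counts)) {
    stopifnot(all(c("pos", "count") %in% names(counts)))
    v <- integer(length)
    if (nrow(counts) > 0L) {
      if (any(counts$pos < 1L | counts$pos > length)) {
        stop("count positions outside [1, segment length]")
      }
      agg <- rowsum(as.integer(counts$count), group = as.integer(counts$pos))
      v[as.integer(rownames(agg))] <- as.integer(agg)
    }
    counts <- v
  }
  counts <- as.integer(counts)
  stopifnot(base::length(counts) == length, all(counts >= 0L))
  structure(
    list(segment_id = segment_id, strand = strand, length = length,
         counts = counts),
    class = "end_count_track"
  )
}

#' @export
print.end_count_track <- function(x, ...) {
  cat(sprintf(
    "<end_count_track> %s/%s: %d positions, %d reads at %d occupied positions\n",
    x$segment_id, x$strand, x$length, sum(x$counts), sum(x$counts > 0L)
  ))
  invisible(x)
}

.track_granges <- function(track) {
  nz <- which(track$counts > 0L)
  GenomicRanges::GRanges(
    seqnames = track$segment_id,
    ranges = IRanges::IRanges(start = nz, width = 1L),
    score = track$counts[nz]
  )
}

#' Write an end-count track to BedGraph
#'
#' One file per strand; by convention the strand is encoded in the filename
#' suffix (`.top.bedgraph` / `.bottom.bedgraph`). Output intervals are
#' 0-based half-open single-base intervals (internal position p becomes
#' `[p-1, p)`).
#'
#' @param track An [end_count_track()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "end_count_track"))
  rtracklayer::export(.track_granges(track), path, format = "bedGraph")
  invisible(path)
}

#' Read an end-count track from BedGraph
#'
#' @param path BedGraph file (0-based half-open intervals with counts).
#' @param segment_id Expected segment id (must match the track's seqname).
#' @param strand `"top"` or `"bottom"`.
#' @param length Segment length in nt.
#' @return An [end_count_track()].
#' @export
read_bedgraph <- function(path, segment_id, strand, length) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  counts <- integer(length)
  if (length(gr) > 0L) {
    if (!all(as.character(GenomicRanges::seqnames(gr)) == segment_id)) {
      stop(sprintf("BedGraph seqnames do not all match segment '%s'", segment_id))
    }
    st <- GenomicRanges::start(gr)
    en <- GenomicRanges::end(gr)
    if (any(en < st)) stop("zero- or negative-length interval in BedGraph")
    if (any(st < 1L) || any(en > length)) {
      stop("BedGraph interval outside [1, segment length]")
    }
    sc <- as.integer(gr$score)
    if (any(sc < 0L)) stop("negative counts in BedGraph")
    for (k in seq_along(gr)) {
      counts[st[k]:en[k]] <- counts[st[k]:en[k]] + sc[k]
    }
  }
  end_count_track(segment_id, strand, length, counts)
}

#' Write a data frame as TSV with '#' metadata header lines
#'
#' @param df Data frame.
#' @param path Output file.
#' @param meta Character vector of metadata lines (written as `# key: value`).
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(meta) > 0L) writeLines(paste0("# ", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table written by [write_tsv_table()]
#' @param path TSV file; lines starting with `#` are ignored.
#' @return A data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Run-configuration metadata lines for output headers
#'
#' Serialises a configuration list into `key=value` metadata strings
#' (embedded into every table this package writes) so a run can be
#' reproduced from its outputs.
#'
#' @param config Named list of scalar parameters.
#' @param seed Integer seed used for the run, if any.
#' @return Character vector of metadata lines.
#' @export
run_metadata <- function(config = list(), seed = NULL) {
  lines <- c(
    sprintf("tool: dscleave %s", as.character(utils::packageVersion("dscleave"))),
    "coordinates: 1-based residue-inclusive; bond i lies between residues i and i+1"
  )
  if (!is.null(seed)) lines <- c(lines, sprintf("seed: %d", as.integer(seed)))
  if (length(config) > 0L) {
    flat <- vapply(config, function(v) paste(format(v), collapse = ","),
                   character(1L))
    lines <- c(lines, sprintf("config: %s",
                              paste(names(flat), flat, sep = "=", collapse = "; ")))
  }
  lines
}
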