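# Saturation-mutagenesis design and consensus derivation, motif/PWM
# scanning of duplexes, and in-silico digestion with gel-banding prediction.

#' Design a saturation-mutagenesis variant set
#'
#' Every position of a 14-nt window substituted by every alternative base:
#' exactly 3 variants per position, 42 in total, each at Hamming distance 1
#' from the wild type.
#'
#' @param window Wild-type 14-nt RNA window.
#' @return Data frame: `window_position`, `base`, `sequence`.
#' @export
design_saturation <- function(window) {
  stopifnot(is.character(window), length(window) == 1L)
  if (nchar(window) != 14L) stop("window must be exactly 14 nt")
  chars <- strsplit(window, "", fixed = TRUE)[[1L]]
  if (any(!(chars %in% RNA_BASES))) stop("window must be over {A,C,G,U}")
  rows <- list()
  for (j in seq_len(14L)) {
    for (b in setdiff(RNA_BASES, chars[j])) {
      v <- chars
      v[j] <- b
      rows[[length(rows) + 1L]] <- data.frame(
        window_position = j, base = b,
        sequence = paste(v, collapse = ""), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Derive a cleavage consensus from saturation-mutagenesis rates
#'
#' Per position, the tolerated set is the wild-type base plus every
#' substitution whose relative cleavage rate is at least `theta` (wild type
#' = 1 by definition); the preferred base is the one with the maximal rate
#' (ties go to the wild type). Positions where all four bases are tolerated
#' are unconstrained and trimmed from the flanks when the consensus is
#' printed.
#'
#' @param records Data frame with `window_position` (1..14), `base`,
#'   `relative_rate` — all 42 single-substitution records must be present.
#' @param wild_type_window The 14-nt wild-type window.
#' @param theta Relative-rate threshold defining "tolerated" (default 0.5).
#' @param bond_position Window position 5' of the scissile bond (default 7).
#' @return A `consensus_spec`: `tolerated` (list of 14 base sets),
#'   `preferred` (14 bases), `bond_position`, `theta`, `wild_type_window`.
#' @export
derive_consensus <- function(records, wild_type_window, theta = 0.5,
                             bond_position = 7L) {
  stopifnot(is.data.frame(records),
            all(c("window_position", "base", "relative_rate") %in% names(records)))
  if (nchar(wild_type_window) != 14L) stop("wild-type window must be 14 nt")
  wt <- strsplit(wild_type_window, "", fixed = TRUE)[[1L]]
  want <- do.call(rbind, lapply(seq_len(14L), function(j)
    data.frame(window_position = j, base = setdiff(RNA_BASES, wt[j]),
               stringsAsFactors = FALSE)))
  key <- function(d) paste(d$window_position, d$base)
  absent <- setdiff(key(want), key(records))
  if (length(absent) > 0L) {
    stop(sprintf("missing variant record(s): %s",
                 paste(absent, collapse = "; ")))
  }
  tolerated <- vector("list", 14L)
  preferred <- character(14L)
  for (j in seq_len(14L)) {
    sub <- records[records$window_position == j, , drop = FALSE]
    rates <- stats::setNames(sub$relative_rate, sub$base)
    rates <- c(stats::setNames(1, wt[j]), rates)   # wild type first: wins ties
    tolerated[[j]] <- intersect(RNA_BASES, names(rates)[rates >= theta])
    if (!(wt[j] %in% tolerated[[j]])) tolerated[[j]] <- union(wt[j], tolerated[[j]])
    preferred[j] <- names(rates)[which.max(rates)]
  }
  structure(
    list(tolerated = tolerated, preferred = preferred,
         bond_position = as.integer(bond_position), theta = theta,
         wild_type_window = wild_type_window),
    class = "consensus_spec"
  )
}

#' Format a consensus spec the way nuclease consensus strings are printed
#'
#' Single-base positions print as the base, degenerate ones as a
#' slash-separated group with the preferred base first; fully unconstrained
#' flanking positions are trimmed; `^` marks the scissile bond.
#'
#' @param x A `consensus_spec`.
#' @param ... Unused.
#' @return A character string, e.g. `"(G/A/U)(A/U)CC^(U/A)(C/A/U)(G/A/U)"`.
#' @export
format.consensus_spec <- function(x, ...) {
  constrained <- vapply(x$tolerated, function(t) length(t) < 4L, logical(1L))
  if (!any(constrained)) return("^")
  first <- min(which(constrained))
  last <- max(which(constrained))
  token <- function(j) {
    t <- x$tolerated[[j]]
    if (length(t) == 1L) return(t)
    rest <- setdiff(t, x$preferred[j])
    paste0("(", paste(c(x$preferred[j], rest), collapse = "/"), ")")
  }
  left <- if (x$bond_position >= first)
    paste(vapply(first:min(last, x$bond_position), token, character(1L)),
          collapse = "") else ""
  right <- if (last > x$bond_position)
    paste(vapply(max(first, x$bond_position + 1L):last, token, character(1L)),
          collapse = "") else ""
  paste0(left, "^", right)
}

#' @export
print.consensus_spec <- function(x, ...) {
  cat(sprintf("<consensus_spec> %s (theta = %g)\n", format(x), x$theta))
  invisible(x)
}

#' Maximum achievable PWM log-odds score
#' @param pwm A `pwm` object or 4-row probability matrix.
#' @param background Background base probability (default uniform 0.25).
#' @return The score of the best-scoring word.
#' @export
pwm_max_score <- function(pwm, background = 0.25) {
  m <- if (inherits(pwm, "pwm")) pwm$matrix else pwm
  sum(apply(log2(m / background), 2L, max))
}

#' A log-odds score threshold as a fraction of the PWM maximum
#' @inheritParams pwm_max_score
#' @param fraction Fraction of the maximal achievable score (default 0.8).
#' @return Numeric threshold for [scan_duplex()].
#' @export
pwm_score_threshold <- function(pwm, fraction = 0.8, background = 0.25) {
  fraction * pwm_max_score(pwm, background)
}

.scan_strand <- function(strand_seq, motif, pwm_m, threshold, cut_offset) {
  L <- nchar(strand_seq)
  if (!is.null(motif)) {
    m <- gregexpr(paste0("(?=", .iupac_regex(motif$letters), ")"),
                  strand_seq, perl = TRUE)[[1L]]
    starts <- if (m[1L] == -1L) integer(0) else as.integer(m)
    data.frame(start = starts, score = rep(NA_real_, length(starts)))
  } else {
    w <- ncol(pwm_m)
    if (L < w) return(data.frame(start = integer(0), score = numeric(0)))
    lo <- log2(pwm_m / 0.25)
    chars <- match(strsplit(strand_seq, "", fixed = TRUE)[[1L]], RNA_BASES)
    starts <- seq_len(L - w + 1L)
    score <- vapply(starts, function(s)
      sum(lo[cbind(chars[s:(s + w - 1L)], seq_len(w))]), numeric(1L))
    keep <- score >= threshold
    data.frame(start = starts[keep], score = score[keep])
  }
}

#' Scan a duplex for motif or PWM matches on both strands
#'
#' Matches are sought on the top strand and on the bottom strand (the
#' reverse complement); a bottom-strand match at bottom bond `b` is
#' canonicalized to the top-strand bond `L - b + overhang`. Overlapping
#' matches are all reported.
#'
#' @param segment A [ds_segment()].
#' @param motif An [iupac_motif()] (with its `cut_offset`), or `NULL` if
#'   scanning with a PWM.
#' @param pwm A `pwm` object or 4-row probability matrix (PWM mode).
#' @param threshold Log-odds score threshold, required in PWM mode (see
#'   [pwm_score_threshold()] for the conventional 80%-of-maximum choice).
#' @param cut_offset Bond position within the PWM window (PWM mode; default
#'   half the width minus one, i.e. centred like a site window).
#' @param overhang Signed overhang for bottom-strand canonicalization
#'   (default 2).
#' @return Data frame: `segment_id`, `i_top`, `strand` (strand carrying the
#'   match), `match_start` (in that strand's own coordinates), `score`
#'   (log-odds; `NA` in motif mode), sorted by `i_top`.
#' @export
scan_duplex <- function(segment, motif = NULL, pwm = NULL, threshold = NULL,
                        cut_offset = NULL, overhang = 2L) {
  stopifnot(inherits(segment, "ds_segment"))
  if (is.null(motif) == is.null(pwm)) {
    stop("provide exactly one of 'motif' or 'pwm'")
  }
  pwm_m <- NULL
  if (!is.null(pwm)) {
    if (is.null(threshold)) {
      stop("PWM mode requires an explicit score threshold (see pwm_score_threshold())")
    }
    pwm_m <- if (inherits(pwm, "pwm")) pwm$matrix else pwm
    if (is.null(cut_offset)) cut_offset <- ncol(pwm_m) / 2L - 1L
  } else {
    stopifnot(inherits(motif, "iupac_motif"))
    cut_offset <- motif$cut_offset
  }
  L <- segment$length
  res <- list()
  top_hits <- .scan_strand(segment$top_sequence, motif, pwm_m, threshold,
                           cut_offset)
  if (nrow(top_hits) > 0L) {
    i <- top_hits$start + cut_offset - 1L
    keep <- i >= 1L & i <= L - 1L
    res$top <- data.frame(
      segment_id = segment$id, i_top = i[keep], strand = "top",
      match_start = top_hits$start[keep], score = top_hits$score[keep],
      stringsAsFactors = FALSE
    )
  }
  bot_hits <- .scan_strand(bottom_sequence(segment), motif, pwm_m, threshold,
                           cut_offset)
  if (nrow(bot_hits) > 0L) {
    b <- bot_hits$start + cut_offset - 1L
    i <- L - b + as.integer(overhang)
    keep <- b >= 1L & b <= L - 1L & i >= 1L & i <= L - 1L
    res$bottom <- data.frame(
      segment_id = segment$id, i_top = i[keep], strand = "bottom",
      match_start = bot_hits$start[keep], score = bot_hits$score[keep],
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(segment_id = character(0), i_top = integer(0),
               strand = character(0), match_start = integer(0),
               score = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$i_top, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' In-silico digestion of a duplex at given sites
#'
#' Products are the maximal uncut duplex spans between cuts. Each staggered
#' cut at top bond `i` severs the top strand after reference position `i`
#' and the bottom strand after reference position `i - overhang`, so the two
#' strands of a product differ in length by up to the overhang; the apparent
#' (gel) size of a product is taken as the longer strand's length.
#'
#' @param segment A [ds_segment()].
#' @param sites Integer vector of top-strand bond indices (or a data frame
#'   with an `i_top` column).
#' @param overhang Signed overhang; default 2.
#' @return Data frame, one row per product in coordinate order: `product`,
#'   `top_start`, `top_end`, `top_length`, `bottom_length`, `apparent_size`.
#' @export
insilico_digest <- function(segment, sites, overhang = 2L) {
  stopifnot(inherits(segment, "ds_segment"))
  if (is.data.frame(sites)) sites <- sites$i_top
  sites <- as.integer(sites)
  L <- segment$length
  if (anyDuplicated(sites)) stop("duplicate cut sites")
  lo <- max(1L, 1L + as.integer(overhang))
  if (any(sites < lo | sites > L - 1L)) {
    stop(sprintf("cut sites must lie in [%d, %d] for overhang %d",
                 lo, L - 1L, overhang))
  }
  sites <- sort(sites)
  top_b <- c(0L, sites, L)
  bot_b <- c(0L, sites - as.integer(overhang), L)
  n <- length(sites) + 1L
  out <- data.frame(
    product = seq_len(n),
    top_start = utils::head(top_b, -1L) + 1L,
    top_end = utils::tail(top_b, -1L),
    top_length = diff(top_b),
    bottom_length = diff(bot_b)
  )
  out$apparent_size <- pmax(out$top_length, out$bottom_length)
  out
}

#' Predicted gel banding of a digest
#'
#' Apparent product sizes at or above the visibility cutoff, sorted
#' descending (gel order), multiplicities preserved.
#'
#' @param products A data frame from [insilico_digest()].
#' @param min_visible Smallest visible product (nt); default 20.
#' @return Integer vector of apparent sizes, largest first.
#' @export
banding_table <- function(products, min_visible = 20L) {
  sizes <- products$apparent_size
  sort(sizes[sizes >= min_visible], decreasing = TRUE)
}
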