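# Synthetic-data generator: a three-segment bacteriophage-like dsRNA genome
# with a planted positional cleavage-preference model, first-order limited
# digestion, end-capture count tracks, kinetics time courses and
# saturation-mutagenesis rate tables — all with known ground truth.

#' Positional cleavage-preference model
#'
#' A 14-column table of per-position, per-base rate multipliers anchored to
#' the scissile bond (bond after window position 7). The default encodes an
#' obligate `ACC^U` core (window positions 5-8) with degenerate flanks: at
#' the CC core (positions 6-7) every substitution abolishes cleavage
#' (multiplier 0); other constrained positions carry multiplier 1 for
#' tolerated bases and `disallowed` otherwise.
#'
#' @param tolerated List of 14 character vectors of tolerated bases (default:
#'   `N N N (G/A/U) A C C U (C/A/U) (G/A/U) N N N N`, bond after position 7).
#' @param preferred Character vector of 14 preferred bases (used for
#'   planting); must each be tolerated.
#' @param disallowed Multiplier for non-tolerated bases at non-core positions.
#' @param core_positions Window positions where substitutions abolish
#'   cleavage entirely (multiplier 0).
#' @return A `preference_model`: 4 x 14 multiplier matrix (rows ACGU), plus
#'   `tolerated`, `preferred`, `bond_offset = 7`.
#' @export
preference_model <- function(tolerated = NULL, preferred = NULL,
                             disallowed = 0.05, core_positions = c(6L, 7L)) {
  N <- c("A", "C", "G", "U")
  if (is.null(tolerated)) {
    tolerated <- list(
      N, N, N,
      c("G", "A", "U"), "A", "C", "C", "U",
      c("C", "A", "U"), c("G", "A", "U"),
      N, N, N, N
    )
  }
  stopifnot(length(tolerated) == 14L)
  if (is.null(preferred)) {
    preferred <- vapply(tolerated, `[`, character(1L), 1L)
  }
  stopifnot(length(preferred) == 14L,
            all(mapply(function(p, t) p %in% t, preferred, tolerated)))
  mult <- matrix(disallowed, nrow = 4L, ncol = 14L,
                 dimnames = list(RNA_BASES, NULL))
  for (j in seq_len(14L)) {
    mult[tolerated[[j]], j] <- 1
    if (j %in% core_positions) {
      mult[, j] <- 0
      mult[tolerated[[j]], j] <- 1
    }
  }
  structure(
    list(multipliers = mult, tolerated = tolerated, preferred = preferred,
         bond_offset = 7L),
    class = "preference_model"
  )
}

#' Simulation configuration
#'
#' Defaults emulate the three-segment linear dsRNA genome of bacteriophage
#' phi6 (segment lengths 6374, 4063 and 2948 bp) subjected to a 10-minute
#' limited digest, end-capture sequenced to about 2e5 mapped fragment ends
#' with a 7% uniform-breakage background (the level seen in uncleaved
#' control libraries).
#'
#' @param segment_lengths Segment lengths in nt (each >= 100).
#' @param seed Integer seed; every random choice in the generator flows from
#'   it.
#' @param planted_model A [preference_model()].
#' @param planted_per_segment Number of preferred sites written into each
#'   segment (recycled); default scales with length (~1 per 500 nt).
#' @param k_s Specific first-order cleavage rate scale (per minute) for a
#'   site with multiplier product 1.
#' @param k_ns Nonspecific breakage rate (per bond per minute).
#' @param digestion_time Digestion time (minutes).
#' @param read_depth Expected total number of sampled fragment ends.
#' @param background_break_fraction Proportion of sampled ends arising from
#'   uniform random breakage rather than real fragment ends.
#' @param control_mode If `TRUE`, simulate an uncleaved library: only
#'   segment-terminal ends plus the uniform background.
#' @return A `sim_config` list.
#' @export
sim_config <- function(segment_lengths = c(6374L, 4063L, 2948L),
                       seed = 1L,
                       planted_model = preference_model(),
                       planted_per_segment = NULL,
                       k_s = 0.2,
                       k_ns = 1e-6,
                       digestion_time = 10,
                       read_depth = 2e5,
                       background_break_fraction = 0.07,
                       control_mode = FALSE) {
  stopifnot(all(segment_lengths >= 100L),
            k_s >= 0, k_ns >= 0, digestion_time >= 0, read_depth >= 1,
            background_break_fraction >= 0, background_break_fraction <= 1)
  if (is.null(planted_per_segment)) {
    planted_per_segment <- pmax(3L, round(segment_lengths / 500))
  }
  structure(
    list(
      segment_lengths = as.integer(segment_lengths),
      seed = as.integer(seed),
      planted_model = planted_model,
      planted_per_segment = as.integer(planted_per_segment),
      k_s = k_s, k_ns = k_ns, digestion_time = digestion_time,
      read_depth = read_depth,
      background_break_fraction = background_break_fraction,
      control_mode = isTRUE(control_mode)
    ),
    class = "sim_config"
  )
}

# multiplier product of the (possibly truncated) 14-window around bond i on
# the given strand sequence; windows are evaluated in the strand's own frame
.window_multiplier <- function(strand_seq, bond, model) {
  L <- nchar(strand_seq)
  prod <- 1
  for (j in seq_len(14L)) {
    pos <- bond - model$bond_offset + j
    if (pos < 1L || pos > L) next
    base <- substr(strand_seq, pos, pos)
    prod <- prod * model$multipliers[base, j]
  }
  prod
}

# scan a genome segment for core matches (ACC^U on either strand) and return
# canonical top-strand bonds with strand of the core and rate multipliers
.scan_truth <- function(segment, model, overhang = 2L) {
  top <- segment$top_sequence
  L <- segment$length
  core_top <- paste(vapply(5:8, function(j) model$tolerated[[j]],
                           character(1L)), collapse = "")  # "ACCU"
  core_bottom <- reverse_complement(core_top)              # "AGGU" on top strand
  find_all <- function(pat) {
    m <- gregexpr(paste0("(?=", pat, ")"), top, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m)
  }
  res <- list()
  for (p in find_all(core_top)) {
    i_top <- p + 2L
    if (i_top < 3L || i_top > L - 1L) next
    res[[length(res) + 1L]] <- data.frame(
      segment_id = segment$id, i_top = i_top, core_strand = "top",
      rate_multiplier = .window_multiplier(top, i_top, model),
      stringsAsFactors = FALSE
    )
  }
  bot <- bottom_sequence(segment)
  for (p in find_all(core_bottom)) {
    i_top <- p + 2L                 # canonical top bond of the duplex site
    if (i_top < 3L || i_top > L - 1L) next
    b <- L - i_top + overhang       # bottom bond; core sits on the bottom strand
    res[[length(res) + 1L]] <- data.frame(
      segment_id = segment$id, i_top = i_top, core_strand = "bottom",
      rate_multiplier = .window_multiplier(bot, b, model),
      stringsAsFactors = FALSE
    )
  }
  if (length(res) == 0L) {
    return(data.frame(segment_id = character(0), i_top = integer(0),
                      core_strand = character(0), rate_multiplier = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$i_top), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic segmented dsRNA genome with planted cleavage sites
#'
#' Sequences are uniform over `{A,C,G,U}` except at planted 14-nt windows,
#' which receive a site drawn from the preference model (preferred core,
#' random tolerated flanks). Ground truth is then obtained by scanning both
#' strands for the model's core (so chance occurrences of `ACC^U`/`AGGU` are
#' reported alongside the planted ones, with their window rate multipliers).
#'
#' @param config A [sim_config()].
#' @return A `sim_genome`: `segments` (named list of [ds_segment()]),
#'   `truth` (data frame: `segment_id`, `i_top`, `core_strand`,
#'   `rate_multiplier`), `planted` (data frame of planted positions), and the
#'   `config`.
#' @export
make_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  model <- config$planted_model
  n_seg <- length(config$segment_lengths)
  n_plant <- rep_len(config$planted_per_segment, n_seg)
  seg_ids <- c("L", "M", "S", paste0("seg", seq_len(max(0L, n_seg - 3L)) + 3L))[seq_len(n_seg)]
  segments <- vector("list", n_seg)
  planted <- list()
  for (s in seq_len(n_seg)) {
    L <- config$segment_lengths[s]
    chars <- sample(RNA_BASES, L, replace = TRUE)
    # choose non-overlapping planting windows well inside the segment
    if (n_plant[s] > 0L) {
      cand <- sample(seq(10L, L - 10L), size = min(10L * n_plant[s], L - 19L))
      chosen <- integer(0)
      for (i in cand) {
        if (length(chosen) >= n_plant[s]) break
        if (all(abs(i - chosen) >= 14L)) chosen <- c(chosen, i)
      }
      if (length(chosen) < n_plant[s]) {
        stop(sprintf("could not place %d non-overlapping sites in segment %s",
                     n_plant[s], seg_ids[s]))
      }
      for (i in sort(chosen)) {
        # window positions i-6 .. i+7 (bond after position 7 of the window)
        site <- vapply(seq_len(14L), function(j) {
          tol <- model$tolerated[[j]]
          if (length(tol) == 1L) tol else sample(tol, 1L)
        }, character(1L))
        chars[(i - 6L):(i + 7L)] <- site
        planted[[length(planted) + 1L]] <- data.frame(
          segment_id = seg_ids[s], i_top = i, stringsAsFactors = FALSE
        )
      }
    }
    segments[[s]] <- ds_segment(seg_ids[s], paste(chars, collapse = ""))
  }
  names(segments) <- seg_ids
  truth <- do.call(rbind, lapply(segments, .scan_truth, model = model))
  rownames(truth) <- NULL
  structure(
    list(
      segments = segments, truth = truth,
      planted = if (length(planted) > 0L) do.call(rbind, planted) else NULL,
      config = config
    ),
    class = "sim_genome"
  )
}

#' Simulate a time-limited digest of a synthetic genome
#'
#' Each ground-truth site `i` is cut independently with probability
#' `1 - exp(-k_s * m_i * t)` where `m_i` is its window multiplier product;
#' additionally every bond is cut nonspecifically with probability
#' `1 - exp(-k_ns * t)`. All cuts use the duplex geometry (top bond `i`,
#' bottom bond `L - i + overhang`), so per-strand fragments tile each
#' segment exactly.
#'
#' @param genome A [make_genome()] result.
#' @param config A [sim_config()]; defaults to the genome's own.
#' @param overhang Signed overhang; default 2.
#' @return A `fragment_set`: per segment, sorted cut bonds and per-strand
#'   fragment intervals in reference coordinates.
#' @export
simulate_limited_digest <- function(genome, config = genome$config,
                                    overhang = 2L) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)
  t <- config$digestion_time
  out <- lapply(genome$segments, function(seg) {
    L <- seg$length
    truth <- genome$truth[genome$truth$segment_id == seg$id, , drop = FALSE]
    p_cut <- 1 - exp(-config$k_s * truth$rate_multiplier * t)
    cuts <- truth$i_top[stats::runif(nrow(truth)) < p_cut]
    bonds <- seq(max(3L, 1L + overhang), L - 1L)    # bonds with valid geometry
    p_ns <- 1 - exp(-config$k_ns * t)
    if (p_ns > 0) cuts <- c(cuts, bonds[stats::runif(length(bonds)) < p_ns])
    cuts <- sort(unique(as.integer(cuts)))
    top_b <- c(0L, cuts, L)
    bot_cut <- cuts - as.integer(overhang)
    bot_b <- c(0L, bot_cut, L)
    list(
      segment_id = seg$id, length = L, cuts = cuts,
      top = cbind(start = utils::head(top_b, -1L) + 1L, end = utils::tail(top_b, -1L)),
      bottom = cbind(start = utils::head(bot_b, -1L) + 1L, end = utils::tail(bot_b, -1L))
    )
  })
  structure(list(segments = out, config = config, overhang = as.integer(overhang)),
            class = "fragment_set")
}

#' Simulate end-capture sequencing of a fragment population
#'
#' Samples fragment 3' ends to the configured expected depth: a top-strand
#' fragment ending at reference position p contributes to the top track at
#' p; a bottom-strand fragment whose 3'-terminal residue sits at reference
#' position q contributes to the bottom track at q. A configurable fraction
#' of reads comes from uniform random breakage. In `control_mode` only the
#' six segment-terminal ends (top at L, bottom at 1 per segment) exist. For
#' each sampled internal end an 8-nt end read is emitted: the reference
#' top-strand window `[bond - 4, bond + 3]` around the implied duplex bond,
#' placed so that the tetranucleotide straddling the scissile bond (3 nt 5'
#' + 1 nt 3' of it) sits centred in the read — which makes the read set
#' closed under reverse complement across site orientations. This emulates
#' post-mapping extraction of site-spanning tags rather than raw sequencer
#' output.
#'
#' @param fragments A [simulate_limited_digest()] result (ignored in
#'   `control_mode` apart from segment identities/lengths).
#' @param genome The [make_genome()] result (for read sequences).
#' @param config A [sim_config()]; defaults to the genome's own.
#' @return A `capture_set`: `tracks` (per segment, list with `top` and
#'   `bottom` [end_count_track()]s) and `reads` (character vector of 8-nt
#'   end reads, one per sampled end with a full window).
#' @export
simulate_end_capture <- function(fragments, genome, config = genome$config) {
  stopifnot(inherits(fragments, "fragment_set"), inherits(genome, "sim_genome"))
  set.seed(config$seed + 2L)
  overhang <- fragments$overhang
  seg_ids <- names(genome$segments)
  lens <- vapply(genome$segments, `[[`, integer(1L), "length")
  # enumerate candidate ends: (segment index, strand 1=top/2=bottom, position)
  ends <- list()
  for (s in seq_along(seg_ids)) {
    fr <- fragments$segments[[seg_ids[s]]]
    if (config$control_mode) {
      ends[[s]] <- rbind(c(s, 1L, lens[s]), c(s, 2L, 1L))
    } else {
      ends[[s]] <- rbind(
        cbind(s, 1L, fr$top[, "end"]),     # top-strand 3' ends (high coord)
        cbind(s, 2L, fr$bottom[, "start"]) # bottom-strand 3' ends (low coord)
      )
    }
  }
  ends <- do.call(rbind, ends)
  if (nrow(ends) == 0L) stop("empty fragment set: no ends to sample")
  depth <- round(config$read_depth)
  n_bg <- stats::rbinom(1L, depth, config$background_break_fraction)
  n_sig <- depth - n_bg
  picked <- ends[sample.int(nrow(ends), n_sig, replace = TRUE), , drop = FALSE]
  if (n_bg > 0L) {
    bg_seg <- sample.int(length(seg_ids), n_bg, replace = TRUE, prob = lens)
    bg <- cbind(
      bg_seg,
      sample(1:2, n_bg, replace = TRUE),
      vapply(bg_seg, function(s) sample.int(lens[s], 1L), integer(1L))
    )
    picked <- rbind(picked, bg)
  }
  tracks <- vector("list", length(seg_ids))
  names(tracks) <- seg_ids
  reads <- character(0)
  for (s in seq_along(seg_ids)) {
    L <- lens[s]
    sel <- picked[picked[, 1L] == s, , drop = FALSE]
    top_counts <- tabulate(sel[sel[, 2L] == 1L, 3L], nbins = L)
    bot_counts <- tabulate(sel[sel[, 2L] == 2L, 3L], nbins = L)
    tracks[[s]] <- list(
      top = end_count_track(seg_ids[s], "top", L, top_counts),
      bottom = end_count_track(seg_ids[s], "bottom", L, bot_counts)
    )
    # implied bond: top end at p -> bond p; bottom end at q -> bond q + 1
    bonds <- ifelse(sel[, 2L] == 1L, sel[, 3L], sel[, 3L] + 1L)
    ok <- bonds - 4L >= 1L & bonds + 3L <= L
    if (any(ok)) {
      topseq <- genome$segments[[s]]$top_sequence
      reads <- c(reads, substring(topseq, bonds[ok] - 4L, bonds[ok] + 3L))
    }
  }
  structure(list(tracks = tracks, reads = reads, config = config),
            class = "capture_set")
}

#' Simulate noisy cleavage time courses
#'
#' `fraction(t) = clamp(slope * t + N(0, noise_sd), 0, 1)` for each
#' substrate and time point.
#'
#' @param true_slopes Named numeric vector of per-substrate slopes
#'   (fraction cleaved per minute).
#' @param times Time points (minutes), default `c(15, 30, 45)`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @param enzyme_id,enzyme_amount Enzyme annotation carried into the table.
#' @return Data frame: `substrate_id`, `enzyme_id`, `enzyme_amount`,
#'   `time_min`, `fraction`.
#' @export
simulate_timecourse <- function(true_slopes, times = c(15, 30, 45),
                                noise_sd = 0, seed = 1L,
                                enzyme_id = "wt", enzyme_amount = 1) {
  stopifnot(!is.null(names(true_slopes)), all(true_slopes >= 0))
  set.seed(seed)
  rows <- lapply(names(true_slopes), function(id) {
    fr <- true_slopes[[id]] * times + stats::rnorm(length(times), 0, noise_sd)
    data.frame(
      substrate_id = id, enzyme_id = enzyme_id,
      enzyme_amount = enzyme_amount, time_min = times,
      fraction = pmin(1, pmax(0, fr)), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Simulate a saturation-mutagenesis relative-rate table
#'
#' Emits the full 42-record design (14 positions x 3 substitutions) for a
#' planted consensus: the wild-type window is the planted preferred base at
#' each position; tolerated non-wild-type substitutions get relative rate
#' 0.8, disallowed ones 0.05 (0 at obligate core positions where the
#' tolerated set is a single base within positions marked obligate), plus
#' Gaussian noise, floored at 0.
#'
#' @param tolerated List of 14 tolerated base sets.
#' @param preferred Character vector of 14 preferred (wild-type) bases.
#' @param core_positions Positions where disallowed substitutions rate 0.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List: `records` (data frame `window_position`, `base`,
#'   `relative_rate`), `wild_type_window` (14-nt string).
#' @export
simulate_satmut_rates <- function(tolerated, preferred = NULL,
                                  core_positions = integer(0),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(length(tolerated) == 14L)
  if (is.null(preferred)) preferred <- vapply(tolerated, `[`, character(1L), 1L)
  stopifnot(all(mapply(function(p, t) p %in% t, preferred, tolerated)))
  set.seed(seed)
  rows <- list()
  for (j in seq_len(14L)) {
    for (b in setdiff(RNA_BASES, preferred[j])) {
      rate <- if (b %in% tolerated[[j]]) 0.8
              else if (j %in% core_positions) 0 else 0.05
      rate <- max(0, rate + stats::rnorm(1L, 0, noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        window_position = j, base = b, relative_rate = rate,
        stringsAsFactors = FALSE
      )
    }
  }
  list(
    records = do.call(rbind, rows),
    wild_type_window = paste(preferred, collapse = "")
  )
}
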