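# Discriminative motif discovery from weighted cleavage-site windows.
#
# Two complementary routes, mirroring common practice for nuclease
# specificity mapping:
#   * a discriminative IUPAC word search: exact-word seeding from the
#     positive set, greedy one-position IUPAC generalization, one-sided
#     hypergeometric (Fisher) enrichment against a sliding-window genomic
#     background, with incremental width selection from 4 to 14 nt;
#   * a one-occurrence-per-sequence EM that refines a position weight matrix
#     from the most frequent unique end-proximal reads.

# two-base IUPAC codes, keyed by sorted base pair
IUPAC_PAIR <- c(AC = "M", AG = "R", AU = "W", CG = "S", CU = "Y", GU = "K")

# IUPAC letters whose base set strictly contains that of the named letter
.iupac_supersets <- local({
  out <- lapply(names(IUPAC_SETS), function(l) {
    s <- IUPAC_SETS[[l]]
    names(IUPAC_SETS)[vapply(IUPAC_SETS, function(t)
      all(s %in% t) && length(t) > length(s), logical(1L))]
  })
  names(out) <- names(IUPAC_SETS)
  out
})

#' Degenerate IUPAC motif
#'
#' @param letters Motif string over the RNA IUPAC alphabet.
#' @param cut_offset Position of the scissile bond within the motif: the
#'   bond lies after motif position `cut_offset` (`0` = before the motif).
#' @return An `iupac_motif`.
#' @export
iupac_motif <- function(letters, cut_offset = nchar(letters) - 1L) {
  stopifnot(is.character(letters), length(letters) == 1L)
  chars <- strsplit(letters, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% names(IUPAC_SETS)))
  if (length(bad) > 0L) {
    stop(sprintf("invalid IUPAC letter(s) at position(s) %s",
                 paste(bad, collapse = ", ")))
  }
  w <- length(chars)
  stopifnot(cut_offset >= 0L, cut_offset <= w)
  structure(list(letters = letters, width = w,
                 cut_offset = as.integer(cut_offset)),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  marked <- paste0(substr(x$letters, 1L, x$cut_offset), "^",
                   substr(x$letters, x$cut_offset + 1L, x$width))
  cat(sprintf("<iupac_motif> %s (width %d)\n", marked, x$width))
  invisible(x)
}

.iupac_regex <- function(letters) {
  chars <- strsplit(letters, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(l) {
    s <- IUPAC_SETS[[l]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

# logical: does each string contain a match of the motif (forward, and
# reverse complement when search_rc)?
.motif_hits <- function(letters, strings, search_rc = TRUE) {
  hit <- grepl(.iupac_regex(letters), strings, perl = TRUE)
  if (search_rc) {
    rc <- reverse_complement(letters, iupac = TRUE)
    if (!identical(rc, letters)) {
      hit <- hit | grepl(.iupac_regex(rc), strings, perl = TRUE)
    }
  }
  hit
}

.n_degenerate <- function(letters) {
  sum(!(strsplit(letters, "", fixed = TRUE)[[1L]] %in% RNA_BASES))
}

#' Upper tail of the hypergeometric distribution
#'
#' `P(X >= k)` for the number of successes in `K` draws without replacement
#' from a population of `N` containing `n` successes — the one-sided Fisher
#' enrichment probability used to rank motifs.
#'
#' @param k Observed successes among the draws.
#' @param K Number of draws (size of the positive set).
#' @param n Successes in the population.
#' @param N Population size.
#' @param log.p Return the natural log of the tail probability. Enrichment
#'   ranking uses the log scale throughout, since tail probabilities
#'   underflow to zero long before motifs become indistinguishable.
#' @return `P(X >= k)` (or its natural log).
#' @export
hypergeom_tail <- function(k, K, n, N, log.p = FALSE) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (k > K || k > n || K > N || n > N) {
    stop(sprintf("inconsistent counts: need 0 <= k <= min(K, n) <= N (got k=%d K=%d n=%d N=%d)",
                 k, K, n, N))
  }
  stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE, log.p = log.p)
}

#' Sliding-window background set from a genome
#'
#' All length-`width` top-strand windows, step 1, of every segment: the
#' negative set for discriminative enrichment. A segment of length L
#' contributes `L - width + 1` windows.
#'
#' @param segments A [ds_segment()] or list thereof (e.g.
#'   `make_genome()$segments`).
#' @param width Window width; default 14.
#' @return Character vector (multiset) of windows.
#' @export
build_background <- function(segments, width = 14L) {
  if (inherits(segments, "ds_segment")) segments <- list(segments)
  unlist(lapply(segments, function(seg) {
    L <- seg$length
    if (L < width) return(character(0))
    substring(seg$top_sequence, 1:(L - width + 1L), width:L)
  }), use.names = FALSE)
}

# weighted number of strings containing each w-mer (each string counted at
# most once per word); with rc = TRUE a string counts for a word if the word
# occurs in the string or in its reverse complement
.seed_hit_counts <- function(strings, weights, w, rc = TRUE) {
  keep <- nchar(strings) >= w
  strings <- strings[keep]
  weights <- weights[keep]
  if (length(strings) == 0L) return(numeric(0))
  per_string <- lapply(seq_along(strings), function(i) {
    s <- strings[i]
    subs <- substring(s, 1:(nchar(s) - w + 1L), w:nchar(s))
    if (rc) {
      r <- reverse_complement(s)
      subs <- c(subs, substring(r, 1:(nchar(r) - w + 1L), w:nchar(r)))
    }
    unique(subs)
  })
  seed <- unlist(per_string, use.names = FALSE)
  wts <- rep(weights, lengths(per_string))
  counts <- rowsum(wts, group = seed)
  stats::setNames(as.numeric(counts), rownames(counts))
}

.enrichment_row <- function(letters, pos_hits, pos_total, bg_hits, bg_total) {
  lp <- hypergeom_tail(pos_hits, pos_total,
                       pos_hits + bg_hits, pos_total + bg_total, log.p = TRUE)
  data.frame(
    motif = letters,
    width = nchar(letters),
    positive_hits = pos_hits, positive_total = pos_total,
    background_hits = bg_hits, background_total = bg_total,
    p_value = exp(lp),
    log_p_value = lp,
    fold_enrichment = (pos_hits / pos_total) /
      if (bg_hits > 0) (bg_hits / bg_total) else NA_real_,
    n_degenerate = .n_degenerate(letters),
    stringsAsFactors = FALSE
  )
}

.rank_results <- function(df) {
  df <- df[order(df$log_p_value, df$n_degenerate, df$motif), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Discriminative motif search at a fixed width
#'
#' Seeds with every exact `width`-mer present in the positive windows (hits
#' counted with the instance weights; a window counts once per word, in
#' forward or reverse-complement orientation when `search_rc`), ranks seeds
#' by one-sided hypergeometric enrichment against the background, then
#' greedily generalizes the best seeds one position at a time to degenerate
#' IUPAC letters (up to three-base codes; never `N`, since a wildcard
#' position carries no discriminative information and would let the width
#' search pad motifs trivially), accepting a generalization only if the
#' p-value strictly improves.
#'
#' When `search_rc` is on, each seed word is canonicalized to the
#' lexicographically smaller of itself and its reverse complement (the two
#' have identical two-strand hit counts).
#'
#' @param instances Character vector of positive windows (or the data frame
#'   from [weighted_instances()], whose `sequence` and `weight` columns are
#'   used). Windows shorter than `width` are ignored.
#' @param background Character vector from [build_background()].
#' @param width Motif width, in `[4, 14]`.
#' @param weights Integer weights (read counts) per instance; default 1.
#' @param search_rc Also search the reverse complement; default `TRUE`.
#' @param refine_top Number of top seeds to generalize (default 5).
#' @param max_results Rows returned (default 20).
#' @return An `enrichment_results` data frame ranked by p-value (ties: fewer
#'   degenerate letters, then lexicographic): `motif`, `width`,
#'   `positive_hits`, `positive_total`, `background_hits`,
#'   `background_total`, `p_value`, `log_p_value` (natural log; the ranking
#'   key), `fold_enrichment`, `n_degenerate`, `e_value`.
#' @export
discover_motif <- function(instances, background, width,
                           weights = NULL, search_rc = TRUE,
                           refine_top = 5L, max_results = 20L) {
  if (is.data.frame(instances)) {
    weights <- instances$weight
    instances <- instances$sequence
  }
  if (length(instances) == 0L) stop("positive set is empty")
  if (width < 4L || width > 14L) stop("width must be in [4, 14]")
  if (is.null(weights)) weights <- rep(1L, length(instances))
  stopifnot(length(weights) == length(instances), all(weights >= 0))

  usable <- nchar(instances) >= width
  pos <- instances[usable]
  pos_w <- weights[usable]
  if (length(pos) == 0L) stop(sprintf("no positive window is >= %d nt", width))
  pos_total <- sum(pos_w)
  bg_total <- length(background)

  seed_pos <- .seed_hit_counts(pos, pos_w, width, rc = search_rc)
  if (search_rc) {
    canon <- vapply(names(seed_pos), function(s)
      min(s, reverse_complement(s)), character(1L))
    seed_pos <- seed_pos[!duplicated(canon)]
    names(seed_pos) <- canon[!duplicated(canon)]
  }
  seed_bg_all <- .seed_hit_counts(background, rep(1L, bg_total), width,
                                  rc = search_rc)
  bg_of <- function(word) {
    keys <- if (search_rc) c(word, reverse_complement(word)) else word
    h <- seed_bg_all[keys]
    h <- h[!is.na(h)]
    if (length(h) == 0L) 0 else max(h)
  }

  rows <- lapply(names(seed_pos), function(word) {
    .enrichment_row(word, seed_pos[[word]], pos_total, bg_of(word), bg_total)
  })
  res <- .rank_results(do.call(rbind, rows))
  n_seeds <- nrow(res)

  # greedy IUPAC generalization of the top seeds
  refine <- utils::head(res$motif, refine_top)
  refined <- lapply(refine, function(word) {
    cur <- strsplit(word, "", fixed = TRUE)[[1L]]
    cur_row <- res[res$motif == word, , drop = FALSE][1L, ]
    repeat {
      best <- NULL
      for (j in seq_along(cur)) {
        # never generalize to N: a wildcard position carries no
        # discriminative information, and N-padded motifs would let the
        # incremental width search grow without ever paying for it —
        # an unconstrained position is expressed by a shorter width instead
        sups <- setdiff(.iupac_supersets[[cur[j]]], "N")
        for (l in sups) {
          cand <- cur
          cand[j] <- l
          cs <- paste(cand, collapse = "")
          k <- sum(pos_w[.motif_hits(cs, pos, search_rc)])
          b <- sum(.motif_hits(cs, background, search_rc))
          row <- .enrichment_row(cs, k, pos_total, b, bg_total)
          if (is.null(best) || row$log_p_value < best$log_p_value) best <- row
        }
      }
      if (!is.null(best) && best$log_p_value < cur_row$log_p_value) {
        cur_row <- best
        cur <- strsplit(best$motif, "", fixed = TRUE)[[1L]]
      } else break
    }
    cur_row
  })
  res <- .rank_results(rbind(do.call(rbind, refined),
                             res[!(res$motif %in% refine), , drop = FALSE]))
  res <- res[!duplicated(res$motif), , drop = FALSE]
  # E-value for context only: p times the number of seeds examined
  res$e_value <- res$p_value * n_seeds
  res <- utils::head(res, max_results)
  class(res) <- c("enrichment_results", "data.frame")
  res
}

#' Incremental motif-width selection
#'
#' Runs the discriminative search at each width in `w_range` and records,
#' for the best motif at each width, its weighted presence in the positive
#' set and the number of distinct exact words matching it (submotif
#' diversity). The chosen width is the largest `w` whose presence is at
#' least `tau_p` times the presence at the minimum width and whose
#' diversity is at least `tau_d` times the diversity at `w - 1` — i.e. the
#' longest motif that does not cause a dramatic drop in either quantity.
#'
#' @inheritParams discover_motif
#' @param w_range Widths to scan (default `4:14`).
#' @param tau_p Presence ratio threshold (default 0.5).
#' @param tau_d Diversity ratio threshold (default 0.5).
#' @return List: `width` (chosen), `trace` (data frame per width: `width`,
#'   `motif`, `p_value`, `presence`, `diversity`).
#' @export
select_width <- function(instances, background, w_range = 4:14,
                         weights = NULL, tau_p = 0.5, tau_d = 0.5,
                         search_rc = TRUE, refine_top = 3L) {
  if (is.data.frame(instances)) {
    weights <- instances$weight
    instances <- instances$sequence
  }
  if (length(instances) == 0L) stop("positive set is empty")
  if (is.null(weights)) weights <- rep(1L, length(instances))
  w_range <- sort(unique(as.integer(w_range)))
  rows <- list()
  for (w in w_range) {
    usable <- nchar(instances) >= w
    if (!any(usable)) break
    res <- discover_motif(instances[usable], background, w,
                          weights = weights[usable], search_rc = search_rc,
                          refine_top = refine_top, max_results = 1L)
    best <- res[1L, ]
    presence <- best$positive_hits / best$positive_total
    words <- names(.seed_hit_counts(instances[usable], weights[usable], w,
                                    rc = search_rc))
    diversity <- sum(.motif_hits(best$motif, words, search_rc))
    rows[[as.character(w)]] <- data.frame(
      width = w, motif = best$motif, p_value = best$p_value,
      presence = presence, diversity = diversity, stringsAsFactors = FALSE
    )
  }
  trace <- do.call(rbind, rows)
  rownames(trace) <- NULL
  ok <- logical(nrow(trace))
  for (r in seq_len(nrow(trace))) {
    p_ok <- trace$presence[r] >= tau_p * trace$presence[1L]
    d_ok <- if (r == 1L) TRUE else trace$diversity[r] >= tau_d * trace$diversity[r - 1L]
    ok[r] <- p_ok && d_ok
  }
  list(width = max(trace$width[ok]), trace = trace)
}

#' Most frequent unique reads
#'
#' Unique sequences ranked by count (descending; ties broken
#' lexicographically), first `n` returned — the classic "top 200 unique
#' reads" input for PWM refinement.
#'
#' @param reads Character vector of reads, or a data frame with `sequence`
#'   and `count` columns.
#' @param n Number of sequences to keep (default 200).
#' @return Data frame: `sequence`, `count`, count non-increasing.
#' @export
top_unique_reads <- function(reads, n = 200L) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("sequence", "count") %in% names(reads)))
    agg <- rowsum(as.numeric(reads$count), group = reads$sequence)
    df <- data.frame(sequence = rownames(agg), count = as.numeric(agg),
                     stringsAsFactors = FALSE)
  } else {
    tab <- table(reads)
    df <- data.frame(sequence = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, n)
}

#' One-occurrence-per-sequence EM refinement of a position weight matrix
#'
#' Fits a single motif of fixed width by expectation-maximisation: the
#' E-step computes, for every sequence, a posterior over the single motif
#' start position (motif columns versus a uniform 0.25 background
#' elsewhere); the M-step re-estimates the PWM from the posterior-weighted
#' base counts plus a pseudocount. The reported objective is the
#' pseudocount-penalised log-likelihood (log-likelihood plus the Dirichlet
#' smoothing term), which the EM guarantee makes non-decreasing across
#' iterations. Initialisation is from the most frequent exact word
#' (additional restarts jitter the start PWM; the best final likelihood is
#' kept).
#'
#' @param sequences Character vector (each at least `width` nt).
#' @param width Motif width; default 8.
#' @param weights Per-sequence multiplicities (read counts); default 1.
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood convergence tolerance.
#' @param seed Integer seed for restarts.
#' @param pseudocount Per-base pseudocount in the M-step (default 0.25).
#' @param restarts Number of EM restarts (default 5).
#' @param search_rc Let the E-step place the motif on either strand of each
#'   read (posterior over start position and orientation). On by default:
#'   genomic cleavage sites occur in both orientations, so an end-read pool
#'   is a mixture of a motif and its reverse complement.
#' @return A `pwm`: `matrix` (4 x width, rows ACGU, columns sum to 1),
#'   `ic` (per-column information content, bits), `loglik` (per-iteration
#'   trace of the penalised log-likelihood for the winning restart,
#'   non-decreasing), `consensus` (via [consensus_string()]), `width`,
#'   `pseudocount`.
#' @export
em_pwm <- function(sequences, width = 8L, weights = NULL, max_iter = 200L,
                   tol = 1e-6, seed = 1L, pseudocount = 0.25, restarts = 5L,
                   search_rc = TRUE) {
  if (is.data.frame(sequences)) {
    weights <- sequences$count
    sequences <- sequences$sequence
  }
  stopifnot(length(sequences) > 0L)
  if (is.null(weights)) weights <- rep(1, length(sequences))
  short <- which(nchar(sequences) < width)
  if (length(short) > 0L) {
    stop(sprintf("sequence %d ('%s') is shorter than the motif width %d",
                 short[1L], sequences[short[1L]], width))
  }
  enc <- lapply(strsplit(sequences, "", fixed = TRUE), function(ch) {
    code <- match(ch, RNA_BASES)
    if (anyNA(code)) stop("non-RNA character in EM input")
    code
  })
  lens <- lengths(enc)
  n_starts <- lens - width + 1L
  enc_rc <- lapply(enc, function(code) rev(5L - code))

  top_words <- top_unique_reads(
    unlist(lapply(seq_along(sequences), function(i) {
      s <- sequences[i]
      rep(substring(s, 1:(nchar(s) - width + 1L), width:nchar(s)),
          round(weights[i]))
    }), use.names = FALSE), n = 5L)

  init_pwm <- function(word, jitter) {
    code <- match(strsplit(word, "", fixed = TRUE)[[1L]], RNA_BASES)
    m <- matrix(0.1, nrow = 4L, ncol = width, dimnames = list(RNA_BASES, NULL))
    for (j in seq_len(width)) m[code[j], j] <- 0.7
    if (jitter > 0) {
      m <- m + matrix(stats::rgamma(4L * width, shape = jitter), nrow = 4L)
    }
    sweep(m, 2L, colSums(m), "/")
  }

  run_em <- function(pwm) {
    ll_trace <- numeric(0)
    repeat {
      logpwm <- log(pwm)
      counts <- matrix(0, nrow = 4L, ncol = width)
      ll <- 0
      for (i in seq_along(enc)) {
        S <- n_starts[i]
        strands <- if (search_rc) list(enc[[i]], enc_rc[[i]]) else list(enc[[i]])
        placements <- do.call(rbind, lapply(seq_along(strands), function(o) {
          cbind(orient = o, start = seq_len(S))
        }))
        logp <- vapply(seq_len(nrow(placements)), function(r) {
          x <- strands[[placements[r, "orient"]]]
          s <- placements[r, "start"]
          sum(logpwm[cbind(x[s:(s + width - 1L)], seq_len(width))])
        }, numeric(1L))
        mx <- max(logp)
        post <- exp(logp - mx)
        tot <- sum(post)
        post <- post / tot
        ll <- ll + weights[i] *
          (mx + log(tot) - log(nrow(placements)) +
             (lens[i] - width) * log(0.25))
        for (r in seq_len(nrow(placements))) {
          x <- strands[[placements[r, "orient"]]]
          s <- placements[r, "start"]
          idx <- cbind(x[s:(s + width - 1L)], seq_len(width))
          counts[idx] <- counts[idx] + weights[i] * post[r]
        }
      }
      # Dirichlet smoothing term: the objective the pseudocount M-step ascends
      ll_trace <- c(ll_trace, ll + pseudocount * sum(logpwm))
      k <- length(ll_trace)
      if (k >= 2L && abs(ll_trace[k] - ll_trace[k - 1L]) < tol) break
      if (k >= max_iter) break
      counts <- counts + pseudocount
      pwm <- sweep(counts, 2L, colSums(counts), "/")
    }
    list(pwm = pwm, loglik = ll_trace)
  }

  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    word <- top_words$sequence[min(r, nrow(top_words))]
    fit <- run_em(init_pwm(word, jitter = if (r == 1L) 0 else 0.3))
    if (is.null(best) ||
        utils::tail(fit$loglik, 1L) > utils::tail(best$loglik, 1L)) {
      best <- fit
    }
  }
  dimnames(best$pwm) <- list(RNA_BASES, NULL)
  p <- best$pwm
  ic <- apply(p, 2L, function(col) 2 + sum(ifelse(col > 0, col * log2(col), 0)))
  structure(
    list(matrix = p, ic = ic, loglik = best$loglik,
         consensus = consensus_string(p), width = as.integer(width),
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> width %d, consensus %s, total IC %.2f bits\n",
              x$width, x$consensus, sum(x$ic)))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Render a PWM column-wise as an IUPAC consensus string
#'
#' Per column: the single top base if its frequency is at least
#' `theta1` and at least twice the runner-up; the two-base IUPAC code if
#' the top two frequencies jointly reach `theta2`; otherwise `N`.
#'
#' @param pwm A `pwm` object or a 4-row probability matrix (rows ACGU).
#' @param theta1 Majority threshold (default 0.5).
#' @param theta2 Joint top-two threshold (default 0.8).
#' @return IUPAC consensus string.
#' @export
consensus_string <- function(pwm, theta1 = 0.5, theta2 = 0.8) {
  m <- if (inherits(pwm, "pwm")) pwm$matrix else pwm
  stopifnot(is.matrix(m), nrow(m) == 4L)
  if (is.null(rownames(m))) rownames(m) <- RNA_BASES
  letters <- vapply(seq_len(ncol(m)), function(j) {
    ord <- order(m[, j], decreasing = TRUE)
    p1 <- m[ord[1L], j]
    p2 <- m[ord[2L], j]
    if (p1 >= theta1 && p1 >= 2 * p2) {
      rownames(m)[ord[1L]]
    } else if (p1 + p2 >= theta2) {
      pair <- paste(sort(rownames(m)[ord[1:2]]), collapse = "")
      unname(IUPAC_PAIR[pair])
    } else "N"
  }, character(1L))
  paste(letters, collapse = "")
}
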