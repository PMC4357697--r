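# Fixtures built in code: small segments, hand-made genomes with known
# ground truth, and quick track constructors.

# an end-count track from a sparse position -> count spec
track_of <- function(segment_id, strand, length, ...) {
  pc <- list(...)
  counts <- integer(length)
  for (p in names(pc)) counts[as.integer(p)] <- pc[[p]]
  end_count_track(segment_id, strand, length, counts)
}

# a random RNA segment
random_segment <- function(id, length, seed) {
  set.seed(seed)
  ds_segment(id, paste(sample(c("A", "C", "G", "U"), length, replace = TRUE),
                       collapse = ""))
}

# a single-segment genome object with exactly the given core sites, built by
# hand so digestion tests have fully controlled ground truth
manual_genome <- function(top_sequence, sites, multipliers = 1,
                          config = sim_config(segment_lengths = 100L)) {
  seg <- ds_segment("S1", top_sequence)
  truth <- data.frame(
    segment_id = rep("S1", length(sites)), i_top = as.integer(sites),
    core_strand = rep("top", length(sites)),
    rate_multiplier = rep_len(multipliers, length(sites)),
    stringsAsFactors = FALSE
  )
  structure(list(segments = list(S1 = seg), truth = truth, planted = NULL,
                 config = config),
            class = "sim_genome")
}

# a sequence of given length with one planted ACCU core at bond i_top and no
# other ACCU/AGGU occurrence anywhere on either strand
single_site_sequence <- function(length, i_top, seed = 1) {
  set.seed(seed)
  repeat {
    chars <- sample(c("A", "C", "G", "U"), length, replace = TRUE)
    chars[(i_top - 2):(i_top + 1)] <- c("A", "C", "C", "U")
    s <- paste(chars, collapse = "")
    hits <- unlist(lapply(c("ACCU", "AGGU"), function(w)
      gregexpr(w, s, fixed = TRUE)[[1L]]))
    hits <- hits[hits > 0]
    if (identical(as.integer(hits), as.integer(i_top - 2L))) return(s)
  }
}

# brute-force hypergeometric tail by subset enumeration: population of N
# items of which the first n are successes; draw K; P(successes >= k)
enum_hypergeom_tail <- function(k, K, n, N) {
  if (K == 0) return(as.numeric(k <= 0))
  subsets <- utils::combn(N, K)
  mean(colSums(subsets <= n) >= k)
}
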