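# Discriminative motif discovery: enrichment statistics, background
# construction, width selection, top-read ranking, EM PWM refinement and
# consensus rendering.

test_that("hypergeometric tail matches hand-computed cases", {
  # (C(4,2)C(6,1) + C(4,3)C(6,0)) / C(10,3) = 40/120
  expect_equal(hypergeom_tail(2, 3, 4, 10), 1 / 3)
  expect_identical(hypergeom_tail(0, 3, 4, 10), 1)
  expect_equal(exp(hypergeom_tail(2, 3, 4, 10, log.p = TRUE)), 1 / 3)
  expect_error(hypergeom_tail(5, 3, 4, 10), "inconsistent")
  expect_error(hypergeom_tail(2, 3, 4, 3), "inconsistent")
  expect_error(hypergeom_tail(-1, 3, 4, 10), "non-negative")
})

test_that("background windows enumerate every sliding position", {
  seg <- random_segment("x", 20, seed = 1)
  bg <- build_background(seg, width = 14)
  expect_identical(length(bg), 7L)
  expect_identical(bg[1], substr(seg$top_sequence, 1, 14))
  expect_identical(bg[7], substr(seg$top_sequence, 7, 20))
  # the default phage-like genome: sum of L - 13 over segments
  g <- make_genome(sim_config(seed = 2))
  expect_identical(length(build_background(g$segments)),
                   6361L + 4050L + 2935L)
  # invariant under segment order
  expect_identical(sort(build_background(rev(g$segments))),
                   sort(build_background(g$segments)))
})

test_that("a positive set identical to the background is unenriched", {
  seg <- random_segment("x", 400, seed = 3)
  bg <- build_background(seg, width = 14)
  res <- discover_motif(bg, bg, width = 4, refine_top = 3)
  expect_gt(min(res$p_value), 0.05)
})

test_that("a single positive window yields its own word at background rarity", {
  seg <- random_segment("x", 300, seed = 4)
  bg <- build_background(seg, width = 10)
  win <- substr(seg$top_sequence, 101, 110)
  res <- discover_motif(win, bg, width = 10, search_rc = FALSE,
                        refine_top = 1)
  top <- res[1, ]
  expect_identical(top$motif, win)
  expect_identical(top$positive_hits, 1)
  # p equals the rarity of the word among all windows (positives pooled in)
  k <- sum(grepl(win, bg, fixed = TRUE))
  expect_equal(top$p_value,
               hypergeom_tail(1, 1, k + 1, length(bg) + 1))
})

test_that("doubling all weights doubles hits and preserves the ranking", {
  cfg <- sim_config(segment_lengths = 900L, seed = 5, planted_per_segment = 4L)
  g <- make_genome(cfg)
  fr <- simulate_limited_digest(g, cfg)
  cap <- simulate_end_capture(fr, g, cfg)
  sites <- call_sites(cap$tracks[[1]]$top, cap$tracks[[1]]$bottom)
  inst <- weighted_instances(sites, g$segments)
  bg <- build_background(g$segments)
  r1 <- discover_motif(inst$sequence, bg, width = 4, weights = inst$weight)
  r2 <- discover_motif(inst$sequence, bg, width = 4,
                       weights = 2L * inst$weight)
  m <- match(r1$motif, r2$motif)
  expect_false(anyNA(m))
  expect_identical(r2$positive_hits[m], 2 * r1$positive_hits)
  expect_identical(r2$motif[1], r1$motif[1])
})

test_that("the planted core is recovered from simulated digests", {
  cfg <- sim_config(seed = 41, background_break_fraction = 0.1,
                    read_depth = 5e4)
  g <- make_genome(cfg)
  fr <- simulate_limited_digest(g, cfg)
  cap <- simulate_end_capture(fr, g, cfg)
  sites <- do.call(rbind, lapply(cap$tracks, function(tr)
    call_sites(tr$top, tr$bottom)))
  inst <- weighted_instances(sites, g$segments)
  expect_gt(sum(inst$weight), 500)
  res <- discover_motif(inst, build_background(g$segments), width = 4)
  expect_true(res$motif[1] %in% c("ACCU", "AGGU"))
})

test_that("width selection keeps the longest motif without a dramatic drop", {
  seg <- random_segment("x", 400, seed = 6)
  bg <- build_background(seg, width = 14)
  # positives all equal to one exact 14-mer: no drop at any width
  word <- substr(seg$top_sequence, 41, 54)
  sel <- select_width(rep(word, 20), bg, search_rc = FALSE)
  expect_identical(sel$width, 14L)
  expect_true(all(sel$trace$presence == 1))
  expect_true(all(sel$trace$diversity == 1))
  # thresholds disabled: always the longest width
  sel0 <- select_width(rep(word, 20), bg, tau_p = 0, tau_d = 0,
                       search_rc = FALSE)
  expect_identical(sel0$width, 14L)
})

test_that("width selection stops where a short planted core dissolves", {
  # windows share only a 4-nt core at a fixed offset; flanks are random,
  # so presence and diversity collapse at longer widths
  set.seed(7)
  mk <- function() {
    chars <- sample(c("A", "C", "G", "U"), 14, replace = TRUE)
    chars[5:8] <- c("A", "C", "C", "U")
    paste(chars, collapse = "")
  }
  positives <- replicate(300, mk())
  bg <- build_background(random_segment("x", 3000, seed = 8), width = 14)
  sel <- select_width(positives, bg, refine_top = 2)
  expect_lte(sel$width, 6L)
  expect_identical(sel$trace$width, 4:14)
})

test_that("top unique reads are ranked by count with lexicographic ties", {
  set.seed(9)
  pool <- unique(replicate(600, paste(
    sample(c("A", "C", "G", "U"), 8, replace = TRUE), collapse = "")))[1:500]
  reads <- rep(pool, times = seq_along(pool))
  top <- top_unique_reads(reads, n = 200)
  expect_identical(nrow(top), 200L)
  expect_true(all(diff(top$count) <= 0))
  expect_identical(top$sequence[1], pool[500])
  # fewer unique inputs than n
  expect_identical(nrow(top_unique_reads(reads[1:10], n = 200)),
                   length(unique(reads[1:10])))
  # equal counts: lexicographically smaller first
  tied <- top_unique_reads(c("UUUUUUUU", "AAAAAAAA"), n = 2)
  expect_identical(tied$sequence, c("AAAAAAAA", "UUUUUUUU"))
  expect_identical(tied$count, c(1L, 1L))
})

test_that("EM on identical sequences converges to an indicator PWM", {
  p <- em_pwm(rep("ACCUGACU", 30), width = 8, seed = 1, restarts = 2)
  code <- match(strsplit("ACCUGACU", "")[[1]], c("A", "C", "G", "U"))
  for (j in 1:8) expect_gt(p$matrix[code[j], j], 0.9)
  expect_true(all(abs(colSums(p$matrix) - 1) < 1e-12))
  expect_true(all(p$ic >= 0 & p$ic <= 2 + 1e-12))
})

test_that("the EM objective is non-decreasing on random inputs", {
  set.seed(10)
  for (rep in 1:5) {
    seqs <- replicate(40, paste(
      sample(c("A", "C", "G", "U"), sample(8:12, 1), replace = TRUE),
      collapse = ""))
    p <- em_pwm(seqs, width = 6, seed = rep, restarts = 2)
    expect_true(all(diff(p$loglik) >= -1e-8))
  }
})

test_that("EM rejects sequences shorter than the motif width", {
  expect_error(em_pwm(c("ACCUGACU", "ACC"), width = 8), "'ACC'")
})

test_that("EM recovers the planted core from top end reads", {
  cfg <- sim_config(seed = 43, background_break_fraction = 0.1,
                    read_depth = 5e4)
  g <- make_genome(cfg)
  cap <- simulate_end_capture(simulate_limited_digest(g, cfg), g, cfg)
  top <- top_unique_reads(cap$reads, n = 200)
  p <- em_pwm(top, width = 8, seed = 1)
  expect_true(grepl("ACCU", p$consensus, fixed = TRUE) ||
                grepl("AGGU", p$consensus, fixed = TRUE))
})

test_that("consensus rendering follows the majority and pair rules", {
  col <- function(a, c, g, u) matrix(c(a, c, g, u), nrow = 4,
                                     dimnames = list(c("A", "C", "G", "U"), NULL))
  expect_identical(consensus_string(col(1, 0, 0, 0)), "A")
  expect_identical(consensus_string(col(0.45, 0.45, 0.05, 0.05)), "M")
  expect_identical(consensus_string(col(0.25, 0.25, 0.25, 0.25)), "N")
  # majority but not 2x the runner-up: falls through to the pair rule
  expect_identical(consensus_string(col(0.55, 0.40, 0.03, 0.02)), "M")
  expect_identical(consensus_string(cbind(col(1, 0, 0, 0), col(0, 0, 0, 1))),
                   "AU")
})
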