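# Synthetic genome, limited digest, end capture: ground-truth contracts,
# tiling invariants, determinism, and the control-library statistic.

test_that("the default preset emits the three phage-like segments", {
  g <- make_genome(sim_config(seed = 1))
  expect_identical(vapply(g$segments, `[[`, integer(1), "length"),
                   c(L = 6374L, M = 4063L, S = 2948L))
  expect_true(all(nchar(vapply(g$segments, `[[`, character(1), "top_sequence"))
                  == c(6374L, 4063L, 2948L)))
})

test_that("planted sites appear in ground truth with multiplier 1", {
  cfg <- sim_config(segment_lengths = c(800L, 500L), seed = 11,
                    planted_per_segment = c(4L, 2L))
  g <- make_genome(cfg)
  expect_identical(nrow(g$planted), 6L)
  key <- function(d) paste(d$segment_id, d$i_top)
  hit <- match(key(g$planted), key(g$truth))
  expect_false(anyNA(hit))
  expect_true(all(g$truth$rate_multiplier[hit] == 1))
})

test_that("chance core occurrences match the binomial expectation", {
  # expected ACCU count on one strand of N uniform nt is (N - 3) / 256
  N <- 5000L
  counts <- vapply(1:12, function(s) {
    g <- make_genome(sim_config(segment_lengths = N, seed = 100 + s,
                                planted_per_segment = 0L))
    sum(g$truth$core_strand == "top")
  }, integer(1))
  expected <- (N - 3) / 256
  se <- sqrt(expected / 12)   # near-Poisson occurrence counts
  expect_lt(abs(mean(counts) - expected), 4 * se)
})

test_that("digestion limits behave as the rate law dictates", {
  seq1 <- single_site_sequence(100, 50, seed = 5)
  cfg0 <- sim_config(segment_lengths = 100L, seed = 2, k_s = 0, k_ns = 0)
  g <- manual_genome(seq1, sites = 50, config = cfg0)
  # no activity: fragments are the intact segment on both strands
  fr0 <- simulate_limited_digest(g, cfg0)
  expect_identical(fr0$segments$S1$cuts, integer(0))
  expect_identical(unname(fr0$segments$S1$top[1, ]), c(1L, 100L))
  expect_identical(unname(fr0$segments$S1$bottom[1, ]), c(1L, 100L))
  # saturating specific cleavage, no background: exactly two duplex products
  cfg1 <- sim_config(segment_lengths = 100L, seed = 2, k_s = 1e6, k_ns = 0)
  fr1 <- simulate_limited_digest(g, cfg1)
  expect_identical(fr1$segments$S1$cuts, 50L)
  expect_identical(nrow(fr1$segments$S1$top), 2L)
  expect_identical(nrow(fr1$segments$S1$bottom), 2L)
})

test_that("small-t cut fractions scale with the site multiplier", {
  # two sites with multipliers 1 and 0.38; at k_s * t = 0.05 the ratio of
  # cut fractions approaches the multiplier ratio (first-order regime)
  seqs <- single_site_sequence(200, 60, seed = 6)
  g <- manual_genome(seqs, sites = c(60, 140), multipliers = c(1, 0.38),
                     config = sim_config(segment_lengths = 200L))
  n_rep <- 10000
  cut1 <- 0; cut2 <- 0
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(segment_lengths = 200L, seed = r, k_s = 0.005,
                      k_ns = 0, digestion_time = 10)
    fr <- simulate_limited_digest(g, cfg)
    cut1 <- cut1 + (60 %in% fr$segments$S1$cuts)
    cut2 <- cut2 + (140 %in% fr$segments$S1$cuts)
  }
  # tolerance: ~3x the Monte-Carlo standard error of the ratio at this
  # depth, plus the small first-order bias of 1-exp(-kt)
  expect_lt(abs(cut2 / cut1 - 0.38), 0.1)
})

test_that("per-strand fragments tile each segment exactly", {
  g <- make_genome(sim_config(segment_lengths = c(1500L, 900L), seed = 3,
                              k_ns = 1e-3))
  fr <- simulate_limited_digest(g)
  for (s in fr$segments) {
    for (strand in c("top", "bottom")) {
      iv <- s[[strand]]
      expect_identical(unname(iv[1, "start"]), 1L)
      expect_identical(unname(iv[nrow(iv), "end"]), s$length)
      if (nrow(iv) > 1) {
        expect_identical(iv[-1, "start"], unname(iv[-nrow(iv), "end"]) + 1L)
      }
      expect_identical(sum(iv[, "end"] - iv[, "start"] + 1L), s$length)
    }
  }
})

test_that("every internal end corresponds to a recorded cut when background is zero", {
  cfg <- sim_config(segment_lengths = 1200L, seed = 9, k_s = 2,
                    background_break_fraction = 0, read_depth = 5000,
                    planted_per_segment = 3L)
  g <- make_genome(cfg)
  fr <- simulate_limited_digest(g, cfg)
  cap <- simulate_end_capture(fr, g, cfg)
  tr <- cap$tracks[[1]]
  L <- tr$top$length
  top_pos <- setdiff(which(tr$top$counts > 0), L)
  bot_pos <- setdiff(which(tr$bottom$counts > 0), 1L)
  cuts <- fr$segments[[1]]$cuts
  expect_true(all(top_pos %in% cuts))
  expect_true(all(bot_pos %in% (cuts - 1L)))
})

test_that("a single cut places ends at bond and bond-minus-one", {
  # one cut at top bond 14 of a 30-nt duplex: top 3' end at 14, bottom 3'
  # end at 13 (reference coordinates), plus the two segment termini
  s <- single_site_sequence(30, 14, seed = 8)
  cfg <- sim_config(segment_lengths = 100L, seed = 4, k_s = 1e6, k_ns = 0,
                    background_break_fraction = 0, read_depth = 400)
  g <- manual_genome(s, sites = 14, config = cfg)
  fr <- simulate_limited_digest(g, cfg)
  cap <- simulate_end_capture(fr, g, cfg)
  tr <- cap$tracks$S1
  expect_setequal(which(tr$top$counts > 0), c(14L, 30L))
  expect_setequal(which(tr$bottom$counts > 0), c(1L, 13L))
})

test_that("control libraries concentrate reads at segment termini", {
  cfg <- sim_config(seed = 21, control_mode = TRUE,
                    background_break_fraction = 0, read_depth = 2e4)
  g <- make_genome(cfg)
  fr <- simulate_limited_digest(g, cfg)
  cap <- simulate_end_capture(fr, g, cfg)
  expect_identical(terminus_fraction(cap$tracks), 1)
  # with a 7% uniform-breakage floor the terminus share is close to 93%
  cfg7 <- sim_config(seed = 22, control_mode = TRUE,
                     background_break_fraction = 0.07, read_depth = 2e5)
  g7 <- make_genome(cfg7)
  cap7 <- simulate_end_capture(simulate_limited_digest(g7, cfg7), g7, cfg7)
  expect_lt(abs(terminus_fraction(cap7$tracks) - 0.93), 0.01)
})

test_that("identical configurations give identical outputs", {
  cfg <- sim_config(segment_lengths = c(600L, 400L), seed = 17)
  a <- make_genome(cfg); b <- make_genome(cfg)
  expect_identical(a$segments, b$segments)
  expect_identical(a$truth, b$truth)
  fa <- simulate_limited_digest(a); fb <- simulate_limited_digest(b)
  expect_identical(fa$segments, fb$segments)
  ca <- simulate_end_capture(fa, a); cb <- simulate_end_capture(fb, b)
  expect_identical(lapply(ca$tracks, function(t) t$top$counts),
                   lapply(cb$tracks, function(t) t$top$counts))
  expect_identical(ca$reads, cb$reads)
})

test_that("noise-free time courses are exact lines", {
  tc <- simulate_timecourse(c(s = 0.01), times = c(15, 30, 45), noise_sd = 0)
  expect_equal(tc$fraction, c(0.15, 0.30, 0.45))
  tc0 <- simulate_timecourse(c(s = 0), times = c(15, 30, 45), noise_sd = 0)
  expect_identical(tc0$fraction, c(0, 0, 0))
  # fractions are clamped to [0, 1]
  tcb <- simulate_timecourse(c(s = 0.05), times = c(15, 30, 45), noise_sd = 0)
  expect_true(all(tcb$fraction <= 1))
})

test_that("saturation-mutagenesis tables encode the planted consensus", {
  model <- preference_model()
  sm <- simulate_satmut_rates(model$tolerated, model$preferred,
                              core_positions = c(6L, 7L), noise_sd = 0)
  expect_identical(nrow(sm$records), 42L)
  # CC-core substitutions are completely dead
  core <- sm$records$window_position %in% c(6L, 7L)
  expect_true(all(sm$records$relative_rate[core] == 0))
  # round trip: consensus derivation recovers the planted tolerated sets
  cs <- derive_consensus(sm$records, sm$wild_type_window)
  expect_identical(lapply(cs$tolerated, sort),
                   lapply(model$tolerated, sort))
  expect_identical(cs$preferred, model$preferred)
})
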