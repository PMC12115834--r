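test_that("take-off durations come from the annotated frame pair", {
  seqs <- escape_sequences(1:2, "g", 40, TRUE, c(100, 100), c(104.5, 118))
  expect_equal(takeoff_duration(seqs), c(4.5, 18))
  # frame-index annotation at 6000 Hz: 27 frames = 4.5 ms
  expect_equal(frames_to_ms(27, 6000), 4.5)
  no_off <- escape_sequences(1, "g", 40, FALSE, NA, NA)
  expect_error(takeoff_duration(no_off), "non-take-off")
  # inconsistent annotations are rejected at construction
  expect_error(escape_sequences(1, "g", 40, TRUE, 100, 99))
})

test_that("mode classification is monotone with the boundary assigned to long", {
  expect_equal(as.character(classify_mode(5)), "short")
  expect_equal(as.character(classify_mode(12)), "long")
  expect_equal(as.character(classify_mode(7)), "long") # tie rule
  d <- sort(runif(50, 1, 20))
  m <- classify_mode(d, 7)
  expect_true(all(diff(as.integer(m)) >= 0)) # monotone in duration
})

test_that("the mixture boundary recovers a known bimodal structure", {
  set.seed(101)
  dur <- c(rlnorm(1000, log(4), 0.15), rlnorm(1000, log(15), 0.25))
  b <- estimate_mode_boundary(dur)
  truth <- exp(oracle_mix_intersection(log(4), 0.15, 0.5, log(15), 0.25, 0.5))
  expect_equal(b$method, "mixture_intersection")
  expect_lt(abs(b$boundary_ms - truth), 0.5)
  # the package's intersection solver agrees with a dense-grid oracle run
  # on the *fitted* parameters
  f <- b$fit
  grid_root <- exp(oracle_mix_intersection(f$mean[1], f$sd[1], f$weight[1],
                                           f$mean[2], f$sd[2], f$weight[2]))
  expect_equal(b$boundary_ms, grid_root, tolerance = 1e-3)
})

test_that("near point masses give a boundary strictly between the modes", {
  set.seed(5)
  dur <- c(4 + rnorm(100, 0, 0.01), 15 + rnorm(100, 0, 0.01))
  b <- estimate_mode_boundary(dur)
  expect_gt(b$boundary_ms, 4)
  expect_lt(b$boundary_ms, 15)
})

test_that("unimodal samples are flagged instead of fitted", {
  set.seed(9)
  expect_error(estimate_mode_boundary(rlnorm(400, log(8), 0.2)),
               class = "loomstrike_unimodal_error")
  expect_error(estimate_mode_boundary(c(4, 15)), "at least")
})

test_that("take-off rate and short-mode percentage follow the counts", {
  set.seed(2)
  n <- 188
  took <- rep(c(TRUE, FALSE), c(160, 28))
  seqs <- escape_sequences(1:n, "g", 10, took,
                           ifelse(took, 100, NA), ifelse(took, 110, NA))
  tr <- takeoff_rate(seqs)
  expect_equal(round(tr$proportion, 3), 0.851)
  expect_true(tr$ci_lo <= tr$proportion && tr$proportion <= tr$ci_hi)
  z <- takeoff_rate(escape_sequences(1:20, "g", 10, FALSE, NA, NA))
  expect_equal(z$proportion, 0)
  expect_equal(z$ci_lo, 0)

  durs <- c(4, 5, 6, 8, 10)
  s2 <- escape_sequences(1:5, "g", 10, TRUE, 100, 100 + durs)
  expect_equal(short_mode_percentage(s2, 7)$proportion, 0.6)
  s3 <- escape_sequences(1:3, "g", 10, TRUE, 100, c(110, 112, 115))
  expect_equal(short_mode_percentage(s3, 7)$proportion, 0)
  s4 <- escape_sequences(1:3, "g", 10, FALSE, NA, NA)
  expect_error(short_mode_percentage(s4), "no take-offs")
})

test_that("silencing-shaped generators yield no short-mode take-offs", {
  seqs <- gen_ethograms(etho_gen_params(short_mode_weight = 0), n = 300,
                        genotype = "silenced", seed = 33)
  expect_equal(short_mode_percentage(seqs, 7)$proportion, 0)
})

test_that("timing summaries separate escape time but not reaction time when only the mode shifts", {
  # identical groups: t = 0, p = 1 on both quantities
  a <- gen_ethograms(etho_gen_params(), n = 40, seed = 12)
  ts_same <- timing_summaries(a, a)
  expect_equal(ts_same$reaction_time$t, 0)
  expect_equal(ts_same$reaction_time$p, 1)
  expect_equal(ts_same$escape_time$p, 1)

  # a 10-pooled-sd shift is overwhelmingly significant
  set.seed(77)
  b1 <- escape_sequences(1:30, "g1", 10, TRUE, rnorm(30, 100, 2),
                         rnorm(30, 110, 2))
  b2 <- escape_sequences(1:30, "g2", 10, TRUE, rnorm(30, 120, 2),
                         rnorm(30, 130, 2))
  ts_shift <- timing_summaries(b1, b2)
  expect_lt(ts_shift$reaction_time$p, 1e-6)

  # the silencing signature: same reaction-time distribution, short mode
  # removed -> escape time significant, reaction time not (matched n)
  ctrl <- gen_ethograms(etho_gen_params(short_mode_weight = 0.7), n = 80,
                        genotype = "control", seed = 21)
  sil <- gen_ethograms(etho_gen_params(short_mode_weight = 0), n = 29,
                       genotype = "silenced", seed = 22)
  ts <- timing_summaries(ctrl, sil, labels = c("control", "silenced"))
  expect_gt(ts$reaction_time$p, 0.05)
  expect_lt(ts$escape_time$p, 0.05)
})

test_that("reaction-time tests are calibrated under a null of equal genotypes", {
  set.seed(404)
  p_vals <- vapply(1:100, function(i) {
    a <- gen_ethograms(etho_gen_params(), n = 40, genotype = "a")
    b <- gen_ethograms(etho_gen_params(short_mode_weight = 0), n = 40,
                       genotype = "b")
    timing_summaries(a, b)$reaction_time$p
  }, numeric(1))
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("downsampling matches group sizes reproducibly", {
  a <- gen_ethograms(etho_gen_params(), n = 100, genotype = "a", seed = 1)
  b <- gen_ethograms(etho_gen_params(), n = 40, genotype = "b", seed = 2)
  pooled <- rbind(as.data.frame(a), as.data.frame(b))
  d1 <- downsample_to_match(pooled, seed = 3)
  d2 <- downsample_to_match(pooled, seed = 3)
  expect_identical(d1, d2)
  expect_equal(as.vector(table(d1$genotype)), c(40L, 40L))
})

test_that("ethogram CSVs round-trip through the reader", {
  seqs <- gen_ethograms(etho_gen_params(), n = 25, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(seqs), path, row.names = FALSE)
  back <- read_ethograms(path)
  expect_equal(back$legs_leave_ms, seqs$legs_leave_ms)
  write.csv(data.frame(fly_id = 1, genotype = "g"), path, row.names = FALSE)
  expect_error(read_ethograms(path), class = "loomstrike_format_error")
})
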