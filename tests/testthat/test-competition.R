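test_that("consumption indices follow the count formulas", {
  expect_equal(wcb(25, 25), 0)
  expect_equal(wcb(37, 0), 1)
  expect_equal(wcb(30, 10), 0.5)
  expect_equal(pci(60, 40), 0.2)
  expect_equal(pci(40, 40), 0)
  expect_equal(pci(0, 22), -1)
  expect_true(is.na(pci(0, 0))) # undefined, flagged not zeroed
  expect_error(pci(-1, 5), "non-negative")
})

test_that("indices are antisymmetric and bounded over count grids", {
  g <- expand.grid(a = 0:15, b = 0:15)
  g <- g[g$a + g$b > 0, ]
  v <- pci(g$a, g$b)
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(pci(g$b, g$a), -v)
  expect_equal(wcb(g$a, g$b), v) # same algebra, different group semantics
})

test_that("one-sample t matches closed form and handles degenerate input", {
  sym <- one_sample_t(c(-0.4, 0.4))
  expect_equal(sym$t, 0)
  expect_equal(sym$p, 1)
  x <- c(0.5, 0.5, 0.5, 0.5) + c(-2, -1, 1, 2) * 1e-4
  r <- one_sample_t(x)
  # closed-form oracle
  t_oracle <- mean(x) / (sd(x) / sqrt(4))
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_lt(r$p, 0.01)
  z <- one_sample_t(rep(0.3, 5))
  expect_true(z$zero_variance)
  expect_equal(z$p, 0)
  z0 <- one_sample_t(rep(0, 5))
  expect_equal(z0$p, 1)
  expect_error(one_sample_t(1), "at least 2")
})

test_that("a moderate effect is detected reliably at n = 8", {
  set.seed(314)
  rej <- vapply(1:1000, function(i) {
    one_sample_t(rnorm(8, 0.4, 0.2))$p < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("two-sample t uses the Student form and degenerate conventions", {
  x <- c(1, 2, 3, 4)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(6)
  a <- rnorm(4, 0, 1e-6)
  b <- 1 + rnorm(4, 0, 1e-6)
  expect_lt(two_sample_t(a, b)$p, 1e-10)
  # matches stats::t.test with var.equal = TRUE exactly
  set.seed(8)
  u <- rnorm(12); v <- rnorm(10, 0.3)
  expect_equal(two_sample_t(u, v)$p,
               t.test(u, v, var.equal = TRUE)$p.value)
  expect_equal(two_sample_t(u, v, var_equal = FALSE)$p,
               t.test(u, v)$p.value)
})

test_that("Wilson intervals match the p-hat oracle and bracket k/n", {
  expect_equal(unname(wilson_interval(5, 10)),
               oracle_wilson(5, 10), tolerance = 1e-12)
  expect_equal(round(unname(wilson_interval(5, 10)), 4), c(0.2366, 0.7634))
  expect_equal(unname(wilson_interval(0, 10)[1]), 0)
  expect_equal(unname(wilson_interval(10, 10)[2]), 1)
  # ~1e4 exhaustive (k, n) pairs: bounds in [0,1] and bracketing k/n
  pairs <- do.call(rbind, lapply(1:141, function(n)
    cbind(k = 0:n, n = n)))
  ci <- wilson_interval(pairs[, "k"], pairs[, "n"])
  p <- pairs[, "k"] / pairs[, "n"]
  expect_true(all(ci[, "lo"] >= 0 & ci[, "hi"] <= 1))
  expect_true(all(ci[, "lo"] <= p + 1e-12 & p <= ci[, "hi"] + 1e-12))
  expect_error(wilson_interval(5, 4), "k <= n")
})

test_that("empirical Wilson coverage matches exact enumeration", {
  set.seed(2024)
  for (p in c(0.1, 0.5, 0.9)) {
    k <- rbinom(1e4, 30, p)
    ci <- wilson_interval(k, 30)
    cover <- mean(ci[, "lo"] <= p & p <= ci[, "hi"])
    expect_equal(cover, oracle_wilson_coverage(30, p), tolerance = 0.01)
  }
})

test_that("index summaries exclude undefined trials and test against zero", {
  vals <- c(0.2, 0.4, 0.1, NA, 0.3)
  expect_message(s <- index_summary(vals), "1 trial")
  expect_equal(s$n_trials, 4)
  expect_equal(s$n_excluded, 1)
  expect_equal(s$mean, 0.25)
  expect_lt(s$p, 0.05)
})

test_that("speed-split escape proportions partition at the threshold", {
  sp <- c(0.1, 0.12, 0.2, 0.25, 0.3, 0.05)
  out <- c("escape", "escape", "escape", "capture", "escape", "escape")
  tab <- outcome_split_by_speed(sp, out, 0.167)
  expect_equal(tab$proportion[tab$side == "slow"], 1)
  expect_equal(tab$proportion[tab$side == "fast"], 2 / 3)
  expect_warning(
    empty <- outcome_split_by_speed(c(0.3, 0.4), c("escape", "capture"),
                                    0.167),
    "slow side")
  expect_true(is.na(empty$proportion[empty$side == "slow"]))

  # binomial generator truth: slow-attack capture probability 0 for one
  # group and 0.5 for the other shows up in the split proportions
  set.seed(55)
  n <- 200
  speeds <- runif(n, 0.05, 0.15)
  ctrl <- rep("escape", n)
  sil <- ifelse(runif(n) < 0.5, "capture", "escape")
  t_ctrl <- suppressWarnings(outcome_split_by_speed(speeds, ctrl, 0.167))
  t_sil <- suppressWarnings(outcome_split_by_speed(speeds, sil, 0.167))
  expect_equal(t_ctrl$proportion[t_ctrl$side == "slow"], 1)
  expect_equal(t_sil$proportion[t_sil$side == "slow"], 0.5,
               tolerance = 0.15)
})

test_that("the angle ANOVA flags only genuinely shifted groups", {
  set.seed(123)
  g <- rep(c("a", "b", "c", "d"), each = 12)
  x <- rnorm(48)
  x[g == "d"] <- x[g == "d"] + 5 # 5-sd shift in one group
  res <- angle_group_test(x, g)
  expect_lt(res$p, 1e-4)
  with_d <- grepl("d", res$tukey$comparison)
  expect_true(all(res$tukey$p_adj[with_d] < 0.01))
  expect_true(all(res$tukey$p_adj[!with_d] > 0.05))
  # duplicated identical groups: no between-group variance
  y <- rep(rnorm(10), 2)
  gy <- rep(c("u", "v"), each = 10)
  expect_lt(angle_group_test(y, gy)$f, 1e-20)
  expect_error(angle_group_test(1:5, c("a", "a", "a", "a", "b")),
               "at least 2 observations")
})

test_that("competition-trial CSVs parse with derived indices", {
  df <- data.frame(trial_id = c("t1", "t2"), group_a = "silenced",
                   group_b = "control", n_a_eaten = c(30, 0),
                   n_b_eaten = c(10, 0), match_type = "PCI")
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  out <- read_competition_trials(path)
  expect_equal(out$index, c(0.5, NA))
  df$match_type <- "XXX"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_competition_trials(path),
               class = "loomstrike_format_error")
})
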