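# Independent oracles, kept deliberately separate from the package's own
# code paths: different algebraic routes to the same quantities.

# looming law evaluated directly (degrees)
oracle_theta_deg <- function(rv_ms, t_ms) 2 * atan(rv_ms / t_ms) * 180 / pi

# retinal angular size via the half-angle sine route (not atan)
oracle_retinal_deg <- function(half_width, d) {
  2 * asin(half_width / sqrt(half_width^2 + d^2)) * 180 / pi
}

# Wilson bounds from the p-hat algebra (different arrangement than the
# package's count-based form)
oracle_wilson <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(centre - half, centre + half)
}

# exact Wilson coverage by enumerating the binomial support
oracle_wilson_coverage <- function(n, p, conf = 0.95) {
  covers <- vapply(0:n, function(k) {
    ci <- oracle_wilson(k, n, conf)
    ci[1] <= p && p <= ci[2]
  }, logical(1))
  sum(dbinom(0:n, n, p)[covers])
}

# weighted-normal intersection by dense grid search between the means
oracle_mix_intersection <- function(mu1, s1, w1, mu2, s2, w2,
                                    n_grid = 200001) {
  g <- seq(mu1, mu2, length.out = n_grid)
  d <- w1 * dnorm(g, mu1, s1) - w2 * dnorm(g, mu2, s2)
  i <- which(diff(sign(d)) != 0)[1]
  g[i]
}

# minimal straight-line trajectory builder: damselfly head runs from
# `from` to `to` (mm) over n frames, fly fixed at the origin
make_line_traj <- function(from, to, n = 50, frame_rate = 1000,
                           outcome = "capture") {
  head <- mapply(function(a, b) seq(a, b, length.out = n), from, to)
  tracked_trajectory(head, head + 25, matrix(0, n, 3),
                     frame_rate = frame_rate, outcome = outcome)
}
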