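#' Escape-sequence annotation table
#'
#' Per-fly take-off annotations from high-speed video of looming-evoked
#' escapes: whether the fly took off, the time the take-off sequence started
#' (first frame of wing raising — the *reaction time*) and the time it ended
#' (first frame the middle jumping legs left the ground — the *escape time*),
#' both in ms from stimulus onset.
#'
#' @param fly_id identifier per fly.
#' @param genotype genotype label.
#' @param rv_ms looming-stimulus size-to-speed ratio (ms) the fly saw.
#' @param took_off logical: did the fly leave the ground?
#' @param wing_raise_ms sequence start, ms from stimulus onset (NA if no
#'   take-off).
#' @param legs_leave_ms sequence end, ms from stimulus onset (NA if no
#'   take-off); must exceed `wing_raise_ms` for take-offs.
#' @param frame_rate annotation video frame rate, Hz (6000 for single-fly
#'   looming assays); stored as an attribute.
#' @return A validated data frame of class `escape_sequences`.
#' @export
escape_sequences <- function(fly_id, genotype, rv_ms, took_off,
                             wing_raise_ms, legs_leave_ms, frame_rate = 6000) {
  df <- data.frame(fly_id = as.character(fly_id),
                   genotype = as.character(genotype),
                   rv_ms = as.numeric(rv_ms),
                   took_off = as.logical(took_off),
                   wing_raise_ms = as.numeric(wing_raise_ms),
                   legs_leave_ms = as.numeric(legs_leave_ms))
  bad <- df$took_off & (!is.finite(df$wing_raise_ms) |
                          !is.finite(df$legs_leave_ms) |
                          df$legs_leave_ms <= df$wing_raise_ms)
  if (any(bad)) {
    stop(sprintf("%d take-off rows lack legs_leave_ms > wing_raise_ms >= 0",
                 sum(bad)))
  }
  if (any(df$wing_raise_ms < 0, na.rm = TRUE)) {
    stop("times must be non-negative (ms from stimulus onset)")
  }
  attr(df, "frame_rate") <- frame_rate
  class(df) <- c("escape_sequences", "data.frame")
  df
}

#' Read an ethogram CSV
#'
#' Expects columns `fly_id,genotype,rv_ms,took_off,wing_raise_ms,legs_leave_ms`.
#'
#' @param path CSV path.
#' @param frame_rate annotation frame rate, Hz.
#' @return An [escape_sequences()] table.
#' @export
read_ethograms <- function(path, frame_rate = 6000) {
  df <- utils::read.csv(path)
  need <- c("fly_id", "genotype", "rv_ms", "took_off", "wing_raise_ms",
            "legs_leave_ms")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop_domain(sprintf("missing columns: %s", paste(absent, collapse = ", ")),
                "loomstrike_format_error")
  }
  escape_sequences(df$fly_id, df$genotype, df$rv_ms, df$took_off,
                   df$wing_raise_ms, df$legs_leave_ms, frame_rate = frame_rate)
}

#' Take-off sequence duration
#'
#' Time from the start of wing raising to the moment the tarsi lose ground
#' contact, per take-off.
#'
#' @param seqs an [escape_sequences()] table; every row must be a take-off.
#' @return Durations in ms (strictly positive).
#' @export
takeoff_duration <- function(seqs) {
  stopifnot(is.data.frame(seqs))
  if (any(!seqs$took_off)) {
    stop("duration is undefined for non-take-off sequences; subset to took_off rows")
  }
  seqs$legs_leave_ms - seqs$wing_raise_ms
}

#' Convert annotation frame counts to ms
#'
#' @param frames number of frames.
#' @param frame_rate frames per second.
#' @return Time in ms.
#' @export
frames_to_ms <- function(frames, frame_rate) frames / frame_rate * 1000

#' Classify a take-off as short or long mode
#'
#' Take-offs split into two motor programmes by sequence duration: a fast,
#' giant-fibre-driven *short* mode and a slower *long* mode. A duration below
#' the boundary is short; a duration at or above it is long (the boundary
#' itself is assigned to long, which is conservative for short-mode claims).
#'
#' @param duration take-off duration(s), ms.
#' @param boundary mode boundary in ms (default 7), or a [mode_boundary()]
#'   object.
#' @return Factor with levels `short`, `long`.
#' @export
classify_mode <- function(duration, boundary = 7) {
  if (inherits(boundary, "mode_boundary")) boundary <- boundary$boundary_ms
  stopifnot(is.numeric(duration), all(duration > 0), boundary > 0)
  factor(ifelse(duration < boundary, "short", "long"),
         levels = c("short", "long"))
}

#' Mode boundary object
#'
#' @param boundary_ms boundary between short and long mode, ms.
#' @param method `"fixed"` or `"mixture_intersection"`.
#' @param fit optional fit diagnostics.
#' @return An object of class `mode_boundary`.
#' @export
mode_boundary <- function(boundary_ms, method = c("fixed", "mixture_intersection"),
                          fit = NULL) {
  method <- match.arg(method)
  stopifnot(boundary_ms > 0)
  structure(list(boundary_ms = boundary_ms, method = method, fit = fit),
            class = "mode_boundary")
}

#' @export
print.mode_boundary <- function(x, ...) {
  cat(sprintf("Mode boundary: %.2f ms (%s)\n", x$boundary_ms, x$method))
  if (!is.null(x$fit)) {
    cat(sprintf("  mixture on log-duration: means %.2f / %.2f ms, sds %.3f / %.3f, weights %.2f / %.2f\n",
                exp(x$fit$mean[1]), exp(x$fit$mean[2]),
                x$fit$sd[1], x$fit$sd[2], x$fit$weight[1], x$fit$weight[2]))
  }
  invisible(x)
}

#' Estimate the short/long mode boundary from durations
#'
#' Fits a two-component Gaussian mixture to log take-off durations (durations
#' are positive and right-skewed) and returns the point between the component
#' means where the posterior responsibilities are equal — the intersection of
#' the two weighted mode distributions. A sample the mixture cannot separate
#' (one-component fit preferred by BIC, merged means, or a vanishing
#' component) raises an error carrying the condition class
#' `loomstrike_unimodal_error`.
#'
#' @param durations take-off durations, ms; at least `min_n` values.
#' @param min_n minimum sample size for a trustworthy fit.
#' @return A [mode_boundary()] with `method = "mixture_intersection"` and fit
#'   diagnostics (component means/sds/weights on the log scale, log-likelihood
#'   and BIC values).
#' @importFrom mclust Mclust mclustBIC
#' @export
estimate_mode_boundary <- function(durations, min_n = 30) {
  stopifnot(is.numeric(durations), all(durations > 0))
  if (length(durations) < min_n) {
    stop(sprintf("need at least %d durations (got %d)", min_n,
                 length(durations)))
  }
  x <- log(durations)
  fit2 <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  fit1 <- Mclust(x, G = 1, modelNames = "X", verbose = FALSE)
  if (is.null(fit2)) {
    stop_domain("two-component mixture fit failed", "loomstrike_unimodal_error")
  }
  mu <- as.numeric(fit2$parameters$mean)
  sig <- sqrt(as.numeric(fit2$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- as.numeric(fit2$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  if (!is.null(fit1) && fit1$bic >= fit2$bic) {
    stop_domain("sample looks unimodal (one-component fit preferred)",
                "loomstrike_unimodal_error")
  }
  if (diff(mu) < 1e-6 || min(w) < 0.02) {
    stop_domain("degenerate mixture fit (merged or vanishing component)",
                "loomstrike_unimodal_error")
  }
  # posterior-equality point: w1 N(x; mu1, s1) = w2 N(x; mu2, s2) between means
  logdiff <- function(z) {
    stats::dnorm(z, mu[1], sig[1], log = TRUE) + log(w[1]) -
      stats::dnorm(z, mu[2], sig[2], log = TRUE) - log(w[2])
  }
  if (logdiff(mu[1]) <= 0 || logdiff(mu[2]) >= 0) {
    stop_domain("mixture components overlap too much for an intersection",
                "loomstrike_unimodal_error")
  }
  root <- stats::uniroot(logdiff, lower = mu[1], upper = mu[2],
                         tol = 1e-12)$root
  mode_boundary(exp(root), method = "mixture_intersection",
                fit = list(mean = mu, sd = sig, weight = w,
                           loglik = fit2$loglik, bic_2 = fit2$bic,
                           bic_1 = if (is.null(fit1)) NA_real_ else fit1$bic,
                           n = length(durations)))
}

#' Take-off rate with Wilson confidence interval
#'
#' @param seqs an [escape_sequences()] table.
#' @param conf confidence level.
#' @return List with `proportion`, `k`, `n`, `ci_lo`, `ci_hi`.
#' @export
takeoff_rate <- function(seqs, conf = 0.95) {
  stopifnot(is.data.frame(seqs), nrow(seqs) > 0)
  k <- sum(seqs$took_off)
  n <- nrow(seqs)
  ci <- unname(wilson_interval(k, n, conf))
  list(proportion = k / n, k = k, n = n, ci_lo = ci[1], ci_hi = ci[2])
}

#' Percentage of take-offs that were short mode
#'
#' @param seqs an [escape_sequences()] table.
#' @param boundary mode boundary, ms (or a [mode_boundary()]).
#' @param conf confidence level for the Wilson interval.
#' @return List with `proportion` (short take-offs / take-offs), `k`, `n`,
#'   `ci_lo`, `ci_hi`.
#' @export
short_mode_percentage <- function(seqs, boundary = 7, conf = 0.95) {
  stopifnot(is.data.frame(seqs))
  off <- seqs[seqs$took_off, , drop = FALSE]
  if (nrow(off) == 0) stop("no take-offs: short-mode percentage undefined")
  modes <- classify_mode(takeoff_duration(off), boundary)
  k <- sum(modes == "short")
  n <- nrow(off)
  ci <- unname(wilson_interval(k, n, conf))
  list(proportion = k / n, k = k, n = n, ci_lo = ci[1], ci_hi = ci[2])
}

summarise_timing <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(x), mean = mean(x), median = q[2], q25 = q[1], q75 = q[3],
       iqr = q[3] - q[1])
}

#' Reaction-time and escape-time comparison between two groups
#'
#' The *reaction time* is the latency from stimulus onset to the start of
#' the take-off sequence (wing raise); the *escape time* is the latency to
#' its end (legs leave the ground). For each quantity, per-group medians,
#' interquartile ranges and means are reported together with a two-sample
#' Student t-test between groups. Only take-offs contribute.
#'
#' @param group_a,group_b [escape_sequences()] tables (one group each).
#' @param labels character(2) group labels.
#' @param var_equal use the equal-variance Student form (default) or Welch.
#' @return A list of class `timing_summaries` with elements `reaction_time`
#'   and `escape_time`, each holding per-group summaries and `t`, `df`, `p`.
#' @export
timing_summaries <- function(group_a, group_b, labels = c("A", "B"),
                             var_equal = TRUE) {
  a <- group_a[group_a$took_off, , drop = FALSE]
  b <- group_b[group_b$took_off, , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) stop("each group needs at least 2 take-offs")
  one <- function(col) {
    xa <- a[[col]]; xb <- b[[col]]
    tt <- two_sample_t(xa, xb, var_equal = var_equal)
    out <- list(summarise_timing(xa), summarise_timing(xb))
    names(out) <- labels
    c(out, tt)
  }
  structure(list(reaction_time = one("wing_raise_ms"),
                 escape_time = one("legs_leave_ms"),
                 labels = labels),
            class = "timing_summaries")
}

#' @export
print.timing_summaries <- function(x, ...) {
  for (q in c("reaction_time", "escape_time")) {
    s <- x[[q]]
    cat(sprintf("%s: t = %.3f, p = %.4g\n", q, s$t, s$p))
    for (lab in x$labels) {
      g <- s[[lab]]
      cat(sprintf("  %s: n = %d, median %.1f ms (IQR %.1f-%.1f), mean %.1f ms\n",
                  lab, g$n, g$median, g$q25, g$q75, g$mean))
    }
  }
  invisible(x)
}

#' Randomly downsample the larger of two groups to match the smaller
#'
#' Pooling utility used to avoid biasing pooled histograms toward the larger
#' group: rows are removed from the larger group at random until the group
#' sizes match.
#'
#' @param seqs an [escape_sequences()] table.
#' @param group_col column defining the two groups.
#' @param seed RNG seed.
#' @return The downsampled table.
#' @export
downsample_to_match <- function(seqs, group_col = "genotype", seed = 1) {
  g <- seqs[[group_col]]
  tab <- table(g)
  if (length(tab) != 2) stop("need exactly two groups")
  n_min <- min(tab)
  set.seed(seed)
  keep <- unlist(lapply(names(tab), function(lv) {
    idx <- which(g == lv)
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  }))
  seqs[sort(keep), , drop = FALSE]
}
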