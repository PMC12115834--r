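#' Wing clipping bias index
#'
#' `WCB = (left eaten - right eaten) / (left eaten + right eaten)` for a
#' competition trial in which left- and right-wing-clipped flies of the same
#' genotype competed. 0 means no bias; +1 (-1) means only left-clipped
#' (right-clipped) flies were consumed. A trial with no flies eaten has an
#' undefined index and returns NA (callers exclude and log such trials).
#'
#' @param left_eaten,right_eaten non-negative eaten counts. Vectorised.
#' @return Index values in `[-1, 1]`, NA where the total is zero.
#' @export
wcb <- function(left_eaten, right_eaten) {
  consumption_index(left_eaten, right_eaten)
}

#' Prey consumption index
#'
#' `PCI = (silenced eaten - control eaten) / (silenced eaten + control
#' eaten)` for a trial competing giant-fibre-silenced flies against
#' driver-only controls. Positive values mean silenced flies were eaten
#' preferentially.
#'
#' @param silenced_eaten,control_eaten non-negative eaten counts. Vectorised.
#' @return Index values in `[-1, 1]`, NA where the total is zero.
#' @export
pci <- function(silenced_eaten, control_eaten) {
  consumption_index(silenced_eaten, control_eaten)
}

consumption_index <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("eaten counts must be non-negative")
  }
  total <- a + b
  ifelse(total > 0, (a - b) / total, NA_real_)
}

#' One-sample Student t-test
#'
#' Tests whether the mean of `values` differs from `mu0` (two-sided).
#' Degenerate zero-variance samples follow the documented conventions: all
#' values equal to `mu0` gives t = 0, p = 1; all equal to some other value
#' gives p = 0 with a `zero_variance` flag.
#'
#' @param values numeric, at least 2 finite values.
#' @param mu0 null mean.
#' @return List with `t`, `df`, `p`, `mean`, `sem`, `n`, `zero_variance`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  if (stats::sd(values) == 0) {
    hit <- isTRUE(all.equal(mean(values), mu0))
    return(list(t = if (hit) 0 else Inf * sign(mean(values) - mu0),
                df = n - 1, p = if (hit) 1 else 0,
                mean = mean(values), sem = 0, n = n, zero_variance = TRUE))
  }
  tt <- stats::t.test(values, mu = mu0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n,
       zero_variance = FALSE)
}

#' Two-sample t-test
#'
#' Student (equal-variance) form by default, matching classical reporting;
#' Welch's unequal-variance form via `var_equal = FALSE`.
#'
#' @param a,b numeric samples, each with at least 2 values.
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b, var_equal = TRUE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs at least 2 values")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (same) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p = if (same) 1 else 0,
                mean_a = mean(a), mean_b = mean(b)))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

#' Wilson score interval for a binomial proportion
#'
#' @param k successes, `0 <= k <= n`. Vectorised over `k` and `n`.
#' @param n trials, at least 1.
#' @param conf confidence level.
#' @return For scalar input, `c(lo, hi)`; for vector input a two-column
#'   matrix. Bounds always bracket `k/n` and lie in `[0, 1]`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(is.numeric(k), is.numeric(n), conf > 0, conf < 1)
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    stop("need 0 <= k <= n with n >= 1")
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- n + z^2
  centre <- (k + z^2 / 2) / denom
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / denom
  lo <- pmax(0, centre - half)
  hi <- pmin(1, centre + half)
  if (length(lo) == 1) c(lo = lo, hi = hi) else cbind(lo = lo, hi = hi)
}

#' Summarise per-trial index values against zero
#'
#' Excludes undefined (NA) trial indices with a message, then reports the
#' mean, s.e.m. and a one-sample Student t-test against zero — the standard
#' question for a consumption index being whether predation was biased
#' toward one group.
#'
#' @param values per-trial index values (from [wcb()] or [pci()]).
#' @param mu0 null value (0 = no bias).
#' @return List of class `index_summary`: `values`, `mean`, `sem`,
#'   `n_trials`, `n_excluded`, `t`, `df`, `p`.
#' @export
index_summary <- function(values, mu0 = 0) {
  n_excl <- sum(is.na(values))
  if (n_excl > 0) {
    message(sprintf("%d trial(s) with undefined index excluded", n_excl))
  }
  v <- values[!is.na(values)]
  tt <- one_sample_t(v, mu0)
  structure(list(values = v, mean = tt$mean, sem = tt$sem,
                 n_trials = tt$n, n_excluded = n_excl,
                 t = tt$t, df = tt$df, p = tt$p),
            class = "index_summary")
}

#' @export
print.index_summary <- function(x, ...) {
  cat(sprintf(
    "Index summary: mean %.3f +/- %.3f s.e.m. (n = %d trials%s), one-sample t = %.3f, p = %.4g\n",
    x$mean, x$sem, x$n_trials,
    if (x$n_excluded) sprintf(", %d excluded", x$n_excluded) else "",
    x$t, x$p))
  invisible(x)
}

#' Escape proportions for slow versus fast attacks
#'
#' Partitions predation events at a peak-speed threshold (events strictly
#' below are "slow", the rest "fast") and reports the escape proportion with
#' a Wilson confidence interval on each side.
#'
#' @param peak_speed per-event damselfly peak attack speed, m/s.
#' @param outcome per-event outcome, `"escape"` or `"capture"`.
#' @param threshold split threshold, m/s (e.g. the grand-mean attack speed of
#'   a dataset).
#' @param conf confidence level.
#' @return Data frame with one row per side (`slow`, `fast`): `n`,
#'   `n_escaped`, `proportion`, `ci_lo`, `ci_hi` (NA, with a warning, for an
#'   empty side).
#' @export
outcome_split_by_speed <- function(peak_speed, outcome, threshold,
                                   conf = 0.95) {
  stopifnot(length(peak_speed) == length(outcome), is.numeric(threshold))
  outcome <- as.character(outcome)
  stopifnot(all(outcome %in% c("escape", "capture")))
  side <- ifelse(peak_speed < threshold, "slow", "fast")
  out <- lapply(c("slow", "fast"), function(s) {
    idx <- side == s
    n <- sum(idx)
    if (n == 0) {
      warning(sprintf("no events on the %s side of %g m/s", s, threshold))
      return(data.frame(side = s, n = 0L, n_escaped = 0L,
                        proportion = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_))
    }
    k <- sum(outcome[idx] == "escape")
    ci <- wilson_interval(k, n, conf)
    data.frame(side = s, n = n, n_escaped = k, proportion = k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  do.call(rbind, out)
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Omnibus test for differences among group means (e.g. mean attack
#' elevation/azimuth angles across genotype-by-outcome groups) followed by
#' all pairwise Tukey honest-significant-difference comparisons.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor); at least 2 groups with at
#'   least 2 observations each.
#' @param conf family-wise confidence level for Tukey intervals.
#' @return List of class `angle_group_test`: `f`, `df1`, `df2`, `p`, and
#'   `tukey` (data frame with `comparison`, `diff`, `lo`, `hi`, `p_adj`).
#' @export
angle_group_test <- function(values, groups, conf = 0.95) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 observations")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = conf)$g
  structure(
    list(f = an[["F value"]][1], df1 = an[["Df"]][1], df2 = an[["Df"]][2],
         p = an[["Pr(>F)"]][1],
         tukey = data.frame(comparison = rownames(tk),
                            diff = tk[, "diff"], lo = tk[, "lwr"],
                            hi = tk[, "upr"], p_adj = tk[, "p adj"],
                            row.names = NULL)),
    class = "angle_group_test"
  )
}

#' @export
print.angle_group_test <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f, x$p))
  print(x$tukey, digits = 4)
  invisible(x)
}

#' Read a competition-trial CSV
#'
#' Expects columns
#' `trial_id,group_a,group_b,n_a_eaten,n_b_eaten,match_type` with
#' `match_type` in `WCB`/`PCI` (for a WCB row, group a = left-clipped, group
#' b = right-clipped; for a PCI row, group a = silenced, group b = control).
#'
#' @param path CSV path.
#' @return Data frame with an added `index` column.
#' @export
read_competition_trials <- function(path) {
  df <- utils::read.csv(path)
  need <- c("trial_id", "group_a", "group_b", "n_a_eaten", "n_b_eaten",
            "match_type")
  absent <- setdiff(need, names(df))
  if (length(absent)) {
    stop_domain(sprintf("missing columns: %s", paste(absent, collapse = ", ")),
                "loomstrike_format_error")
  }
  if (!all(df$match_type %in% c("WCB", "PCI"))) {
    stop_domain("match_type must be WCB or PCI", "loomstrike_format_error")
  }
  df$index <- consumption_index(df$n_a_eaten, df$n_b_eaten)
  df
}
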