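#' Virtual looming stimulus
#'
#' A looming stimulus mimics a dark object of radius `r` approaching at
#' constant velocity `v`. Its expansion profile on the eye is fully
#' characterised by the size-to-speed ratio `r/v` (in ms): a large object
#' approaching quickly has the same expansion time course as a small object
#' approaching slowly if the two share `r/v` and the same onset size. The
#' angular size subtended at time `t` before (virtual) contact is
#' `theta(t) = 2 * atan((r/v) / t)`.
#'
#' @param r_over_v size-to-speed ratio of the virtual object, in ms. Must be
#'   positive. Conventional values: 10 (fast-looming) and 40 (slow-looming).
#' @param theta_onset angular size (degrees) at stimulus onset; the disk is
#'   displayed at this size when the stimulus starts.
#' @param theta_max fixed final angular size (degrees) at which expansion
#'   stops. Must satisfy `0 < theta_onset < theta_max <= 180`.
#' @param onset_time experiment-clock time (ms) of stimulus onset.
#' @return An object of class `loom_stimulus`.
#' @examples
#' stim <- loom_stimulus(40)
#' angular_size(stim, 40) # 90 degrees: the disk subtends 90 deg 40 ms out
#' @export
loom_stimulus <- function(r_over_v, theta_onset = 10, theta_max = 90,
                          onset_time = 0) {
  stopifnot(is.numeric(r_over_v), length(r_over_v) == 1, is.finite(r_over_v))
  if (r_over_v <= 0) stop_domain("r_over_v must be > 0", "loomstrike_domain_error")
  if (!(theta_onset > 0 && theta_onset < theta_max && theta_max <= 180)) {
    stop_domain("need 0 < theta_onset < theta_max <= 180",
                "loomstrike_domain_error")
  }
  structure(
    list(r_over_v = as.numeric(r_over_v),
         theta_onset = as.numeric(theta_onset),
         theta_max = as.numeric(theta_max),
         onset_time = as.numeric(onset_time)),
    class = "loom_stimulus"
  )
}

#' @export
print.loom_stimulus <- function(x, ...) {
  cat(sprintf(
    "Looming stimulus: r/v = %g ms, %g deg (onset) -> %g deg (final), onset at t = %g ms\n",
    x$r_over_v, x$theta_onset, x$theta_max, x$onset_time))
  cat(sprintf("  virtual contact %.1f ms after onset\n",
              time_to_reach(x, x$theta_onset)))
  invisible(x)
}

#' Angular size of a looming stimulus before contact
#'
#' Evaluates `theta(t) = 2 * atan((r/v) / t)` for `t` strictly before virtual
#' contact, clipped to the stimulus' displayed range
#' `[theta_onset, theta_max]` (the disk appears at the onset size and stops
#' expanding at the final size).
#'
#' @param stim a [loom_stimulus()].
#' @param t_before_contact time before virtual contact, ms; strictly positive.
#'   Vectorised.
#' @return Angular size in degrees, in `(0, theta_max]`; monotonically
#'   non-increasing in `t_before_contact`.
#' @export
angular_size <- function(stim, t_before_contact) {
  stopifnot(inherits(stim, "loom_stimulus"), is.numeric(t_before_contact))
  if (any(!is.finite(t_before_contact)) || any(t_before_contact <= 0)) {
    stop_domain("t_before_contact must be > 0 (contact already reached)",
                "loomstrike_domain_error")
  }
  theta <- 2 * rad2deg(atan(stim$r_over_v / t_before_contact))
  pmin(pmax(theta, stim$theta_onset), stim$theta_max)
}

#' Time before contact at which a given angular size is reached
#'
#' Inverse of the looming law: `t = (r/v) / tan(theta / 2)`.
#'
#' @param stim a [loom_stimulus()].
#' @param theta angular size in degrees, strictly inside `(0, 180)`.
#'   Vectorised.
#' @return Time before virtual contact, in ms.
#' @export
time_to_reach <- function(stim, theta) {
  stopifnot(inherits(stim, "loom_stimulus"), is.numeric(theta))
  if (any(!is.finite(theta)) || any(theta <= 0) || any(theta >= 180)) {
    stop_domain("theta must lie strictly in (0, 180) degrees",
                "loomstrike_domain_error")
  }
  stim$r_over_v / tan(deg2rad(theta) / 2)
}

#' Theoretical time-of-contact on the experiment clock
#'
#' The hypothetical moment the virtual object would touch the fly: stimulus
#' onset plus the time the looming law takes to go from the onset size to
#' contact.
#'
#' @param stim a [loom_stimulus()].
#' @return Contact time in ms on the experiment clock
#'   (`onset_time + (r/v)/tan(theta_onset/2)`).
#' @export
theoretical_contact_time <- function(stim) {
  stopifnot(inherits(stim, "loom_stimulus"))
  stim$onset_time + time_to_reach(stim, stim$theta_onset)
}

#' Tabulate a looming expansion profile
#'
#' @param stim a [loom_stimulus()].
#' @param dt time step in ms.
#' @return A data frame with `t_ms` (time since onset), `countdown_ms` (time
#'   remaining before virtual contact) and `theta_deg`.
#' @export
loom_profile <- function(stim, dt = 1) {
  stopifnot(inherits(stim, "loom_stimulus"), dt > 0)
  t_contact <- time_to_reach(stim, stim$theta_onset)
  t_ms <- seq(0, t_contact - dt, by = dt)
  countdown <- t_contact - t_ms
  data.frame(t_ms = t_ms + stim$onset_time - stim$onset_time,
             countdown_ms = countdown,
             theta_deg = angular_size(stim, countdown))
}

#' Fraction of flies that took off before the theoretical contact time
#'
#' For a set of escape sequences recorded under one looming stimulus, the
#' likelihood that flies left the ground before the hypothetical
#' time-of-contact with the virtual object.
#'
#' @param seqs an escape-sequence table (see [escape_sequences()]); escape
#'   times (`legs_leave_ms`) must be on the same clock as `stim`.
#' @param stim a [loom_stimulus()].
#' @param denominator `"responders"` (take-offs only; errors if none) or
#'   `"all"` (all flies; non-responders count as not escaped).
#' @return A list with `value` (proportion in `[0, 1]`), `n_before`,
#'   `n_denominator`, `denominator` and `contact_time_ms`.
#' @export
fraction_escaped_before_contact <- function(seqs, stim,
                                            denominator = c("responders", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(stim, "loom_stimulus"), is.data.frame(seqs))
  if (nrow(seqs) == 0) stop("empty escape-sequence table")
  contact <- theoretical_contact_time(stim)
  took <- as.logical(seqs$took_off)
  before <- took & seqs$legs_leave_ms < contact
  n_den <- if (denominator == "responders") sum(took) else nrow(seqs)
  if (n_den == 0) {
    stop_domain("no responders: cannot form responders-denominator proportion",
                "loomstrike_empty_denominator")
  }
  list(value = sum(before, na.rm = TRUE) / n_den,
       n_before = sum(before, na.rm = TRUE),
       n_denominator = n_den,
       denominator = denominator,
       contact_time_ms = contact)
}
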