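#' Position-smoothing parameters
#'
#' Parameters for the two-stage position filter applied to each component
#' axis of a digitized trajectory: a zero-phase (forward-backward)
#' Butterworth low-pass followed by a Savitzky-Golay polynomial smoother.
#' Defaults suit 1 kHz high-speed video of insect-scale flight: strike
#' dynamics live well below the cutoff while frame-to-frame digitization
#' jitter is attenuated.
#'
#' @param butterworth_order filter order (applied forward and backward, so the
#'   effective attenuation is doubled).
#' @param butterworth_cutoff low-pass cutoff frequency, Hz; must be below the
#'   Nyquist frequency of the trajectory it is applied to.
#' @param savgol_window Savitzky-Golay window length in frames; odd and
#'   greater than `savgol_polyorder`.
#' @param savgol_polyorder Savitzky-Golay polynomial order.
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(butterworth_order = 2, butterworth_cutoff = 30,
                             savgol_window = 11, savgol_polyorder = 3) {
  if (savgol_window %% 2 != 1) stop("savgol_window must be odd")
  if (savgol_window <= savgol_polyorder) {
    stop("savgol_window must exceed savgol_polyorder")
  }
  if (butterworth_order < 1 || butterworth_cutoff <= 0) {
    stop("invalid Butterworth parameters")
  }
  structure(list(butterworth_order = as.integer(butterworth_order),
                 butterworth_cutoff = butterworth_cutoff,
                 savgol_window = as.integer(savgol_window),
                 savgol_polyorder = as.integer(savgol_polyorder)),
            class = "smoothing_params")
}

#' @export
print.smoothing_params <- function(x, ...) {
  cat(sprintf(
    "Smoothing: Butterworth order %d @ %g Hz (zero phase) + Savitzky-Golay window %d, order %d\n",
    x$butterworth_order, x$butterworth_cutoff, x$savgol_window,
    x$savgol_polyorder))
  invisible(x)
}

# Zero-phase Butterworth, applied to the residual around the line through
# the series' endpoints, with odd-reflection end padding. filtfilt's zero
# initial conditions otherwise leave a transient proportional to the signal
# magnitude, so filtering the detrended residual makes constants and linear
# ramps pass through exactly and keeps boundary transients negligible.
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  line <- x[1] + (x[n] - x[1]) / (n - 1) * (seq_len(n) - 1)
  r <- x - line
  pad <- min(n - 1L, 100L)
  left <- 2 * r[1] - r[seq(pad + 1L, 2L)]
  right <- 2 * r[n] - r[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(left, r, right))
  y[seq(pad + 1L, pad + n)] + line
}

# Linear interpolation across interior NA runs of length <= max_gap.
# Returns the filled series plus the lengths of any runs left unfilled.
fill_short_gaps <- function(x, max_gap) {
  idx_na <- is.na(x)
  if (!any(idx_na)) return(list(x = x, long_runs = integer(0)))
  r <- rle(idx_na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_runs <- integer(0)
  for (k in which(r$values)) {
    run <- starts[k]:ends[k]
    interior <- starts[k] > 1L && ends[k] < length(x)
    if (interior && r$lengths[k] <= max_gap) {
      x[run] <- stats::approx(x = c(starts[k] - 1L, ends[k] + 1L),
                              y = x[c(starts[k] - 1L, ends[k] + 1L)],
                              xout = run)$y
    } else {
      long_runs <- c(long_runs, r$lengths[k])
    }
  }
  list(x = x, long_runs = long_runs)
}

#' Smooth trajectory positions
#'
#' Applies the two-stage filter of [smoothing_params()] independently to each
#' component axis (x, y, z) of each labelled point series. Interior gaps of at
#' most `max_gap` frames are linearly interpolated first; a longer (or edge)
#' gap cannot be bridged reliably, so the event is truncated to its longest
#' gap-free segment containing the end frame, with a warning.
#'
#' @param traj a [tracked_trajectory()].
#' @param params a [smoothing_params()]; cutoff must be below
#'   `traj$frame_rate / 2`.
#' @param max_gap largest interior gap (frames) bridged by linear
#'   interpolation.
#' @return A `tracked_trajectory` of the same length (or the truncated
#'   segment) with filtered positions and `smoothed = TRUE`.
#' @export
smooth_positions <- function(traj, params = smoothing_params(), max_gap = 5) {
  stopifnot(inherits(traj, "tracked_trajectory"),
            inherits(params, "smoothing_params"))
  if (params$butterworth_cutoff >= traj$frame_rate / 2) {
    stop("butterworth_cutoff must be below the Nyquist frequency")
  }
  pts <- traj$points
  any_long <- FALSE
  for (lab in names(pts)) {
    for (j in 1:3) {
      filled <- fill_short_gaps(pts[[lab]][, j], max_gap)
      pts[[lab]][, j] <- filled$x
      if (length(filled$long_runs)) any_long <- TRUE
    }
  }
  keep <- seq_len(n_frames(traj))
  if (any_long) {
    ok <- !Reduce(`|`, lapply(pts, function(m) apply(is.na(m), 1, any)))
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs <- which(r$values)
    containing <- segs[starts[segs] <= traj$end_frame &
                         ends[segs] >= traj$end_frame]
    if (length(containing) == 0) {
      # end frame itself is missing: fall back to the longest clean segment
      containing <- segs[which.max(r$lengths[segs])]
    }
    keep <- starts[containing]:ends[containing]
    warning(sprintf(
      "gap longer than %d frames: event truncated to frames %d-%d",
      max_gap, min(keep), max(keep)))
    pts <- lapply(pts, function(m) m[keep, , drop = FALSE])
  }
  n <- length(keep)
  if (n < params$savgol_window) {
    stop("trajectory shorter than the Savitzky-Golay window")
  }
  bf <- signal::butter(params$butterworth_order,
                       params$butterworth_cutoff / (traj$frame_rate / 2),
                       type = "low")
  for (lab in names(pts)) {
    for (j in 1:3) {
      x <- filtfilt_padded(bf, pts[[lab]][, j])
      pts[[lab]][, j] <- signal::sgolayfilt(x, p = params$savgol_polyorder,
                                            n = params$savgol_window)
    }
  }
  out <- traj
  out$points <- pts
  out$times <- traj$times[keep]
  out$end_frame <- traj$end_frame - min(keep) + 1L
  out$gaps <- lapply(traj$gaps, function(g) {
    g <- intersect(g, keep)
    g - min(keep) + 1L
  })
  out$smoothed <- TRUE
  out
}
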