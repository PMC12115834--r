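central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Speed and scalar acceleration from positions
#'
#' Differentiates per-frame positions (mm) with central differences
#' (one-sided at the boundaries). Speed is the Euclidean norm of the velocity
#' vector; acceleration is the time derivative of that scalar speed — the
#' along-path acceleration familiar from attack-kinematics panels — rather
#' than the magnitude of the vector acceleration.
#'
#' @param positions numeric matrix, one row per frame, columns x/y/z in mm.
#' @param frame_rate frames per second.
#' @return A data frame with `speed` (m/s) and `accel` (m/s^2).
#' @export
compute_speed_acceleration <- function(positions, frame_rate) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 3) stop("need at least 3 frames to differentiate")
  dt <- 1 / frame_rate
  vel <- apply(positions, 2, central_diff, dt = dt) / 1000 # mm/s -> m/s
  speed <- sqrt(rowSums(vel^2))
  accel <- central_diff(speed, dt)
  data.frame(speed = speed, accel = accel)
}

#' Detect the attack window after the final hover
#'
#' Damselflies hover close to prey height before darting forward; the attack
#' is the post-hover period during which the damselfly moves toward the
#' targeted fly. The window starts at the first frame after the last run of
#' at least `hover_min_duration` ms in which speed stays below
#' `hover_speed_threshold`, and ends at the trajectory's contact-or-escape
#' frame.
#'
#' @param speed per-frame speed series, m/s.
#' @param frame_rate frames per second.
#' @param end_frame contact-or-escape frame (window end).
#' @param hover_speed_threshold hover classification threshold, m/s.
#' @param hover_min_duration minimum hover duration, ms.
#' @return A list of class `attack_window` with `start`, `end` and
#'   `hover_found`; if no qualifying hover exists the full series is used and
#'   `hover_found` is `FALSE` (with a warning).
#' @export
detect_attack_window <- function(speed, frame_rate, end_frame = length(speed),
                                 hover_speed_threshold = 0.05,
                                 hover_min_duration = 50) {
  stopifnot(end_frame >= 1, end_frame <= length(speed))
  min_frames <- max(1L, ceiling(hover_min_duration / 1000 * frame_rate))
  below <- speed[seq_len(end_frame)] < hover_speed_threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hovers <- which(r$values & r$lengths >= min_frames)
  if (length(hovers) == 0) {
    warning("no hover found; falling back to the full series")
    win <- list(start = 1L, end = as.integer(end_frame), hover_found = FALSE)
  } else {
    last <- hovers[length(hovers)]
    if (ends[last] >= end_frame) {
      stop_domain("trajectory is stationary through the end frame: no attack",
                  "loomstrike_no_attack")
    }
    win <- list(start = ends[last] + 1L, end = as.integer(end_frame),
                hover_found = TRUE)
  }
  structure(win, class = "attack_window")
}

#' Prey-centred elevation and azimuth of the attacking damselfly
#'
#' Angles of the damselfly head relative to the targeted fly, in a frame
#' whose +x axis is the mesh-wall normal pointing into the chamber and +z is
#' up. Elevation is `atan2(dz, sqrt(dx^2 + dy^2))` in `[-90, 90]` degrees.
#' Because of left-right symmetry, the lateral (y) coordinate enters as its
#' absolute value, so azimuth `atan2(|dy|, dx)` is folded into `[0, 180]`
#' degrees (0 = head-on along the wall normal, 180 = from behind).
#'
#' @param traj a [tracked_trajectory()].
#' @param window an [detect_attack_window()] result (or a list with
#'   `start`/`end`); defaults to the full series ending at `end_frame`.
#' @param reference `"window_start"` (angles measured from the fly's position
#'   at the window start — the perching position) or `"per_frame"`.
#' @return A list with per-frame `elevation` and `azimuth` (degrees, NA where
#'   undefined), window means `mean_elevation` / `mean_azimuth`, and
#'   `n_undefined`.
#' @export
elevation_azimuth <- function(traj, window = NULL,
                              reference = c("window_start", "per_frame")) {
  reference <- match.arg(reference)
  stopifnot(inherits(traj, "tracked_trajectory"))
  if (is.null(window)) window <- list(start = 1L, end = traj$end_frame)
  head <- traj$points$damselfly_head
  fly <- traj$points$fly_centroid
  ref <- if (reference == "window_start") {
    matrix(fly[window$start, ], nrow = nrow(head), ncol = 3, byrow = TRUE)
  } else {
    fly
  }
  d <- head - ref
  rxy <- sqrt(d[, 1]^2 + d[, 2]^2)
  rtot <- sqrt(rxy^2 + d[, 3]^2)
  elev <- rad2deg(atan2(d[, 3], rxy))
  azim <- rad2deg(atan2(abs(d[, 2]), d[, 1]))
  elev[rtot < 1e-9] <- NA_real_
  azim[rtot < 1e-9 | rxy < 1e-9] <- NA_real_
  idx <- window$start:window$end
  list(elevation = elev, azimuth = azim,
       mean_elevation = mean(elev[idx], na.rm = TRUE),
       mean_azimuth = mean(azim[idx], na.rm = TRUE),
       n_undefined = sum(is.na(azim[idx])))
}

#' Peak kinematic metrics over the attack window
#'
#' @param speed,accel per-frame series (m/s, m/s^2).
#' @param window an attack window (list with `start`, `end`).
#' @param frame_rate frames per second.
#' @param end_frame frame defining t = 0.
#' @return List with `peak_speed`, `peak_accel`, `time_of_peak_speed_ms` and
#'   `time_of_peak_accel_ms` (ms relative to t = 0; negative = before the
#'   contact-or-escape frame). Ties in the maximum are broken to the latest
#'   frame.
#' @export
peak_metrics <- function(speed, accel, window, frame_rate, end_frame) {
  idx <- window$start:window$end
  if (length(idx) == 0) stop("empty attack window")
  pk_s <- max(speed[idx], na.rm = TRUE)
  i_s <- max(idx[which(speed[idx] == pk_s)])
  pk_a <- max(accel[idx], na.rm = TRUE)
  i_a <- max(idx[which(accel[idx] == pk_a)])
  list(peak_speed = pk_s,
       peak_accel = pk_a,
       time_of_peak_speed_ms = (i_s - end_frame) / frame_rate * 1000,
       time_of_peak_accel_ms = (i_a - end_frame) / frame_rate * 1000)
}

#' Retinal angular size of the damselfly at the event end
#'
#' Converts the damselfly-to-fly distance at the contact-or-escape frame to
#' the visual angle the damselfly head subtends on the fly's retina:
#' `theta = 2 * atan(r / d)` with head half-width `r = head_width / 2` and
#' Euclidean distance `d`.
#'
#' @param traj a [tracked_trajectory()].
#' @param head_width damselfly head width (2r), mm.
#' @return Angle in degrees.
#' @export
angular_size_at_end <- function(traj, head_width = 2.2) {
  stopifnot(inherits(traj, "tracked_trajectory"), head_width > 0)
  d_end <- distance_to_fly(traj)[traj$end_frame]
  if (is.na(d_end)) stop("distance undefined at the end frame (gap)")
  if (d_end <= 0) {
    stop_domain("zero damselfly-fly distance at end frame (contact)",
                "loomstrike_domain_error")
  }
  2 * rad2deg(atan((head_width / 2) / d_end))
}

#' Full attack-kinematics pipeline for one predation event
#'
#' Smooths the digitized positions, differentiates them into speed and
#' acceleration, finds the post-hover attack window, computes prey-centred
#' angles, peak metrics and the retinal angular size at the event end.
#'
#' @param traj a [tracked_trajectory()] (raw positions; smoothing is applied
#'   here).
#' @param smoothing a [smoothing_params()].
#' @param head_width damselfly head width, mm.
#' @param hover_speed_threshold,hover_min_duration passed to
#'   [detect_attack_window()].
#' @param angle_reference passed to [elevation_azimuth()].
#' @param max_gap passed to [smooth_positions()].
#' @return Object of class `attack_kinematics`: `trajectory` (smoothed),
#'   `table` (per-frame `frame`, `t_ms`, `speed`, `accel`, `distance_mm`,
#'   `elevation`, `azimuth`), `window`, and `summary` (peaks, mean angles,
#'   `angular_size_at_end_deg`, outcome).
#' @export
attack_kinematics <- function(traj, smoothing = smoothing_params(),
                              head_width = 2.2,
                              hover_speed_threshold = 0.05,
                              hover_min_duration = 50,
                              angle_reference = "window_start",
                              max_gap = 5) {
  sm <- smooth_positions(traj, smoothing, max_gap = max_gap)
  ka <- compute_speed_acceleration(sm$points$damselfly_head, sm$frame_rate)
  window <- detect_attack_window(ka$speed, sm$frame_rate,
                                 end_frame = sm$end_frame,
                                 hover_speed_threshold = hover_speed_threshold,
                                 hover_min_duration = hover_min_duration)
  ang <- elevation_azimuth(sm, window, reference = angle_reference)
  pk <- peak_metrics(ka$speed, ka$accel, window, sm$frame_rate, sm$end_frame)
  tab <- data.frame(frame = seq_len(n_frames(sm)),
                    t_ms = time_rel_ms(sm),
                    speed = ka$speed, accel = ka$accel,
                    distance_mm = distance_to_fly(sm),
                    elevation = ang$elevation, azimuth = ang$azimuth)
  structure(
    list(trajectory = sm, table = tab, window = window,
         summary = c(pk, list(
           mean_elevation = ang$mean_elevation,
           mean_azimuth = ang$mean_azimuth,
           angular_size_at_end_deg = angular_size_at_end(sm, head_width),
           outcome = sm$outcome,
           frame_rate = sm$frame_rate))),
    class = "attack_kinematics"
  )
}

#' @export
print.attack_kinematics <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Attack kinematics (%s): window frames %d-%d of %d\n",
              s$outcome, x$window$start, x$window$end, nrow(x$table)))
  cat(sprintf("  peak speed %.3f m/s at %+.0f ms; peak accel %.2f m/s^2\n",
              s$peak_speed, s$time_of_peak_speed_ms, s$peak_accel))
  cat(sprintf("  mean elevation %.1f deg, mean azimuth %.1f deg, angular size at end %.1f deg\n",
              s$mean_elevation, s$mean_azimuth, s$angular_size_at_end_deg))
  invisible(x)
}

#' Align events at t = 0 and average a kinematic quantity
#'
#' Events of different durations are aligned on their contact-or-escape frame
#' (t = 0) and a per-timepoint mean, standard deviation and coverage count is
#' computed across the events that span each timepoint; averages can
#' therefore show step changes where shorter events drop out of the count.
#'
#' @param kins list of [attack_kinematics()] objects sharing a frame rate.
#' @param quantity column of the per-frame table to average (`"speed"`,
#'   `"accel"`, `"distance_mm"`, `"elevation"` or `"azimuth"`).
#' @param window_only if `TRUE` (default) use only frames inside each event's
#'   attack window.
#' @return Data frame with `t_ms`, `mean`, `sd`, `n`.
#' @export
align_and_average <- function(kins, quantity = "speed", window_only = TRUE) {
  if (length(kins) == 0) stop("empty list of events")
  fr <- unique(vapply(kins, function(k) k$summary$frame_rate, 1))
  if (length(fr) != 1) stop("events must share a frame rate")
  pieces <- lapply(kins, function(k) {
    tab <- k$table
    keep <- if (window_only) seq(k$window$start, k$window$end) else
      seq_len(nrow(tab))
    data.frame(t = round(tab$t_ms[keep], 6), v = tab[[quantity]][keep])
  })
  all <- do.call(rbind, pieces)
  grid <- sort(unique(all$t))
  agg_mean <- tapply(all$v, factor(all$t, levels = grid), mean, na.rm = TRUE)
  agg_sd <- tapply(all$v, factor(all$t, levels = grid), stats::sd, na.rm = TRUE)
  agg_n <- tapply(!is.na(all$v), factor(all$t, levels = grid), sum)
  data.frame(t_ms = grid, mean = as.numeric(agg_mean),
             sd = as.numeric(agg_sd), n = as.integer(agg_n))
}
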