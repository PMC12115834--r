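TRAJ_LABELS <- c("damselfly_head", "damselfly_tail", "fly_centroid")

as_point_matrix <- function(m, label) {
  m <- as.matrix(m)
  if (ncol(m) != 3) stop(sprintf("%s must have 3 columns (x, y, z)", label))
  storage.mode(m) <- "double"
  colnames(m) <- c("x", "y", "z")
  m
}

#' Tracked predation-event trajectory
#'
#' Container for the digitized 3D points of one predation event: per-frame
#' coordinates (mm) of the damselfly head, damselfly tail and targeted-fly
#' body centroid, together with the camera frame rate, the event outcome and
#' the contact-or-escape frame that defines time zero.
#'
#' Frames with missing coordinates for a label are recorded as *gaps*
#' (retrievable via [trajectory_gaps()]); they are never silently zeroed.
#' Frame indices are 1-based; times relative to the event end are
#' `(frame - end_frame) / frame_rate`, so the end frame sits at t = 0 and
#' earlier frames are negative.
#'
#' @param damselfly_head,damselfly_tail,fly_centroid numeric matrices, one row
#'   per frame, columns x/y/z in mm. All three must have the same number of
#'   rows (at least 5).
#' @param frame_rate recording frame rate in Hz (high-speed predation video is
#'   typically 1000).
#' @param outcome `"capture"` or `"escape"`.
#' @param end_frame 1-based index of the contact-or-escape frame; defaults to
#'   the last frame.
#' @param times optional explicit time stamps (s), strictly increasing;
#'   defaults to `(0:(n-1)) / frame_rate`.
#' @return An object of class `tracked_trajectory`.
#' @export
tracked_trajectory <- function(damselfly_head, damselfly_tail, fly_centroid,
                               frame_rate = 1000,
                               outcome = c("escape", "capture"),
                               end_frame = NULL, times = NULL) {
  outcome <- match.arg(outcome)
  pts <- list(damselfly_head = as_point_matrix(damselfly_head, "damselfly_head"),
              damselfly_tail = as_point_matrix(damselfly_tail, "damselfly_tail"),
              fly_centroid = as_point_matrix(fly_centroid, "fly_centroid"))
  n <- nrow(pts[[1]])
  if (any(vapply(pts, nrow, 1L) != n)) {
    stop("all labelled point series must have equal length")
  }
  if (n < 5) stop("trajectory needs at least 5 frames")
  if (!is.numeric(frame_rate) || frame_rate <= 0) stop("frame_rate must be > 0")
  end_frame <- as.integer(end_frame %||% n)
  if (end_frame < 1 || end_frame > n) stop("end_frame out of range")
  if (is.null(times)) times <- (seq_len(n) - 1) / frame_rate
  if (length(times) != n || any(diff(times) <= 0)) {
    stop("times must be strictly increasing and match the number of frames")
  }
  gaps <- lapply(pts, function(m) which(apply(is.na(m), 1, any)))
  structure(
    list(points = pts, times = as.numeric(times), frame_rate = frame_rate,
         outcome = outcome, end_frame = end_frame, gaps = gaps,
         smoothed = FALSE),
    class = "tracked_trajectory"
  )
}

#' @export
print.tracked_trajectory <- function(x, ...) {
  n <- n_frames(x)
  cat(sprintf(
    "Tracked trajectory: %d frames @ %g Hz (%.3f s), outcome = %s, end frame %d%s\n",
    n, x$frame_rate, x$times[n] - x$times[1], x$outcome, x$end_frame,
    if (x$smoothed) " [smoothed]" else ""))
  ng <- sum(lengths(x$gaps) > 0)
  if (ng > 0) {
    cat(sprintf("  gaps: %s\n",
                paste(sprintf("%s (%d frames)", names(x$gaps)[lengths(x$gaps) > 0],
                              lengths(x$gaps)[lengths(x$gaps) > 0]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @rdname tracked_trajectory
#' @param traj a `tracked_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$points$damselfly_head)

#' Flagged missing-frame gaps
#'
#' @param traj a [tracked_trajectory()].
#' @return Named list of 1-based frame indices with missing coordinates, one
#'   entry per label.
#' @export
trajectory_gaps <- function(traj) traj$gaps

#' Time of each frame relative to the event end (ms)
#'
#' @param traj a [tracked_trajectory()].
#' @return Numeric vector: `(frame - end_frame) / frame_rate * 1000`; negative
#'   before contact/escape, 0 at the end frame.
#' @export
time_rel_ms <- function(traj) {
  (seq_len(n_frames(traj)) - traj$end_frame) / traj$frame_rate * 1000
}

#' Per-frame damselfly-to-fly distance
#'
#' Euclidean distance (mm) between the damselfly head and the fly centroid.
#'
#' @param traj a [tracked_trajectory()].
#' @return Numeric vector of distances, NA where either point is missing.
#' @export
distance_to_fly <- function(traj) {
  d <- traj$points$damselfly_head - traj$points$fly_centroid
  sqrt(rowSums(d^2))
}

#' Read digitized video-tracking points
#'
#' Parses a DLTdv-style CSV of per-frame 3D coordinates into a
#' [tracked_trajectory()]. The native dialect has a `frame` column plus
#' `<label>_x`, `<label>_y`, `<label>_z` columns (mm) for the labels
#' `damselfly_head`, `damselfly_tail` and `fly_centroid`; blank cells are
#' missing coordinates and become flagged gaps. Generic digitizer headers
#' (e.g. `pt1_X`) are supported through `label_map`.
#'
#' @param path path to the CSV file.
#' @param frame_rate recording frame rate, Hz.
#' @param label_map optional named character vector mapping canonical labels
#'   to file column prefixes, e.g.
#'   `c(damselfly_head = "pt1", damselfly_tail = "pt2", fly_centroid = "pt3")`.
#' @param outcome,end_frame event metadata passed to [tracked_trajectory()].
#' @return A [tracked_trajectory()].
#' @export
read_digitized_points <- function(path, frame_rate = 1000, label_map = NULL,
                                  outcome = c("escape", "capture"),
                                  end_frame = NULL) {
  outcome <- match.arg(outcome)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE)
  names(df) <- tolower(names(df))
  prefixes <- stats::setNames(TRAJ_LABELS, TRAJ_LABELS)
  if (!is.null(label_map)) {
    bad <- setdiff(names(label_map), TRAJ_LABELS)
    if (length(bad)) stop(sprintf("unknown labels in label_map: %s",
                                  paste(bad, collapse = ", ")))
    prefixes[names(label_map)] <- tolower(label_map)
  }
  missing_cols <- character(0)
  pts <- lapply(prefixes, function(p) {
    cols <- paste0(p, "_", c("x", "y", "z"))
    absent <- setdiff(cols, names(df))
    if (length(absent)) {
      missing_cols <<- c(missing_cols, absent)
      return(NULL)
    }
    as.matrix(df[cols])
  })
  if (length(missing_cols)) {
    stop_domain(sprintf("cannot resolve columns: %s",
                        paste(missing_cols, collapse = ", ")),
                "loomstrike_format_error")
  }
  if ("frame" %in% names(df) && any(diff(df$frame) <= 0)) {
    stop_domain("frame column is not strictly increasing",
                "loomstrike_data_error")
  }
  tracked_trajectory(pts$damselfly_head, pts$damselfly_tail, pts$fly_centroid,
                     frame_rate = frame_rate, outcome = outcome,
                     end_frame = end_frame)
}

#' Write a trajectory to the digitized-points CSV dialect
#'
#' @param traj a [tracked_trajectory()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_digitized_points <- function(traj, path) {
  df <- data.frame(frame = seq_len(n_frames(traj)))
  for (lab in TRAJ_LABELS) {
    m <- traj$points[[lab]]
    df[[paste0(lab, "_x")]] <- m[, 1]
    df[[paste0(lab, "_y")]] <- m[, 2]
    df[[paste0(lab, "_z")]] <- m[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
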