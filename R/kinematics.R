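#' Movement velocity along a track
#'
#' Velocity of frame transition t -> t+1 is the Euclidean displacement
#' divided by the frame interval `dt = 1/fs`:
#' `v(t) = sqrt((x_{t+1}-x_t)^2 + (y_{t+1}-y_t)^2) * fs`, in pixels/second.
#'
#' @param track data frame with columns `frame`, `x`, `y` for one identity,
#'   gap-free (consecutive frames).
#' @param fs frame rate in frames/second.
#' @return Numeric vector of length `nrow(track) - 1` (empty for a track
#'   shorter than 2 points).
#' @export
compute_velocity <- function(track, fs) {
  check_number(fs, "fs", 0, strict_lower = TRUE)
  track <- check_track(track)
  if (nrow(track) < 2) return(numeric(0))
  sqrt(diff(track$x)^2 + diff(track$y)^2) * fs
}

#' Movement acceleration from a velocity series
#'
#' First finite difference of velocity over one frame interval:
#' `a(t) = (v(t+1) - v(t)) * fs`, in pixels/second^2. Negative values mean
#' deceleration.
#'
#' @param velocity numeric velocity series (pixels/second).
#' @param fs frame rate in frames/second.
#' @return Numeric vector of length `length(velocity) - 1` (empty if the
#'   series is shorter than 2).
#' @export
compute_acceleration <- function(velocity, fs) {
  check_number(fs, "fs", 0, strict_lower = TRUE)
  if (length(velocity) < 2) return(numeric(0))
  diff(velocity) * fs
}

#' Movement direction along a track
#'
#' Heading of each frame transition, `atan2(y_{t+1}-y_t, x_{t+1}-x_t)`, in
#' radians in (-pi, pi]. By default directions are reported in image
#' coordinates (y grows downward, so +pi/2 points down the frame); set
#' `image_coords = FALSE` for the mathematical convention (angle negated).
#' Zero-displacement transitions have no direction and are returned as `NA`.
#'
#' @param track data frame with columns `frame`, `x`, `y`, gap-free.
#' @param image_coords logical; see above.
#' @return Numeric vector of length `nrow(track) - 1` with `NA` where the
#'   organism did not move.
#' @export
compute_direction <- function(track, image_coords = TRUE) {
  track <- check_track(track)
  if (nrow(track) < 2) return(numeric(0))
  dx <- diff(track$x)
  dy <- diff(track$y)
  th <- atan2(dy, dx)
  th[dx == 0 & dy == 0] <- NA_real_
  if (!image_coords) th <- -th
  th
}

check_track <- function(track) {
  stopifnot(is.data.frame(track), all(c("frame", "x", "y") %in% names(track)))
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) > 1 && any(diff(track$frame) != 1))
    stop("track has frame gaps; kinematics require a gap-free track",
         call. = FALSE)
  track
}

#' Per-frame kinematics of a trajectory set
#'
#' Computes velocity, acceleration and direction for every identity in a
#' trajectory set. Each row describes the transition from `frame` to
#' `frame + 1`; acceleration is `NA` at each track's final transition and
#' direction is `NA` for zero displacement.
#'
#' @param trajectories a `trajectory_set` (or any data frame with
#'   `track_id`, `frame`, `x`, `y`).
#' @param fs frame rate in frames/second.
#' @param image_coords passed to [compute_direction()].
#' @return A `kinematics_table` data frame: `track_id`, `frame`,
#'   `velocity` (px/s), `acceleration` (px/s^2), `direction` (radians).
#' @export
track_kinematics <- function(trajectories, fs, image_coords = TRUE) {
  out <- lapply(split(trajectories, trajectories$track_id), function(p) {
    p <- p[order(p$frame), , drop = FALSE]
    if (nrow(p) < 2) return(NULL)
    v <- compute_velocity(p, fs)
    a <- compute_acceleration(v, fs)
    data.frame(track_id = p$track_id[1], frame = p$frame[-nrow(p)],
               velocity = v,
               acceleration = c(a, NA_real_),
               direction = compute_direction(p, image_coords))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(track_id = integer(), frame = integer(),
                      velocity = numeric(), acceleration = numeric(),
                      direction = numeric())
  rownames(res) <- NULL
  attr(res, "fs") <- fs
  class(res) <- c("kinematics_table", "data.frame")
  res
}

#' Per-individual locomotion summaries
#'
#' Median, mean, minimum and maximum of velocity and of absolute
#' acceleration per identity, plus the number of transitions with a defined
#' direction — one summary row per tracked individual.
#'
#' @param table a `kinematics_table` from [track_kinematics()].
#' @return A data frame with one row per `track_id`.
#' @export
summarize_individuals <- function(table) {
  if (nrow(table) == 0) stop("empty kinematics table", call. = FALSE)
  out <- lapply(split(table, table$track_id), function(p) {
    a <- abs(p$acceleration[!is.na(p$acceleration)])
    data.frame(track_id = p$track_id[1],
               n_transitions = nrow(p),
               velocity_median = stats::median(p$velocity),
               velocity_mean = mean(p$velocity),
               velocity_min = min(p$velocity),
               velocity_max = max(p$velocity),
               abs_accel_median = if (length(a)) stats::median(a) else NA_real_,
               abs_accel_mean = if (length(a)) mean(a) else NA_real_,
               abs_accel_max = if (length(a)) max(a) else NA_real_,
               n_directed = sum(!is.na(p$direction)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plot kinematics
#'
#' `type = "series"` draws per-identity velocity over time (the time axis in
#' seconds); `type = "box"` draws one velocity box per individual, the
#' median marked by the box line.
#'
#' @param x a `kinematics_table`.
#' @param type `"series"` or `"box"`.
#' @param ... passed to the underlying plotting function.
#' @export
plot.kinematics_table <- function(x, type = c("series", "box"), ...) {
  type <- match.arg(type)
  fs <- attr(x, "fs") %||% 1
  if (type == "box") {
    graphics::boxplot(velocity ~ track_id, data = x,
                      xlab = "individual", ylab = "velocity (px/s)", ...)
  } else {
    ids <- unique(x$track_id)
    cols <- grDevices::hcl.colors(max(length(ids), 2), "Dark 3")
    graphics::plot(NA, xlim = range(x$frame / fs), ylim = range(x$velocity),
                   xlab = "time (s)", ylab = "velocity (px/s)", ...)
    for (k in seq_along(ids)) {
      p <- x[x$track_id == ids[k], ]
      graphics::lines(p$frame / fs, p$velocity, col = cols[k])
    }
  }
  invisible(x)
}
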