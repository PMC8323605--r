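#' Simulate ground-truth organism trajectories
#'
#' Draws one trajectory per organism from a two-state (stationary/moving)
#' Markov chain: a stationary organism enters a movement burst with
#' per-frame probability `p_start_move`, a moving organism stops with
#' probability `p_stop_move`. During a burst the organism takes steps of
#' Gaussian length along a slowly wandering heading; boundaries reflect
#' (organisms stay inside the dish). Steps that would bring two organisms
#' closer than `min_separation` are suppressed and the heading reversed, so
#' well-separated organisms stay separated. When `p_start_move > 0`,
#' organisms start in the moving state and keep moving for the first
#' `startle_frames` frames, emulating the elevated activity small organisms
#' show in the first seconds after recording onset; with `p_start_move = 0`
#' the population is quiescent and every position is constant.
#'
#' @param config a [scene_config()].
#' @return A `ground_truth` data frame with columns `track_id` (1-based),
#'   `frame` (0-based), `x`, `y` (sub-pixel, image convention) and `visible`
#'   (always 1 here; [make_crossing_pair()] flags engineered occlusions),
#'   with the configuration attached as attribute `config`.
#' @export
simulate_trajectories <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  n <- config$n_organisms
  T <- config$n_frames
  w <- config$frame_width
  h <- config$frame_height
  margin <- config$organism_radius + 2
  lo_x <- margin; hi_x <- w - 1 - margin
  lo_y <- margin; hi_y <- h - 1 - margin
  if (!is.null(config$arena)) {
    lo_x <- max(lo_x, config$arena[1]); hi_x <- min(hi_x, config$arena[3])
    lo_y <- max(lo_y, config$arena[2]); hi_y <- min(hi_y, config$arena[4])
  }
  if (lo_x >= hi_x || lo_y >= hi_y)
    stop("frame (or arena) too small for the configured organism radius",
         call. = FALSE)

  with_seed(config$seed, {
    pos <- place_organisms(config, lo_x, hi_x, lo_y, hi_y)
    if (n == 0) {
      gt <- data.frame(track_id = integer(), frame = integer(),
                       x = numeric(), y = numeric(), visible = integer())
      attr(gt, "config") <- config
      class(gt) <- c("ground_truth", "data.frame")
      return(gt)
    }
    xs <- matrix(NA_real_, nrow = T, ncol = n)
    ys <- matrix(NA_real_, nrow = T, ncol = n)
    xs[1, ] <- pos[, 1]
    ys[1, ] <- pos[, 2]
    moving <- rep(config$p_start_move > 0, n)
    heading <- runif(n, -pi, pi)
    if (T > 1) for (t in 2:T) {
      startle <- config$p_start_move > 0 && t <= config$startle_frames + 1
      for (i in seq_len(n)) {
        if (startle) {
          moving[i] <- TRUE
        } else if (moving[i]) {
          if (runif(1) < config$p_stop_move) moving[i] <- FALSE
        } else {
          if (runif(1) < config$p_start_move) {
            moving[i] <- TRUE
            heading[i] <- runif(1, -pi, pi)
          }
        }
        px <- xs[t - 1, i]; py <- ys[t - 1, i]
        if (moving[i]) {
          heading[i] <- heading[i] + rnorm(1, 0, 0.2)
          step <- max(0, rnorm(1, config$burst_speed, config$burst_speed_sd))
          cx <- px + step * cos(heading[i])
          cy <- py + step * sin(heading[i])
          # bounce: reflect both the position and the heading component
          if (cx < lo_x || cx > hi_x) {
            cx <- reflect(cx, lo_x, hi_x)
            heading[i] <- pi - heading[i]
          }
          if (cy < lo_y || cy > hi_y) {
            cy <- reflect(cy, lo_y, hi_y)
            heading[i] <- -heading[i]
          }
          # collision avoidance: suppress steps that close below min_separation
          others <- setdiff(seq_len(n), i)
          if (length(others) > 0 && config$min_separation > 0) {
            ox <- ifelse(is.na(xs[t, others]), xs[t - 1, others], xs[t, others])
            oy <- ifelse(is.na(ys[t, others]), ys[t - 1, others], ys[t, others])
            if (min(sqrt((ox - cx)^2 + (oy - cy)^2)) < config$min_separation) {
              cx <- px; cy <- py
              heading[i] <- heading[i] + pi
            }
          }
          xs[t, i] <- cx; ys[t, i] <- cy
        } else {
          xs[t, i] <- px; ys[t, i] <- py
        }
      }
    }
    gt <- data.frame(
      track_id = rep(seq_len(n), each = T),
      frame = rep(0:(T - 1), times = n),
      x = as.vector(xs),
      y = as.vector(ys),
      visible = 1L
    )
    attr(gt, "config") <- config
    class(gt) <- c("ground_truth", "data.frame")
    gt
  })
}

# non-overlapping initial placement with bounded retries
place_organisms <- function(config, lo_x, hi_x, lo_y, hi_y) {
  n <- config$n_organisms
  if (!is.null(config$init_positions)) {
    pos <- config$init_positions
    if (any(pos[, 1] < 0 | pos[, 1] >= config$frame_width |
            pos[, 2] < 0 | pos[, 2] >= config$frame_height))
      stop("`init_positions` outside frame bounds", call. = FALSE)
    if (n > 1) {
      d <- as.matrix(stats::dist(pos))
      if (min(d[upper.tri(d)]) < config$min_separation)
        stop("`init_positions` violate min_separation", call. = FALSE)
    }
    return(pos)
  }
  pos <- matrix(NA_real_, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(500L)) {
      cand <- c(runif(1, lo_x, hi_x), runif(1, lo_y, hi_y))
      if (i == 1 ||
          min(sqrt((pos[seq_len(i - 1), 1] - cand[1])^2 +
                   (pos[seq_len(i - 1), 2] - cand[2])^2)) >=
            config$min_separation) {
        pos[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop(sprintf(paste0("could not place %d organisms with min_separation ",
                          "%g in a %d x %d frame"),
                   n, config$min_separation,
                   config$frame_width, config$frame_height), call. = FALSE)
  }
  pos
}

reflect <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

#' Construct a crossing pair with an engineered occlusion
#'
#' Builds ground truth for two organisms on straight constant-velocity
#' crossing paths, geometrically arranged so that their rendered disks form a
#' single connected component for exactly `gap_frames` consecutive frames.
#' The slower organism (track 1) retains its identity through the merge; the
#' faster organism (track 2) is flagged invisible during the merged frames —
#' its true positions during the gap lie on the straight segment between its
#' last and next visible positions, which is what gap bridging is expected to
#' reconstruct.
#'
#' @param config a [scene_config()]; `n_organisms` is ignored (always 2).
#' @param gap_frames number of fully merged frames (1 to `n_frames - 2`).
#' @return A `ground_truth` data frame (see [simulate_trajectories()]) with
#'   attributes `occluded_frames` (0-based frames where the blobs merge) and
#'   `occluded_track` (2).
#' @export
make_crossing_pair <- function(config, gap_frames) {
  stopifnot(inherits(config, "scene_config"))
  g <- check_count(gap_frames, "gap_frames", 1L)
  T <- config$n_frames
  if (g > T - 2) stop("`gap_frames` must be at most n_frames - 2", call. = FALSE)
  r <- config$organism_radius
  w <- config$frame_width; h <- config$frame_height
  dy <- 3                              # small vertical offset between paths
  # rasterisation-safe merge geometry: centres closer than d_in are certainly
  # one component, farther than d_out certainly two
  d_in <- 2 * r - 2
  d_out <- 2 * r + 3
  if (d_in <= dy)
    stop("organism radius too small for a crossing-pair scene", call. = FALSE)
  m_in <- sqrt(d_in^2 - dy^2)
  m_out <- sqrt(d_out^2 - dy^2)
  # in-window relative speed: the frames flanking the window must be
  # separated, the window frames merged
  vrel_f <- 2 * m_out / (g + 1)
  if (g > 1 && vrel_f * (g - 1) / 2 > m_in)
    stop(sprintf("no feasible crossing geometry for gap_frames = %d at radius %g",
                 g, r), call. = FALSE)
  vrel_s <- 4                          # approach/departure relative speed
  tc <- round(0.45 * T) + if (g %% 2 == 0) 0.5 else 0
  t <- 0:(T - 1)
  # relative horizontal separation u(t) = x_B - x_A, piecewise linear:
  # dart through the crossing (|u| <= u_fast), cruise outside it
  u_fast <- vrel_f * ((g + 1) / 2 + 2)
  u <- -vrel_f * (t - tc)
  pre <- u > u_fast
  post <- u < -u_fast
  u[pre] <- u_fast + vrel_s * (tc - u_fast / vrel_f - t[pre])
  u[post] <- -u_fast - vrel_s * (t[post] - tc - u_fast / vrel_f)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  xA <- cx - 0.35 * u
  xB <- cx + 0.65 * u
  yA <- rep(cy - dy / 2, T)
  yB <- rep(cy + dy / 2, T)
  margin <- r + 2
  if (min(xA, xB) < margin || max(xA, xB) > w - 1 - margin ||
      cy - dy / 2 < margin || cy + dy / 2 > h - 1 - margin)
    stop("crossing paths leave the frame; increase frame_width or n_frames",
         call. = FALSE)
  merged <- which(abs(u) <= m_in) - 1L         # 0-based frames
  if (length(merged) != g)
    stop("internal error: crossing geometry produced wrong merge length")
  gt <- data.frame(
    track_id = rep(1:2, each = T),
    frame = rep(t, 2),
    x = c(xA, xB),
    y = c(yA, yB),
    visible = 1L
  )
  gt$visible[gt$track_id == 2L & gt$frame %in% merged] <- 0L
  attr(gt, "config") <- config
  attr(gt, "occluded_frames") <- merged
  attr(gt, "occluded_track") <- 2L
  class(gt) <- c("ground_truth", "data.frame")
  gt
}
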