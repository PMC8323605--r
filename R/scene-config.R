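#' Configuration for a synthetic tracking scene
#'
#' Describes a synthetic time-lapse scene: dark disk-shaped organisms moving
#' with a bursty two-state (stationary/moving) Markov pattern over a brighter,
#' static background, optionally contaminated by blob-like noise fragments
#' (bubbles, impurities) and additive pixel noise. The defaults mirror a
#' Daphnia-scale recording: 480 x 640 frames at 14 frames/s with ~400 px
#' organisms and a movement activity of 7.5% of frames.
#'
#' Coordinates follow the image convention used throughout the package:
#' `x` is the column, `y` the row, the origin is the top-left pixel centre,
#' and both pixels and frames are 0-based.
#'
#' @param frame_width,frame_height frame size in pixels.
#' @param n_frames number of frames.
#' @param frame_rate frames per second (temporal metadata only; the generator
#'   works in pixels/frame).
#' @param n_organisms number of organisms.
#' @param organism_radius disk radius in pixels (an area of ~400 px
#'   corresponds to radius 11).
#' @param organism_intensity,background_intensity gray levels in `[0, 255]`;
#'   organisms are darker than the background in the emulated recordings.
#' @param p_start_move per-frame probability that a stationary organism
#'   enters a movement burst. If 0, organisms never move.
#' @param p_stop_move per-frame probability that a moving organism stops.
#'   The long-run fraction of moving frames is
#'   `p_start_move / (p_start_move + p_stop_move)`; the defaults give 7.5%.
#' @param burst_speed,burst_speed_sd mean and spread (pixels/frame) of the
#'   per-frame step length during a burst.
#' @param startle_frames length of the startle phase at recording onset:
#'   small organisms respond to the camera/handling with elevated movement
#'   for the first seconds of a recording, so organisms stay in the moving
#'   state for this many initial frames (0 disables; also disabled when
#'   `p_start_move = 0`). This is what lets the background model see the
#'   scene behind each organism early on.
#' @param arena optional `c(x0, y0, x1, y1)` rectangle confining organism
#'   centres — the housing well of the emulated recordings, which often
#'   covers only part of the frame (impurities and bubbles sit outside it).
#'   `NULL` means the whole frame.
#' @param min_separation minimum allowed distance between organism centres,
#'   enforced at placement and during movement (steps that would violate it
#'   are suppressed and the heading reversed). Defaults to 3 radii so that
#'   organisms stay well separated; engineered overlaps are produced with
#'   [make_crossing_pair()] instead.
#' @param n_noise_fragments number of blob-like noise fragments.
#' @param noise_fragment_area area of each fragment in pixels.
#' @param noise_drift per-frame random-walk standard deviation of fragment
#'   positions (0 = static fragments).
#' @param noise_appear_prob if 1, fragments are visible in every frame; if in
#'   (0, 1), fragments blink: single-frame flashes with this probability,
#'   restricted to every other frame so appearances are never consecutive.
#' @param additive_noise_sd standard deviation of additive Gaussian pixel
#'   noise (gray levels).
#' @param init_positions optional `n_organisms` x 2 matrix of initial (x, y)
#'   organism positions; random non-overlapping placement when `NULL`.
#' @param noise_positions optional `n_noise_fragments` x 2 matrix of fragment
#'   anchor positions; random placement when `NULL`.
#' @param seed integer seed; all generator output is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `scene_config`.
#' @seealso [simulate_trajectories()], [render_frames()],
#'   [make_crossing_pair()]
#' @export
scene_config <- function(frame_width = 640, frame_height = 480,
                         n_frames = 200, frame_rate = 14,
                         n_organisms = 5, organism_radius = 11,
                         organism_intensity = 30, background_intensity = 200,
                         p_start_move = 0.06, p_stop_move = 0.74,
                         burst_speed = 4, burst_speed_sd = 1,
                         startle_frames = 15,
                         arena = NULL,
                         min_separation = 3 * organism_radius,
                         n_noise_fragments = 0, noise_fragment_area = 200,
                         noise_drift = 0, noise_appear_prob = 1,
                         additive_noise_sd = 2,
                         init_positions = NULL, noise_positions = NULL,
                         seed = 1L) {
  cfg <- list(
    frame_width = check_count(frame_width, "frame_width", 8L),
    frame_height = check_count(frame_height, "frame_height", 8L),
    n_frames = check_count(n_frames, "n_frames", 1L),
    frame_rate = check_number(frame_rate, "frame_rate", 0, strict_lower = TRUE),
    n_organisms = check_count(n_organisms, "n_organisms", 0L),
    organism_radius = check_number(organism_radius, "organism_radius",
                                   0, strict_lower = TRUE),
    organism_intensity = check_number(organism_intensity,
                                      "organism_intensity", 0, 255),
    background_intensity = check_number(background_intensity,
                                        "background_intensity", 0, 255),
    p_start_move = check_number(p_start_move, "p_start_move", 0, 1),
    p_stop_move = check_number(p_stop_move, "p_stop_move", 0, 1),
    burst_speed = check_number(burst_speed, "burst_speed", 0),
    burst_speed_sd = check_number(burst_speed_sd, "burst_speed_sd", 0),
    startle_frames = check_count(startle_frames, "startle_frames", 0L),
    arena = arena,
    min_separation = check_number(min_separation, "min_separation", 0),
    n_noise_fragments = check_count(n_noise_fragments, "n_noise_fragments", 0L),
    noise_fragment_area = check_number(noise_fragment_area,
                                       "noise_fragment_area", 1),
    noise_drift = check_number(noise_drift, "noise_drift", 0),
    noise_appear_prob = check_number(noise_appear_prob, "noise_appear_prob",
                                     0, 1),
    additive_noise_sd = check_number(additive_noise_sd, "additive_noise_sd", 0),
    init_positions = init_positions,
    noise_positions = noise_positions,
    seed = check_count(seed, "seed")
  )
  if (cfg$organism_radius >= min(cfg$frame_width, cfg$frame_height) / 4)
    stop("`organism_radius` must be smaller than a quarter of the frame side",
         call. = FALSE)
  if (cfg$organism_intensity == cfg$background_intensity)
    stop("organism and background intensity must differ", call. = FALSE)
  if (!is.null(arena)) {
    if (length(arena) != 4 || arena[1] >= arena[3] || arena[2] >= arena[4] ||
        arena[1] < 0 || arena[2] < 0 ||
        arena[3] > cfg$frame_width - 1 || arena[4] > cfg$frame_height - 1)
      stop("`arena` must be c(x0, y0, x1, y1) inside the frame", call. = FALSE)
    cfg$arena <- as.numeric(arena)
  }
  if (!is.null(init_positions)) {
    init_positions <- as.matrix(init_positions)
    if (nrow(init_positions) != cfg$n_organisms || ncol(init_positions) != 2)
      stop("`init_positions` must be an n_organisms x 2 matrix", call. = FALSE)
    cfg$init_positions <- init_positions
  }
  if (!is.null(noise_positions)) {
    noise_positions <- as.matrix(noise_positions)
    if (nrow(noise_positions) != cfg$n_noise_fragments ||
        ncol(noise_positions) != 2)
      stop("`noise_positions` must be an n_noise_fragments x 2 matrix",
           call. = FALSE)
    cfg$noise_positions <- noise_positions
  }
  structure(cfg, class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d x %d px, %d frames @ %g fps\n",
              x$frame_width, x$frame_height, x$n_frames, x$frame_rate))
  cat(sprintf("  %d organisms (radius %g px, gray %g on %g)\n",
              x$n_organisms, x$organism_radius, x$organism_intensity,
              x$background_intensity))
  act <- if (x$p_start_move + x$p_stop_move > 0)
    x$p_start_move / (x$p_start_move + x$p_stop_move) else 0
  cat(sprintf("  movement: p_start %g, p_stop %g (activity %.1f%%), speed %g +/- %g px/frame\n",
              x$p_start_move, x$p_stop_move, 100 * act,
              x$burst_speed, x$burst_speed_sd))
  if (x$n_noise_fragments > 0)
    cat(sprintf("  %d noise fragments (~%g px, drift %g, appear prob %g)\n",
                x$n_noise_fragments, x$noise_fragment_area, x$noise_drift,
                x$noise_appear_prob))
  cat(sprintf("  additive noise sd %g, seed %d\n",
              x$additive_noise_sd, x$seed))
  invisible(x)
}
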