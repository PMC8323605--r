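#' Render a synthetic scene to grayscale frames
#'
#' Rasterises ground-truth trajectories into grayscale frames: a uniform
#' background, one filled disk per organism position, optional blob-like
#' noise fragments (static, drifting or blinking) and additive Gaussian
#' pixel noise. Rendering is deterministic given the configuration seed and
#' independent of the trajectory randomness.
#'
#' @param gt a `ground_truth` table from [simulate_trajectories()] or
#'   [make_crossing_pair()].
#' @param config the [scene_config()] the ground truth was generated with.
#' @return A `frame_sequence`: a list of `frame_height x frame_width`
#'   numeric matrices with gray values in `[0, 255]`, with the frame rate
#'   attached as attribute `frame_rate`.
#' @export
render_frames <- function(gt, config) {
  stopifnot(inherits(config, "scene_config"))
  h <- config$frame_height
  w <- config$frame_width
  T <- config$n_frames
  if (nrow(gt) > 0 &&
      (any(gt$x < 0 | gt$x >= w) || any(gt$y < 0 | gt$y >= h)))
    stop("ground truth positions outside the configured frame", call. = FALSE)
  r <- config$organism_radius
  rn <- max(1, sqrt(config$noise_fragment_area / pi))

  with_seed(config$seed + 1000003L, {
    # noise fragment anchors, drift paths and blink pattern
    k <- config$n_noise_fragments
    npos <- NULL
    nvis <- NULL
    if (k > 0) {
      anchors <- config$noise_positions
      if (is.null(anchors)) {
        anchors <- cbind(runif(k, rn, w - 1 - rn), runif(k, rn, h - 1 - rn))
      }
      npos <- array(NA_real_, dim = c(T, k, 2))
      npos[1, , ] <- anchors
      if (T > 1) for (t in 2:T) {
        step <- if (config$noise_drift > 0)
          matrix(rnorm(2 * k, 0, config$noise_drift), ncol = 2) else 0
        npos[t, , 1] <- pmin(pmax(npos[t - 1, , 1] + if (is.matrix(step)) step[, 1] else 0, 0), w - 1)
        npos[t, , 2] <- pmin(pmax(npos[t - 1, , 2] + if (is.matrix(step)) step[, 2] else 0, 0), h - 1)
      }
      nvis <- matrix(TRUE, nrow = T, ncol = k)
      if (config$noise_appear_prob < 1) {
        # blinking fragments flash for single isolated frames: at most one
        # fragment flashes per frame, and flashes are restricted to every
        # other frame, so no two appearances ever fall in consecutive frames
        nvis[] <- FALSE
        p_any <- min(1, k * config$noise_appear_prob)
        for (t in seq_len(T)) {
          flash <- runif(1) < p_any
          j <- sample.int(k, 1)
          if (flash && (t - 1L) %% 2L == 1L) nvis[t, j] <- TRUE
        }
      }
    }

    frames <- vector("list", T)
    for (t in seq_len(T)) {
      fr <- matrix(config$background_intensity, nrow = h, ncol = w)
      if (k > 0) for (j in seq_len(k)) {
        if (nvis[t, j])
          fr <- draw_disk(fr, npos[t, j, 1], npos[t, j, 2], rn,
                          config$organism_intensity)
      }
      sub <- gt[gt$frame == t - 1L, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        fr <- draw_disk(fr, sub$x[i], sub$y[i], r, config$organism_intensity)
      }
      if (config$additive_noise_sd > 0) {
        fr <- fr + matrix(rnorm(h * w, 0, config$additive_noise_sd),
                          nrow = h, ncol = w)
        fr <- pmin(pmax(fr, 0), 255)
      }
      frames[[t]] <- round(fr)
    }
    frame_sequence(frames, frame_rate = config$frame_rate)
  })
}

# fill a disk of radius r centred at 0-based (x, y) into matrix fr
draw_disk <- function(fr, x, y, r, value) {
  h <- nrow(fr); w <- ncol(fr)
  rows <- max(1, floor(y - r) + 1):min(h, ceiling(y + r) + 1)
  cols <- max(1, floor(x - r) + 1):min(w, ceiling(x + r) + 1)
  ry <- rows - 1 - y
  cx <- cols - 1 - x
  inside <- outer(ry^2, cx^2, "+") <= r^2
  fr[rows, cols][inside] <- value
  fr
}

#' Construct a frame sequence
#'
#' Light-weight container for an ordered list of grayscale frames
#' (`height x width` numeric matrices, gray levels 0-255).
#'
#' @param frames list of numeric matrices with identical dimensions.
#' @param frame_rate frames per second.
#' @return An object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, frame_rate = 14) {
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have inconsistent dimensions", call. = FALSE)
  structure(frames, frame_rate = frame_rate, class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("frame_sequence: %d frames, %d x %d px @ %g fps\n",
              length(x), d[1], d[2], attr(x, "frame_rate")))
  invisible(x)
}

#' @export
`[.frame_sequence` <- function(x, i) {
  frame_sequence(unclass(x)[i], frame_rate = attr(x, "frame_rate"))
}
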