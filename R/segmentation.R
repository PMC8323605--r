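#' Segmentation configuration
#'
#' Parameters of the adaptive Gaussian-mixture background model and of the
#' foreground post-processing chain (median filter, diamond erosion,
#' size-based noise removal).
#'
#' The background model keeps up to `max_components` Gaussians per pixel.
#' Component weights relax with learning rate `alpha`, so a component born
#' when an organism stops moving needs about
#' `log(1 - c_f) / log(1 - alpha)` matched frames before its weight exceeds
#' the background threshold `c_f` — until then the stationary organism keeps
#' being detected. The defaults (`alpha = 0.001`, `c_f = 0.25`) retain a
#' stopped organism for ~288 frames (~20 s at 14 fps), comfortably longer
#' than the stationary periods of bursty movers; raise `alpha` (e.g. 0.005,
#' ~57-frame retention) for recordings whose background itself drifts.
#'
#' @param alpha learning-rate constant in (0, 1).
#' @param c_f background weight threshold in (0, 1).
#' @param max_components maximum Gaussians per pixel.
#' @param burn_in_frames frames used to initialise the background model
#'   (per-pixel temporal quantile); masks are produced for every frame, but
#'   detections during the burn-in window are only reliable when organisms
#'   move during it.
#' @param median_window odd side length of the median filter (1 disables).
#' @param erosion_radius radius of the flat diamond structuring element
#'   (0 disables erosion).
#' @param organism_area expected organism area in pixels; only used for the
#'   default size gates.
#' @param min_area,max_area connected components outside `[min_area,
#'   max_area]` are removed (defaults: a quarter to four times
#'   `organism_area`).
#' @param var_init,var_min initial and minimum component variance (gray^2).
#' @param match_k match window half-width in standard deviations.
#' @param init_quantile temporal quantile of the burn-in window used to
#'   initialise the background. The emulated recordings show dark organisms
#'   on a brighter background, so a high quantile (default 0.8) recovers the
#'   background even under pixels an organism occupies for much of the
#'   burn-in; use 0.5 (the temporal median) for polarity-neutral scenes.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(alpha = 0.001, c_f = 0.25, max_components = 5,
                       burn_in_frames = 25, median_window = 3,
                       erosion_radius = 1, organism_area = 380,
                       min_area = organism_area / 4,
                       max_area = 4 * organism_area,
                       var_init = 100, var_min = 16, match_k = 2.5,
                       init_quantile = 0.8) {
  cfg <- list(
    alpha = check_number(alpha, "alpha", 0, 1, TRUE, TRUE),
    c_f = check_number(c_f, "c_f", 0, 1, TRUE, TRUE),
    max_components = check_count(max_components, "max_components", 1L),
    burn_in_frames = check_count(burn_in_frames, "burn_in_frames", 1L),
    median_window = check_count(median_window, "median_window", 1L),
    erosion_radius = check_count(erosion_radius, "erosion_radius", 0L),
    organism_area = check_number(organism_area, "organism_area", 1),
    min_area = check_number(min_area, "min_area", 0),
    max_area = check_number(max_area, "max_area", 0),
    var_init = check_number(var_init, "var_init", 0, strict_lower = TRUE),
    var_min = check_number(var_min, "var_min", 0, strict_lower = TRUE),
    match_k = check_number(match_k, "match_k", 0, strict_lower = TRUE),
    init_quantile = check_number(init_quantile, "init_quantile", 0, 1)
  )
  if (cfg$median_window %% 2 == 0)
    stop("`median_window` must be odd", call. = FALSE)
  if (cfg$min_area >= cfg$max_area)
    stop("`min_area` must be smaller than `max_area`", call. = FALSE)
  structure(cfg, class = "seg_config")
}

#' Estimate per-frame foreground masks
#'
#' Runs the adaptive per-pixel Gaussian-mixture background model over a frame
#' sequence and returns a binary foreground mask per frame. The model is
#' initialised from the per-pixel temporal quantile of the first
#' `burn_in_frames` frames (weight 1), then components are created, replaced
#' and re-weighted frame by frame; a pixel is foreground when its value
#' matches no component or only a component whose weight has not yet exceeded
#' `c_f`.
#'
#' @param frames a [frame_sequence()] (or list of grayscale matrices).
#' @param cfg a [seg_config()].
#' @return A `mask_sequence`: list of logical matrices, `TRUE` = foreground.
#' @export
estimate_foreground <- function(frames, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  if (!is.list(frames)) stop("`frames` must be a list of matrices", call. = FALSE)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have inconsistent dimensions", call. = FALSE)
  if (length(frames) < cfg$burn_in_frames + 1)
    stop(sprintf("need at least burn_in_frames + 1 = %d frames, got %d",
                 cfg$burn_in_frames + 1, length(frames)), call. = FALSE)
  b <- cfg$burn_in_frames
  h <- dims[1, 1]; w <- dims[2, 1]
  stack <- vapply(frames[seq_len(b)], as.numeric, numeric(h * w))
  init <- matrix(row_quantiles_cpp(stack, cfg$init_quantile),
                 nrow = h, ncol = w)
  masks <- gmm_foreground_cpp(lapply(frames, function(f) {
    storage.mode(f) <- "double"; f
  }), init, cfg$alpha, cfg$c_f, cfg$max_components,
  cfg$var_init, cfg$var_min, cfg$match_k)
  structure(masks, class = "mask_sequence", burn_in = b)
}

#' Clean a foreground mask
#'
#' Post-processing chain applied to a binary foreground mask, in fixed
#' order: median filtering, morphological erosion with a flat diamond
#' structuring element, then removal of connected components with area
#' outside `[min_area, max_area]`. The size filter is idempotent.
#'
#' @param mask a logical matrix, or a `mask_sequence` (cleaned per frame).
#' @param cfg a [seg_config()].
#' @return Cleaned mask(s) of the same shape as the input.
#' @export
clean_mask <- function(mask, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  if (inherits(mask, "mask_sequence") || (is.list(mask) && !is.matrix(mask))) {
    out <- lapply(mask, clean_mask_one, cfg = cfg)
    attributes(out) <- attributes(mask)
    return(out)
  }
  clean_mask_one(mask, cfg)
}

clean_mask_one <- function(mask, cfg) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- if (is.logical(mask)) mask else mask > 0.5
  if (cfg$median_window > 1) {
    m <- binary_median_cpp(m, cfg$median_window)
  }
  storage.mode(m) <- "double"
  if (cfg$erosion_radius > 0) {
    r <- cfg$erosion_radius
    # pad with background: outside the frame is not foreground
    padded <- matrix(0, nrow(m) + 2 * r, ncol(m) + 2 * r)
    padded[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))] <- m
    kern <- EBImage::makeBrush(2 * r + 1, shape = "diamond")
    padded <- EBImage::erode(padded, kern)
    m <- padded[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))]
  }
  m <- m > 0.5
  filter_by_area(m, cfg$min_area, cfg$max_area)
}

filter_by_area <- function(mask, min_area, max_area) {
  lab <- label_components8(mask)
  if (max(lab) == 0) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  out <- matrix(lab %in% keep, nrow = nrow(mask), ncol = ncol(mask))
  out
}

#' Detect organisms in a cleaned mask
#'
#' Labels 8-connected foreground components and reports one centroid per
#' component: the arithmetic mean of member pixel coordinates (x = column,
#' y = row, 0-based). Temporary ids are assigned 1..n in raster order of
#' component discovery; they carry no identity across frames.
#'
#' @param mask a cleaned logical matrix.
#' @param frame_index 0-based frame index stamped on the rows.
#' @return A data frame with columns `frame`, `det_id`, `x`, `y` (one row
#'   per detected component; zero rows for an empty mask).
#' @export
detect_organisms <- function(mask, frame_index = 0L) {
  stopifnot(is.matrix(mask))
  lab <- label_components8(mask)
  n <- max(lab)
  if (n == 0) return(empty_detections())
  idx <- which(lab > 0, arr.ind = TRUE)
  l <- lab[lab > 0]
  x <- tapply(idx[, "col"] - 1, l, mean)
  y <- tapply(idx[, "row"] - 1, l, mean)
  data.frame(frame = as.integer(frame_index), det_id = seq_len(n),
             x = as.numeric(x), y = as.numeric(y))
}

#' Detect organisms in every frame of a mask sequence
#'
#' @param masks a `mask_sequence` of cleaned masks (frame 0 first).
#' @return A detection table: one row per component per frame, columns
#'   `frame` (0-based), `det_id` (1-based within frame), `x`, `y`.
#' @seealso [detect_organisms()]
#' @export
detect_sequence <- function(masks) {
  out <- do.call(rbind, lapply(seq_along(masks), function(t) {
    detect_organisms(masks[[t]], t - 1L)
  }))
  if (is.null(out)) out <- empty_detections()
  out
}
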