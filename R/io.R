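#' Read a frame sequence from disk
#'
#' Accepts a directory of numbered PNG files (read in lexicographic name
#' order) or a multi-page TIFF file. Color frames are converted to
#' grayscale with the standard luma weights (0.299 R + 0.587 G + 0.114 B).
#' Video containers (AVI/MP4) are not decodable here; extract frames to PNG
#' first (e.g. `ffmpeg -i in.avi frames/%05d.png`).
#'
#' @param path directory of PNGs or a `.tif`/`.tiff` file.
#' @param frame_rate frames per second to attach (no container metadata is
#'   available for PNG/TIFF input).
#' @return A [frame_sequence()] with gray values 0-255.
#' @export
read_frames <- function(path, frame_rate = 14) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0)
      stop(sprintf("no PNG frames found in '%s'", path), call. = FALSE)
    frames <- lapply(files, function(f) to_gray(png::readPNG(f)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!file.exists(path)) stop(sprintf("'%s' not found", path), call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0) stop("TIFF contains no frames", call. = FALSE)
    frames <- lapply(pages, to_gray)
  } else if (grepl("\\.(avi|mp4|mov|mkv)$", path, ignore.case = TRUE)) {
    stop("video containers are not supported; extract frames to a PNG directory first",
         call. = FALSE)
  } else {
    stop(sprintf("cannot read frames from '%s' (expected a PNG directory or a TIFF file)",
                 path), call. = FALSE)
  }
  frame_sequence(frames, frame_rate = frame_rate)
}

# [0,1] image (matrix or RGB(A) array) -> grayscale matrix 0..255
to_gray <- function(img) {
  if (is.matrix(img)) return(round(img * 255))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) {
      g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    } else {
      g <- img[, , 1]
    }
    return(round(g * 255))
  }
  stop("unsupported image layout", call. = FALSE)
}

#' Write a frame sequence to disk
#'
#' @param frames a [frame_sequence()].
#' @param path output directory (PNG sequence, files `00000.png`, ...) or a
#'   `.tif`/`.tiff` filename (multi-page TIFF).
#' @param format `"png"` or `"tiff"`; inferred from `path` by default.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path,
                         format = if (grepl("\\.tiff?$", path,
                                            ignore.case = TRUE)) "tiff" else "png") {
  format <- match.arg(format, c("png", "tiff"))
  norm <- lapply(frames, function(f) pmin(pmax(f / 255, 0), 1))
  if (format == "tiff") {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(norm)) {
      png::writePNG(norm[[i]],
                    file.path(path, sprintf("%05d.png", i - 1L)))
    }
  }
  invisible(path)
}

# ---- tabular schemas -------------------------------------------------------

#' Read and write the package's CSV tables
#'
#' Fixed plain-text schemas shared by the command-line interface and the
#' file-based helpers:
#' \describe{
#'   \item{detections}{`frame,det_id,x,y` — 0-based frame, 1-based id within
#'     frame.}
#'   \item{tracks}{`track_id,frame,x,y,interpolated` — 1-based identity,
#'     0-based frame, `interpolated` 0/1.}
#'   \item{ground truth}{`track_id,frame,x,y,visible` — `visible` 0/1.}
#'   \item{kinematics}{`track_id,frame,velocity,acceleration,direction` —
#'     undefined entries empty.}
#' }
#'
#' @param x table to write.
#' @param path CSV file path.
#' @return Readers return the table (tracks as a `trajectory_set`, ground
#'   truth as a `ground_truth`); writers return `path` invisibly.
#' @name msot_csv
NULL

#' @rdname msot_csv
#' @export
write_detections <- function(x, path) {
  write.csv(x[, c("frame", "det_id", "x", "y")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname msot_csv
#' @export
read_detections <- function(path) {
  x <- read.csv(path)
  need_cols(x, c("frame", "det_id", "x", "y"), path)
  x
}

#' @rdname msot_csv
#' @export
write_tracks <- function(x, path) {
  out <- data.frame(track_id = x$track_id, frame = x$frame, x = x$x, y = x$y,
                    interpolated = as.integer(x$interpolated))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname msot_csv
#' @export
read_tracks <- function(path) {
  x <- read.csv(path)
  need_cols(x, c("track_id", "frame", "x", "y", "interpolated"), path)
  x$interpolated <- x$interpolated != 0
  class(x) <- c("trajectory_set", "data.frame")
  x
}

#' @rdname msot_csv
#' @export
write_ground_truth <- function(x, path) {
  out <- data.frame(track_id = x$track_id, frame = x$frame, x = x$x, y = x$y,
                    visible = as.integer(x$visible))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname msot_csv
#' @export
read_ground_truth <- function(path) {
  x <- read.csv(path)
  need_cols(x, c("track_id", "frame", "x", "y", "visible"), path)
  class(x) <- c("ground_truth", "data.frame")
  x
}

#' @rdname msot_csv
#' @export
write_kinematics <- function(x, path) {
  write.csv(x[, c("track_id", "frame", "velocity", "acceleration",
                  "direction")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

need_cols <- function(x, cols, path) {
  missing <- setdiff(cols, names(x))
  if (length(missing))
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(x)
}

#' Write a CLEAR MOT report as JSON
#'
#' Schema: `motp_px`, `mota`, and `per_frame`, an array of objects with
#' keys `frame`, `n_gt`, `misses`, `false_positives`, `id_swaps`.
#'
#' @param report a `mot_report` from [evaluate_tracking()].
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_mot_report <- function(report, path) {
  pf <- report$per_frame
  obj <- list(
    motp_px = report$motp_px,
    mota = report$mota,
    per_frame = lapply(seq_len(nrow(pf)), function(i) list(
      frame = pf$frame[i], n_gt = pf$n_gt[i], misses = pf$misses[i],
      false_positives = pf$false_positives[i], id_swaps = pf$id_swaps[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
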