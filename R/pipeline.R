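#' Pipeline configuration
#'
#' Bundles the per-stage configurations and global settings used by the
#' `run_*` entry points and the command-line interface.
#'
#' @param segmentation a [seg_config()].
#' @param association an [assoc_config()].
#' @param bridge a [bridge_config()].
#' @param evaluation an [eval_config()].
#' @param scene a [scene_config()] (defaults for simulation).
#' @param frame_rate frames per second assumed when the input carries no
#'   rate; 14 fps is the recommended minimum for reliable association.
#' @param verbose emit per-stage progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = seg_config(),
                            association = assoc_config(),
                            bridge = bridge_config(),
                            evaluation = eval_config(),
                            scene = scene_config(),
                            frame_rate = 14, verbose = FALSE) {
  stopifnot(inherits(segmentation, "seg_config"),
            inherits(association, "assoc_config"),
            inherits(bridge, "bridge_config"),
            inherits(evaluation, "eval_config"),
            inherits(scene, "scene_config"))
  structure(list(segmentation = segmentation, association = association,
                 bridge = bridge, evaluation = evaluation, scene = scene,
                 frame_rate = check_number(frame_rate, "frame_rate", 0,
                                           strict_lower = TRUE),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration file
#'
#' The configuration file is a flat, human-readable key-value document with
#' dotted section names, one setting per line, e.g.
#' \preformatted{
#' segmentation.alpha = 0.002
#' association.delta = 3
#' bridge.max_search_frame = 6
#' frame_rate = 14
#' }
#' Lines starting with `#` are comments. Unset keys keep their defaults.
#'
#' @param path configuration file.
#' @return [read_pipeline_config()] returns a [pipeline_config()];
#'   [write_pipeline_config()] returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- pipeline_config()
  raw <- lapply(unclass(cfg), function(s) if (is.list(s)) unclass(s) else s)
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    val <- if (!is.na(num)) num else if (val %in% c("TRUE", "FALSE"))
      as.logical(val) else val
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      if (!parts %in% c("frame_rate", "verbose"))
        stop(sprintf("unknown config key '%s'", key), call. = FALSE)
      raw[[parts]] <- val
    } else if (length(parts) == 2 && parts[1] %in% names(raw) &&
               is.list(raw[[parts[1]]])) {
      if (!parts[2] %in% names(raw[[parts[1]]]) &&
          !parts[2] %in% c("init_positions", "noise_positions"))
        stop(sprintf("unknown config key '%s'", key), call. = FALSE)
      raw[[parts[1]]][[parts[2]]] <- val
    } else {
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    }
  }
  pipeline_config(
    segmentation = do.call(seg_config,
                           drop_derived(raw$segmentation, seg_config)),
    association = do.call(assoc_config, raw$association),
    bridge = do.call(bridge_config, raw$bridge),
    evaluation = do.call(eval_config, raw$evaluation),
    scene = do.call(scene_config,
                    raw$scene[!vapply(raw$scene, is.null, logical(1))]),
    frame_rate = raw$frame_rate, verbose = isTRUE(raw$verbose))
}

# keep only arguments the constructor accepts
drop_derived <- function(values, constructor) {
  values[intersect(names(values), names(formals(constructor)))]
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()] to serialise.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- character(0)
  for (section in c("segmentation", "association", "bridge", "evaluation",
                    "scene")) {
    s <- unclass(config[[section]])
    for (key in names(s)) {
      v <- s[[key]]
      if (is.null(v) || is.matrix(v)) next
      lines <- c(lines, sprintf("%s.%s = %s", section, key, format(v)))
    }
  }
  lines <- c(lines, sprintf("frame_rate = %s", format(config$frame_rate)),
             sprintf("verbose = %s", config$verbose))
  writeLines(lines, path)
  invisible(path)
}

#' Track organisms in a video and write the results
#'
#' Reads frames, runs the tracking pipeline ([track_frames()]) and writes
#' `detections.csv`, `tracks.csv`, `rejected.csv` and an echo of the
#' configuration (`config.txt`) into the output directory, so every run is
#' reproducible from its inputs.
#'
#' @param input a path accepted by [read_frames()] or a [frame_sequence()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The [track_frames()] result, invisibly.
#' @export
run_track <- function(input, config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  frames <- if (inherits(input, "frame_sequence")) input else
    read_frames(input, frame_rate = config$frame_rate)
  burn <- config$segmentation$burn_in_frames
  if (length(frames) < burn + 1)
    stop(sprintf("input has %d frames but burn_in_frames = %d requires at least %d",
                 length(frames), burn, burn + 1), call. = FALSE)
  if (config$verbose)
    message(sprintf("tracking %d frames of %d x %d px",
                    length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  debug_file <- if (config$verbose) file.path(out_dir, "assignments.jsonl")
  res <- track_frames(frames, config$segmentation, config$association,
                      config$bridge, debug_file = debug_file)
  write_detections(res$detections, file.path(out_dir, "detections.csv"))
  write_tracks(res$trajectories, file.path(out_dir, "tracks.csv"))
  write.csv(res$rejected_noise, file.path(out_dir, "rejected.csv"),
            row.names = FALSE, quote = FALSE)
  write_pipeline_config(config, file.path(out_dir, "config.txt"))
  if (config$verbose)
    message(sprintf("%d trajectories, %d detections rejected as noise",
                    length(unique(res$trajectories$track_id)),
                    nrow(res$rejected_noise)))
  invisible(res)
}

#' Evaluate a tracks CSV against a ground-truth CSV
#'
#' @param tracks_csv,gt_csv file paths (schemas in [msot_csv]).
#' @param config a [pipeline_config()] (its `evaluation$gate` is used).
#' @param out optional path for the JSON report ([write_mot_report()]).
#' @return The `mot_report`.
#' @export
run_evaluate <- function(tracks_csv, gt_csv, config = pipeline_config(),
                         out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- evaluate_tracking(read_tracks(tracks_csv),
                              read_ground_truth(gt_csv),
                              config$evaluation)
  if (!is.null(out)) write_mot_report(report, out)
  report
}

#' Compute kinematics for a tracks CSV
#'
#' Writes `kinematics.csv` and `kinematics_summary.csv` into `out_dir`.
#'
#' @param tracks_csv tracks file (schema in [msot_csv]).
#' @param frame_rate frames per second.
#' @param out_dir output directory.
#' @return The `kinematics_table`, invisibly.
#' @export
run_kinematics <- function(tracks_csv, frame_rate = 14, out_dir) {
  tracks <- read_tracks(tracks_csv)
  kin <- track_kinematics(tracks, frame_rate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_kinematics(kin, file.path(out_dir, "kinematics.csv"))
  write.csv(summarize_individuals(kin),
            file.path(out_dir, "kinematics_summary.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(kin)
}

#' Simulate a scene and write frames plus ground truth
#'
#' @param config a [scene_config()], or the name of a preset:
#'   `"zebrafish"` (960 x 1280 frames, ~1900 px organisms),
#'   `"artemia"` (480 x 640, ~500 px, 10 organisms) or
#'   `"daphnia"` (480 x 640, ~400 px, 10 organisms).
#' @param seed overrides the configuration seed when not `NULL`.
#' @param out_dir output directory; receives the rendered frames (PNG
#'   sequence under `frames/`), `ground_truth.csv` and a configuration echo.
#' @return The ground-truth table, invisibly.
#' @export
run_simulate <- function(config = scene_config(), seed = NULL, out_dir) {
  if (is.character(config)) config <- scene_preset(config)
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(seed)) {
    config$seed <- check_count(seed, "seed")
  }
  gt <- simulate_trajectories(config)
  frames <- render_frames(gt, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_frames(frames, file.path(out_dir, "frames"))
  write_ground_truth(gt, file.path(out_dir, "ground_truth.csv"))
  write_pipeline_config(pipeline_config(scene = config,
                                        frame_rate = config$frame_rate),
                        file.path(out_dir, "config.txt"))
  invisible(gt)
}

#' Scene presets at the scale of the three emulated organism types
#'
#' @param name `"zebrafish"`, `"artemia"` or `"daphnia"`.
#' @return A [scene_config()].
#' @export
scene_preset <- function(name = c("daphnia", "artemia", "zebrafish")) {
  name <- match.arg(name)
  switch(name,
    zebrafish = scene_config(frame_width = 1280, frame_height = 960,
                             n_organisms = 5, organism_radius = 25),
    artemia = scene_config(frame_width = 640, frame_height = 480,
                           n_organisms = 10, organism_radius = 13,
                           n_noise_fragments = 3, noise_appear_prob = 1),
    daphnia = scene_config(frame_width = 640, frame_height = 480,
                           n_organisms = 10, organism_radius = 11))
}
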