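#' Evaluation configuration
#'
#' @param gate maximum hypothesis-to-ground-truth distance (pixels) for a
#'   correspondence; a sensible default is twice the organism radius.
#' @return An object of class `eval_config`.
#' @export
eval_config <- function(gate = 22) {
  structure(list(gate = check_number(gate, "gate", 0, strict_lower = TRUE)),
            class = "eval_config")
}

#' Match tracking output to ground truth, frame by frame
#'
#' For every frame, hypothesis points and ground-truth points are matched
#' one-to-one by minimum-total-cost assignment among pairs within `gate`
#' pixels. Unmatched ground-truth objects count as misses, unmatched
#' hypotheses as false positives, and a matched ground-truth object whose
#' hypothesis identity differs from the identity at its previous matched
#' frame counts one identity swap. Ground-truth rows flagged invisible are
#' kept: an occluded organism still has a true position, which a bridged
#' (interpolated) hypothesis point is expected to recover.
#'
#' @param tracks a `trajectory_set` (columns `track_id`, `frame`, `x`, `y`).
#' @param gt a `ground_truth` table (same columns).
#' @param cfg an [eval_config()].
#' @return A `mot_correspondence` list: `pairs` (data frame `frame`,
#'   `track_id`, `gt_id`, `dist`) and `per_frame` (data frame `frame`,
#'   `n_gt`, `n_hyp`, `misses`, `false_positives`, `id_swaps`).
#' @export
match_to_ground_truth <- function(tracks, gt, cfg = eval_config()) {
  stopifnot(inherits(cfg, "eval_config"))
  f_t <- sort(unique(tracks$frame))
  f_g <- sort(unique(gt$frame))
  if (length(f_t) == 0 || !identical(as.integer(f_g), as.integer(f_t)))
    stop("tracks and ground truth must cover the same frame range",
         call. = FALSE)
  big <- cfg$gate + 1e8
  pairs <- list()
  per_frame <- list()
  last_hyp <- integer(0)   # gt_id -> hypothesis id at previous matched frame
  for (f in f_g) {
    h <- tracks[tracks$frame == f, , drop = FALSE]
    g <- gt[gt$frame == f, , drop = FALSE]
    cost <- build_cost_matrix(h, g)
    if (length(cost) > 0) cost[cost > cfg$gate] <- big
    sol <- solve_assignment(cost)
    ok <- sol$matches[, , drop = FALSE]
    if (nrow(ok) > 0) {
      d <- cost[ok]
      keep <- d <= cfg$gate
      ok <- ok[keep, , drop = FALSE]
    }
    swaps <- 0L
    if (nrow(ok) > 0) {
      hyp_ids <- h$track_id[ok[, "row"]]
      gt_ids <- g$track_id[ok[, "col"]]
      for (i in seq_along(gt_ids)) {
        key <- as.character(gt_ids[i])
        prev <- last_hyp[key]
        if (!is.na(prev) && length(prev) == 1 && !is.null(prev) &&
            prev != hyp_ids[i]) swaps <- swaps + 1L
        last_hyp[key] <- hyp_ids[i]
      }
      pairs[[length(pairs) + 1]] <- data.frame(
        frame = f, track_id = hyp_ids, gt_id = gt_ids,
        dist = sqrt((h$x[ok[, "row"]] - g$x[ok[, "col"]])^2 +
                    (h$y[ok[, "row"]] - g$y[ok[, "col"]])^2))
    }
    per_frame[[length(per_frame) + 1]] <- data.frame(
      frame = f, n_gt = nrow(g), n_hyp = nrow(h),
      misses = nrow(g) - nrow(ok),
      false_positives = nrow(h) - nrow(ok),
      id_swaps = swaps)
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(frame = integer(), track_id = integer(), gt_id = integer(),
               dist = numeric())
  structure(list(pairs = pairs, per_frame = do.call(rbind, per_frame),
                 gate = cfg$gate),
            class = "mot_correspondence")
}

#' Multiple object tracking precision (MOTP)
#'
#' Mean position error of matched hypotheses:
#' `MOTP = sum of matched-pair distances / sum over frames of N_t`, where
#' `N_t` is the number of ground-truth objects in frame t. Smaller is more
#' precise; 0 means every object's position is recovered exactly.
#'
#' @param correspondences a `mot_correspondence`.
#' @return MOTP in pixels, or `NA` (with a warning) when the ground truth
#'   is empty.
#' @export
compute_motp <- function(correspondences) {
  n <- sum(correspondences$per_frame$n_gt)
  if (n == 0) {
    warning("MOTP undefined: ground truth contains no objects")
    return(NA_real_)
  }
  sum(correspondences$pairs$dist) / n
}

#' Multiple object tracking accuracy (MOTA)
#'
#' `MOTA = 1 - (misses + false positives + identity swaps) / total
#' ground-truth objects`. The ideal value is 1; the value is negative when
#' the error count exceeds the object count.
#'
#' @param correspondences a `mot_correspondence`.
#' @return MOTA (dimensionless, at most 1), or `NA` (with a warning) when
#'   the ground truth is empty.
#' @export
compute_mota <- function(correspondences) {
  pf <- correspondences$per_frame
  g <- sum(pf$n_gt)
  if (g == 0) {
    warning("MOTA undefined: ground truth contains no objects")
    return(NA_real_)
  }
  1 - sum(pf$misses + pf$false_positives + pf$id_swaps) / g
}

#' Evaluate tracking output against ground truth
#'
#' Convenience wrapper: computes correspondences and both CLEAR MOT
#' metrics.
#'
#' @inheritParams match_to_ground_truth
#' @return A `mot_report` list: `motp_px`, `mota`, `per_frame`, `pairs`,
#'   `gate`.
#' @export
evaluate_tracking <- function(tracks, gt, cfg = eval_config()) {
  corr <- match_to_ground_truth(tracks, gt, cfg)
  structure(list(motp_px = compute_motp(corr), mota = compute_mota(corr),
                 per_frame = corr$per_frame, pairs = corr$pairs,
                 gate = corr$gate),
            class = "mot_report")
}

#' @export
print.mot_report <- function(x, ...) {
  pf <- x$per_frame
  cat(sprintf("CLEAR MOT report over %d frames (gate %g px)\n",
              nrow(pf), x$gate))
  cat(sprintf("  MOTP: %.4f px   MOTA: %.4f\n", x$motp_px, x$mota))
  cat(sprintf("  misses %d, false positives %d, identity swaps %d (of %d ground-truth objects)\n",
              sum(pf$misses), sum(pf$false_positives), sum(pf$id_swaps),
              sum(pf$n_gt)))
  invisible(x)
}

#' Use a ground-truth table as a trajectory set
#'
#' Reinterprets ground truth as tracking output (e.g. to verify that
#' perfect tracks score MOTP 0 and MOTA 1, or to analyse ground-truth
#' kinematics).
#'
#' @param gt a `ground_truth` table.
#' @return A `trajectory_set` with `interpolated = FALSE` everywhere.
#' @export
gt_as_tracks <- function(gt) {
  out <- data.frame(track_id = gt$track_id, frame = gt$frame,
                    x = gt$x, y = gt$y, interpolated = FALSE)
  out <- out[order(out$track_id, out$frame), ]
  rownames(out) <- NULL
  class(out) <- c("trajectory_set", "data.frame")
  out
}
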