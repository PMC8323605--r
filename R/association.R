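#' Association configuration
#'
#' @param delta dimensionless gate multiplier: a source detection whose
#'   distance to every candidate target exceeds `delta *
#'   median(cost matrix)` is rejected as a segmentation noise fragment.
#' @return An object of class `assoc_config`.
#' @export
assoc_config <- function(delta = 3.0) {
  structure(list(delta = check_number(delta, "delta", 0, strict_lower = TRUE)),
            class = "assoc_config")
}

#' Build the source-target cost matrix
#'
#' Entry (i, j) is the Euclidean pixel distance between source detection i
#' (frame t) and target detection j (frame t + 1).
#'
#' @param sources,targets detection tables for two consecutive frames
#'   (columns `x`, `y`; typically rows of [detect_sequence()] output).
#' @return An `n x m` numeric matrix; the shape is kept even when one side
#'   is empty.
#' @export
build_cost_matrix <- function(sources, targets) {
  n <- nrow(sources); m <- nrow(targets)
  if (n == 0 || m == 0)
    return(matrix(numeric(0), nrow = n, ncol = m))
  dx <- outer(sources$x, targets$x, "-")
  dy <- outer(sources$y, targets$y, "-")
  sqrt(dx^2 + dy^2)
}

#' Gate out noise sources from a cost matrix
#'
#' Computes the threshold `delta * median(d)` over all entries of the
#' frame-pair cost matrix (once, before any rejection) and removes every
#' source row whose minimum entry is strictly larger: such a detection is
#' too far from every candidate target to be a moving organism and is
#' treated as a segmentation noise fragment.
#'
#' @param cost a cost matrix from [build_cost_matrix()].
#' @param cfg an [assoc_config()].
#' @return A list with `cost` (the reduced matrix), `kept` (original row
#'   indices retained), `rejected` (row indices gated out) and `threshold`.
#' @export
reject_noise <- function(cost, cfg = assoc_config()) {
  stopifnot(inherits(cfg, "assoc_config"))
  n <- nrow(cost)
  if (n == 0 || ncol(cost) == 0)
    return(list(cost = cost, kept = seq_len(n), rejected = integer(0),
                threshold = NA_real_))
  thr <- cfg$delta * stats::median(cost)
  row_min <- apply(cost, 1, min)
  rejected <- which(row_min > thr)
  kept <- setdiff(seq_len(n), rejected)
  list(cost = cost[kept, , drop = FALSE], kept = kept, rejected = rejected,
       threshold = thr)
}

#' Associate detections between two consecutive frames
#'
#' The frame-to-frame mapping step: builds the Euclidean cost matrix,
#' gates out noise sources ([reject_noise()]), then computes the
#' minimum-total-cost one-to-one assignment ([solve_assignment()]). Matched
#' targets inherit the identity of their source; sources with no target and
#' targets with no source are reported with their frame stamps so that
#' trajectory fragments can later be bridged.
#'
#' @param points_t,points_t1 detection tables for frames t and t + 1
#'   (columns `frame`, `det_id`, `x`, `y`).
#' @param cfg an [assoc_config()].
#' @return An `assignment_result` list: `matched` (data frame `source_id`,
#'   `target_id`, `cost`), `unmatched_sources`, `unmatched_targets`,
#'   `rejected_noise` (detection rows with frame stamps), and `threshold`.
#' @export
associate <- function(points_t, points_t1, cfg = assoc_config()) {
  stopifnot(inherits(cfg, "assoc_config"))
  cost <- build_cost_matrix(points_t, points_t1)
  gate <- reject_noise(cost, cfg)
  sol <- solve_assignment(gate$cost)
  matched <- data.frame(
    source_id = points_t$det_id[gate$kept[sol$matches[, "row"]]],
    target_id = points_t1$det_id[sol$matches[, "col"]],
    cost = gate$cost[sol$matches]
  )
  res <- list(
    matched = matched,
    unmatched_sources = points_t[gate$kept[sol$unmatched_rows], , drop = FALSE],
    unmatched_targets = points_t1[sol$unmatched_cols, , drop = FALSE],
    rejected_noise = points_t[gate$rejected, , drop = FALSE],
    threshold = gate$threshold
  )
  class(res) <- "assignment_result"
  res
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("assignment: %d matched, %d unmatched sources, %d unmatched targets, %d rejected\n",
              nrow(x$matched), nrow(x$unmatched_sources),
              nrow(x$unmatched_targets), nrow(x$rejected_noise)))
  invisible(x)
}
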