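#' Gap-bridging configuration
#'
#' @param max_search_frame largest frame separation considered when joining
#'   an unmatched trajectory-fragment end to a fragment start: bridging first
#'   looks 2 frames ahead, then extends the search up to this offset
#'   (default 6, i.e. up to 5 missing frames are reconstructed).
#' @return An object of class `bridge_config`.
#' @export
bridge_config <- function(max_search_frame = 6) {
  v <- check_count(max_search_frame, "max_search_frame", 2L)
  structure(list(max_search_frame = v), class = "bridge_config")
}

#' Link detections into trajectory fragments
#'
#' Runs [associate()] over every consecutive frame pair and chains the
#' matches into trajectory fragments: maximal runs of consecutively linked
#' detections. A fragment ends where its detection finds no target
#' (unmatched source) and a fragment begins at a detection with no source
#' (unmatched target, or any detection in the first frame). Sources gated
#' out as noise are removed: their point is deleted from its fragment (a
#' fragment left empty disappears, together with any pool entry pointing at
#' it) and they never enter the bridging pools.
#'
#' @param detections detection table (`frame`, `det_id`, `x`, `y`) covering
#'   at least two frames; frames with no detections are allowed.
#' @param cfg an [assoc_config()].
#' @param frames optional integer vector of the 0-based frames the sequence
#'   covers; defaults to the range present in `detections`.
#' @param debug_file optional path; when given, one JSON line per frame pair
#'   summarising the assignment is appended (debug logging).
#' @return A `fragment_set` list: `fragments` (data frame `fragment_id`,
#'   `frame`, `x`, `y`), `unmatched_sources` and `unmatched_targets`
#'   (fragment-stamped pools for [match_fragments()]), and `rejected_noise`.
#' @export
link_sequence <- function(detections, cfg = assoc_config(), frames = NULL,
                          debug_file = NULL) {
  stopifnot(inherits(cfg, "assoc_config"))
  if (nrow(detections) == 0) {
    return(structure(list(fragments = empty_points(),
                          unmatched_sources = empty_points(),
                          unmatched_targets = empty_points(),
                          rejected_noise = empty_points()[-1]),
                     class = "fragment_set"))
  }
  if (is.null(frames)) frames <- min(detections$frame):max(detections$frame)
  if (length(frames) < 2)
    stop("need detections spanning at least 2 frames", call. = FALSE)

  by_frame <- split(detections, factor(detections$frame, levels = frames))
  pts <- vector("list", 2048)          # fragment_id -> data frame of points
  n_frag <- 0L
  pool_src <- list()                   # fragment ends awaiting a continuation
  pool_tgt <- list()                   # fragment starts with no source
  rejected <- list()
  con <- if (!is.null(debug_file)) file(debug_file, open = "wt") else NULL
  on.exit(if (!is.null(con)) close(con), add = TRUE)

  new_fragment <- function(row) {
    n_frag <<- n_frag + 1L
    pts[[n_frag]] <<- data.frame(fragment_id = n_frag, frame = row$frame,
                                 x = row$x, y = row$y)
    n_frag
  }

  # active: det_id -> fragment id, for the current frame
  first <- by_frame[[1]]
  active <- integer(0)
  if (nrow(first) > 0) {
    active <- vapply(seq_len(nrow(first)),
                     function(i) new_fragment(first[i, ]), integer(1))
    names(active) <- as.character(first$det_id)
  }

  for (t in seq_len(length(frames) - 1)) {
    src <- by_frame[[t]]
    tgt <- by_frame[[t + 1]]
    res <- associate(src, tgt, cfg)
    if (!is.null(con)) {
      writeLines(jsonlite::toJSON(list(
        frame = frames[t], matched = nrow(res$matched),
        unmatched_sources = nrow(res$unmatched_sources),
        unmatched_targets = nrow(res$unmatched_targets),
        rejected = nrow(res$rejected_noise),
        threshold = res$threshold), auto_unbox = TRUE, digits = NA), con)
    }
    nxt <- integer(0)
    # rejected sources: delete the point, drop emptied fragments everywhere
    if (nrow(res$rejected_noise) > 0) {
      rejected[[length(rejected) + 1]] <- res$rejected_noise
      for (i in seq_len(nrow(res$rejected_noise))) {
        fid <- active[[as.character(res$rejected_noise$det_id[i])]]
        p <- pts[[fid]]
        p <- p[p$frame != frames[t], , drop = FALSE]
        pts[[fid]] <- p
        if (nrow(p) == 0) {
          pool_src <- Filter(function(e) e$fragment_id != fid, pool_src)
          pool_tgt <- Filter(function(e) e$fragment_id != fid, pool_tgt)
          pts[fid] <- list(NULL)
        }
      }
    }
    # matched pairs propagate identity
    if (nrow(res$matched) > 0) {
      for (i in seq_len(nrow(res$matched))) {
        fid <- active[[as.character(res$matched$source_id[i])]]
        trow <- tgt[tgt$det_id == res$matched$target_id[i], ]
        pts[[fid]] <- rbind(pts[[fid]],
                            data.frame(fragment_id = fid, frame = trow$frame,
                                       x = trow$x, y = trow$y))
        nxt[[as.character(trow$det_id)]] <- fid
      }
    }
    # unmatched sources close their fragment
    if (nrow(res$unmatched_sources) > 0) {
      for (i in seq_len(nrow(res$unmatched_sources))) {
        row <- res$unmatched_sources[i, ]
        fid <- active[[as.character(row$det_id)]]
        pool_src[[length(pool_src) + 1]] <-
          list(fragment_id = fid, frame = row$frame, x = row$x, y = row$y)
      }
    }
    # unmatched targets open a new fragment
    if (nrow(res$unmatched_targets) > 0) {
      for (i in seq_len(nrow(res$unmatched_targets))) {
        row <- res$unmatched_targets[i, ]
        fid <- new_fragment(row)
        nxt[[as.character(row$det_id)]] <- fid
        pool_tgt[[length(pool_tgt) + 1]] <-
          list(fragment_id = fid, frame = row$frame, x = row$x, y = row$y)
      }
    }
    active <- nxt
  }

  frag_df <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  if (is.null(frag_df)) frag_df <- empty_points()
  pool_df <- function(pool) {
    if (length(pool) == 0) return(empty_points())
    do.call(rbind, lapply(pool, as.data.frame))
  }
  rej_df <- if (length(rejected) == 0) empty_detections() else
    do.call(rbind, rejected)
  structure(list(fragments = frag_df,
                 unmatched_sources = pool_df(pool_src),
                 unmatched_targets = pool_df(pool_tgt),
                 rejected_noise = rej_df),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments (%d points), %d open ends, %d open starts, %d rejected detections\n",
              length(unique(x$fragments$fragment_id)), nrow(x$fragments),
              nrow(x$unmatched_sources), nrow(x$unmatched_targets),
              nrow(x$rejected_noise)))
  invisible(x)
}

#' Estimate positions of a mis-detected or occluded organism
#'
#' Given the last detection before a gap (frame t) and the first detection
#' after it (frame t + j), fills the j - 1 missing frames by uniform linear
#' interpolation: the point for frame t + k is
#' `(x_s + (k/j)(x_t - x_s), y_s + (k/j)(y_t - y_s))`. For j = 2 this is the
#' midpoint of the flanking detections.
#'
#' @param source numeric `(x, y)` of the unmatched source point (frame t).
#' @param target numeric `(x, y)` of the unmatched target point (frame t+j).
#' @param j frame separation (`>= 2`; j - 1 points are produced).
#' @return A data frame with columns `offset` (k = 1..j-1 frames after the
#'   source), `x`, `y`, `interpolated = TRUE`.
#' @export
estimate_missing_positions <- function(source, target, j) {
  j <- check_count(j, "j")
  if (j < 2) stop("`j` must be at least 2 (no gap to fill)", call. = FALSE)
  k <- seq_len(j - 1)
  data.frame(offset = k,
             x = source[[1]] + (k / j) * (target[[1]] - source[[1]]),
             y = source[[2]] + (k / j) * (target[[2]] - source[[2]]),
             interpolated = TRUE)
}

#' Match fragment ends to fragment starts across short gaps
#'
#' Bridges trajectory fragments: unmatched source points (fragment ends)
#' first search for unmatched target points (fragment starts) exactly 2
#' frames ahead; pairs separated by the same gap are matched by
#' minimum-total-cost assignment on their Euclidean distances. The search
#' then extends to 3, 4, ... up to `max_search_frame` frames. Matched pairs
#' leave the pools; leftovers stay unbridged and keep their own identities.
#'
#' @param unmatched_sources,unmatched_targets fragment-stamped pools from
#'   [link_sequence()].
#' @param cfg a [bridge_config()].
#' @return A data frame of joins: `source_fragment`, `target_fragment`,
#'   `source_frame`, `target_frame`, `gap` (= frame separation j), `cost`.
#' @export
match_fragments <- function(unmatched_sources, unmatched_targets,
                            cfg = bridge_config()) {
  stopifnot(inherits(cfg, "bridge_config"))
  joins <- data.frame(source_fragment = integer(), target_fragment = integer(),
                      source_frame = integer(), target_frame = integer(),
                      gap = integer(), cost = numeric())
  us <- unmatched_sources
  ut <- unmatched_targets
  if (nrow(us) == 0 || nrow(ut) == 0) return(joins)
  for (j in 2:cfg$max_search_frame) {
    if (nrow(us) == 0 || nrow(ut) == 0) break
    for (f in sort(unique(us$frame))) {
      s <- us[us$frame == f, , drop = FALSE]
      tt <- ut[ut$frame == f + j, , drop = FALSE]
      if (nrow(s) == 0 || nrow(tt) == 0) next
      cost <- build_cost_matrix(s, tt)
      sol <- solve_assignment(cost)
      if (nrow(sol$matches) == 0) next
      joins <- rbind(joins, data.frame(
        source_fragment = s$fragment_id[sol$matches[, "row"]],
        target_fragment = tt$fragment_id[sol$matches[, "col"]],
        source_frame = f,
        target_frame = f + j,
        gap = j,
        cost = cost[sol$matches]
      ))
      us <- us[!us$fragment_id %in% joins$source_fragment, , drop = FALSE]
      ut <- ut[!ut$fragment_id %in% joins$target_fragment, , drop = FALSE]
    }
  }
  joins
}

#' Merge fragments and joins into final trajectories
#'
#' Concatenates chains of joined fragments into complete per-identity
#' trajectories, inserting linearly interpolated points
#' ([estimate_missing_positions()]) for every bridged gap frame. Final
#' identities are renumbered 1..K in order of first appearance.
#'
#' @param fragments fragment point table from [link_sequence()] (or a
#'   `fragment_set`, whose `$fragments` is used).
#' @param joins join table from [match_fragments()] (may have zero rows).
#' @return A `trajectory_set` data frame: `track_id`, `frame`, `x`, `y`,
#'   `interpolated`, sorted by track then frame; each track covers a
#'   contiguous frame range.
#' @export
merge_fragments <- function(fragments, joins = NULL) {
  if (inherits(fragments, "fragment_set")) fragments <- fragments$fragments
  if (is.null(joins)) joins <- match_fragments(empty_points(), empty_points())
  if (nrow(fragments) == 0) {
    out <- data.frame(track_id = integer(), frame = integer(),
                      x = numeric(), y = numeric(), interpolated = logical())
    class(out) <- c("trajectory_set", "data.frame")
    return(out)
  }
  if (anyDuplicated(joins$source_fragment) ||
      anyDuplicated(joins$target_fragment))
    stop("conflicting joins: a fragment may be joined at most once per side",
         call. = FALSE)
  frag_ids <- unique(fragments$fragment_id)
  nxt <- structure(joins$target_fragment,
                   names = as.character(joins$source_fragment))
  is_target <- frag_ids %in% joins$target_fragment
  heads <- frag_ids[!is_target]
  first_frame <- vapply(heads, function(id)
    min(fragments$frame[fragments$fragment_id == id]), numeric(1))
  heads <- heads[order(first_frame, heads)]
  by_frag <- split(fragments, fragments$fragment_id)

  out <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    id <- heads[k]
    seen <- character(0)
    chain <- list()
    repeat {
      key <- as.character(id)
      if (key %in% seen) stop("cyclic joins detected", call. = FALSE)
      seen <- c(seen, key)
      p <- by_frag[[key]]
      p <- p[order(p$frame), , drop = FALSE]
      chain[[length(chain) + 1]] <-
        data.frame(frame = p$frame, x = p$x, y = p$y, interpolated = FALSE)
      if (!key %in% names(nxt)) break
      nid <- nxt[[key]]
      q <- by_frag[[as.character(nid)]]
      q <- q[order(q$frame), , drop = FALSE]
      last <- p[nrow(p), ]
      j <- q$frame[1] - last$frame
      interp <- estimate_missing_positions(c(last$x, last$y),
                                           c(q$x[1], q$y[1]), j)
      chain[[length(chain) + 1]] <-
        data.frame(frame = last$frame + interp$offset,
                   x = interp$x, y = interp$y, interpolated = TRUE)
      id <- nid
    }
    tr <- do.call(rbind, chain)
    tr <- tr[order(tr$frame), , drop = FALSE]
    if (any(diff(tr$frame) != 1))
      stop("internal error: merged trajectory is not contiguous")
    out[[k]] <- cbind(track_id = k, tr)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trajectory_set", "data.frame")
  res
}

#' Track organisms through a frame sequence
#'
#' The full tracking pipeline: adaptive-mixture foreground estimation,
#' mask cleaning, centroid detection, frame-to-frame association with the
#' median-distance noise gate, and gap bridging with linear position
#' estimation for mis-detected or occluded organisms.
#'
#' @param frames a [frame_sequence()] (or list of grayscale matrices).
#' @param seg a [seg_config()].
#' @param assoc an [assoc_config()].
#' @param bridge a [bridge_config()].
#' @param debug_file optional path for per-frame assignment JSON lines.
#' @return A `track_result` list: `trajectories` (a `trajectory_set`),
#'   `detections`, `fragments` (a `fragment_set`), `joins`,
#'   `rejected_noise`, and the configurations used.
#' @export
track_frames <- function(frames, seg = seg_config(), assoc = assoc_config(),
                         bridge = bridge_config(), debug_file = NULL) {
  masks <- estimate_foreground(frames, seg)
  cleaned <- clean_mask(masks, seg)
  detections <- detect_sequence(cleaned)
  frags <- link_sequence(detections, assoc,
                         frames = 0:(length(frames) - 1),
                         debug_file = debug_file)
  joins <- match_fragments(frags$unmatched_sources, frags$unmatched_targets,
                           bridge)
  trajectories <- merge_fragments(frags$fragments, joins)
  structure(list(trajectories = trajectories, detections = detections,
                 fragments = frags, joins = joins,
                 rejected_noise = frags$rejected_noise,
                 config = list(segmentation = seg, association = assoc,
                               bridge = bridge)),
            class = "track_result")
}

#' @export
print.track_result <- function(x, ...) {
  cat(sprintf("track_result: %d trajectories from %d detections (%d frames)\n",
              length(unique(x$trajectories$track_id)), nrow(x$detections),
              length(unique(x$detections$frame))))
  cat(sprintf("  %d fragments bridged over %d joins; %d detections rejected as noise\n",
              length(unique(x$fragments$fragments$fragment_id)),
              nrow(x$joins), nrow(x$rejected_noise)))
  invisible(x)
}

#' @export
summary.track_result <- function(object, ...) {
  tr <- object$trajectories
  spans <- do.call(rbind, lapply(split(tr, tr$track_id), function(p) {
    data.frame(track_id = p$track_id[1], first_frame = min(p$frame),
               last_frame = max(p$frame), n_points = nrow(p),
               n_interpolated = sum(p$interpolated))
  }))
  rownames(spans) <- NULL
  spans
}

#' Plot a trajectory set
#'
#' Draws each identity's path in image coordinates (y axis pointing down,
#' as in the video frames); interpolated points are marked with open
#' circles.
#'
#' @param x a `trajectory_set`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.trajectory_set <- function(x, ...) {
  ids <- unique(x$track_id)
  cols <- grDevices::hcl.colors(max(length(ids), 2), "Dark 3")
  graphics::plot(NA, xlim = range(x$x), ylim = rev(range(x$y)),
                 xlab = "x (column, px)", ylab = "y (row, px)", asp = 1, ...)
  for (k in seq_along(ids)) {
    p <- x[x$track_id == ids[k], ]
    graphics::lines(p$x, p$y, col = cols[k])
    if (any(p$interpolated))
      graphics::points(p$x[p$interpolated], p$y[p$interpolated],
                       col = cols[k], pch = 1, cex = 0.8)
  }
  invisible(x)
}
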