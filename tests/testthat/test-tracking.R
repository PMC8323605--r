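det_table <- function(tracks) {
  # build a detection table from per-identity positions, shuffling ids
  out <- do.call(rbind, lapply(split(tracks, tracks$frame), function(p) {
    p$det_id <- seq_len(nrow(p))
    p[, c("frame", "det_id", "x", "y")]
  }))
  rownames(out) <- NULL
  out
}

test_that("link_sequence chains clean detections into one fragment per organism", {
  t1 <- straight_track(50, 10, 10, 2, 0)
  t2 <- straight_track(50, 10, 100, 2, 1)
  det <- det_table(rbind(t1, t2)[, c("frame", "x", "y")])
  fs <- link_sequence(det)
  expect_equal(length(unique(fs$fragments$fragment_id)), 2)
  expect_equal(nrow(fs$fragments), 100)
  expect_equal(nrow(fs$unmatched_sources), 0)
  expect_equal(nrow(fs$unmatched_targets), 0)
})

test_that("a deleted detection splits a trajectory into two pooled fragments", {
  tr <- straight_track(30, 5, 5, 3, 1)
  det <- det_table(tr[, c("frame", "x", "y")])
  det <- det[det$frame != 10, ]
  fs <- link_sequence(det)
  frag_ids <- unique(fs$fragments$fragment_id)
  expect_length(frag_ids, 2)
  spans <- tapply(fs$fragments$frame, fs$fragments$fragment_id, range)
  expect_equal(sort(unname(unlist(spans))), c(0, 9, 11, 29))
  expect_equal(fs$unmatched_sources$frame, 9)
  expect_equal(fs$unmatched_targets$frame, 11)

  # and merging with the bridge restores one gap-free trajectory
  joins <- match_fragments(fs$unmatched_sources, fs$unmatched_targets)
  expect_equal(nrow(joins), 1)
  expect_equal(joins$gap, 2)
  traj <- merge_fragments(fs$fragments, joins)
  expect_equal(length(unique(traj$track_id)), 1)
  expect_equal(traj$frame, 0:29)
  expect_equal(which(traj$interpolated), 11)   # frame 10
  p10 <- traj[traj$frame == 10, ]
  expect_equal(p10$x, tr$x[tr$frame == 10])
  expect_equal(p10$y, tr$y[tr$frame == 10])
})

test_that("empty detection tables give empty outputs", {
  fs <- link_sequence(empty_det <- data.frame(frame = integer(),
                                              det_id = integer(),
                                              x = numeric(), y = numeric()))
  expect_equal(nrow(fs$fragments), 0)
  expect_equal(nrow(merge_fragments(fs$fragments,
                                    match_fragments(fs$unmatched_sources,
                                                    fs$unmatched_targets))), 0)
})

test_that("estimate_missing_positions interpolates linearly (Eq. midpoint first)", {
  # midpoint for a two-frame gap
  p <- estimate_missing_positions(c(0, 0), c(4, 8), 2)
  expect_equal(nrow(p), 1)
  expect_equal(c(p$x, p$y), c(2, 4))

  # uniform spacing for a four-frame separation
  p2 <- estimate_missing_positions(c(0, 0), c(8, 4), 4)
  expect_equal(p2$x, c(2, 4, 6))
  expect_equal(p2$y, c(1, 2, 3))
  # the k = 1 point is exactly the single-step estimate x_s + (1/j)(x_t - x_s)
  expect_equal(c(p2$x[1], p2$y[1]), c(0 + (1 / 4) * 8, 0 + (1 / 4) * 4))

  # zero displacement stays put
  p3 <- estimate_missing_positions(c(5, 5), c(5, 5), 6)
  expect_true(all(p3$x == 5 & p3$y == 5))
  expect_true(all(p3$interpolated))

  expect_error(estimate_missing_positions(c(0, 0), c(1, 1), 1), "at least 2")
})

test_that("fragment bridging respects the search window and assignment costs", {
  src <- data.frame(fragment_id = 1L, frame = 9L, x = 10, y = 10)
  tgt <- data.frame(fragment_id = 2L, frame = 11L, x = 12, y = 10)
  j <- match_fragments(src, tgt)
  expect_equal(j$gap, 2)

  # separation 8 exceeds the default window of 6: no join
  tgt_far <- data.frame(fragment_id = 2L, frame = 17L, x = 12, y = 10)
  expect_equal(nrow(match_fragments(src, tgt_far)), 0)

  # two simultaneous gaps rejoin their own continuations
  src2 <- data.frame(fragment_id = c(1L, 2L), frame = 9L,
                     x = c(0, 100), y = c(0, 0))
  tgt2 <- data.frame(fragment_id = c(3L, 4L), frame = 11L,
                     x = c(104, 2), y = c(0, 0))
  j2 <- match_fragments(src2, tgt2)
  j2 <- j2[order(j2$source_fragment), ]
  expect_equal(j2$target_fragment, c(4L, 3L))

  # a closer gap is bridged before a longer one for the same source pool
  srcs <- data.frame(fragment_id = 1L, frame = 10L, x = 0, y = 0)
  tgts <- data.frame(fragment_id = c(2L, 3L), frame = c(12L, 13L),
                     x = c(50, 0.5), y = 0)
  j3 <- match_fragments(srcs, tgts)
  expect_equal(j3$target_fragment, 2L)  # j = 2 searched before j = 3
})

test_that("merge_fragments renumbers by first appearance and fills chains", {
  frags <- rbind(
    data.frame(fragment_id = 5L, frame = 0:4, x = 0:4, y = 0),
    data.frame(fragment_id = 2L, frame = 7:10, x = 7:10, y = 0),
    data.frame(fragment_id = 9L, frame = 13:15, x = 13:15, y = 0))
  joins <- data.frame(source_fragment = c(5L, 2L), target_fragment = c(2L, 9L),
                      source_frame = c(4L, 10L), target_frame = c(7L, 13L),
                      gap = c(3L, 3L), cost = 0)
  traj <- merge_fragments(frags, joins)
  expect_equal(length(unique(traj$track_id)), 1)
  expect_equal(traj$frame, 0:15)
  expect_equal(traj$x, 0:15)            # collinear fill
  expect_equal(sum(traj$interpolated), 4)

  # no joins: fragments renumbered in order of first appearance
  traj2 <- merge_fragments(frags, NULL)
  expect_equal(unique(traj2$track_id[traj2$frame <= 4]), 1)
  expect_equal(unique(traj2$track_id[traj2$frame >= 13]), 3)

  # idempotence: merging an already-merged set with no joins is the identity
  refrag <- traj
  names(refrag)[names(refrag) == "track_id"] <- "fragment_id"
  traj3 <- merge_fragments(refrag[, c("fragment_id", "frame", "x", "y")], NULL)
  expect_equal(traj3[, c("track_id", "frame", "x", "y")],
               traj[, c("track_id", "frame", "x", "y")])

  # conflicting joins are refused
  bad <- rbind(joins, data.frame(source_fragment = 5L, target_fragment = 9L,
                                 source_frame = 4L, target_frame = 13L,
                                 gap = 9L, cost = 0))
  expect_error(merge_fragments(frags, bad), "conflicting")
})

test_that("interpolated points are collinear and conservation holds", {
  set.seed(31)
  for (rep in 1:25) {
    j <- sample(2:6, 1)
    s <- stats::runif(2, 0, 100)
    t <- stats::runif(2, 0, 100)
    p <- estimate_missing_positions(s, t, j)
    # collinearity: cross product of (p - s) and (t - s) vanishes
    expect_equal((p$x - s[1]) * (t[2] - s[2]) - (p$y - s[2]) * (t[1] - s[1]),
                 rep(0, j - 1), tolerance = 1e-9)
    # uniform spacing
    expect_equal(diff(p$x), rep((t[1] - s[1]) / j, j - 2), tolerance = 1e-9)
  }

  # trajectory conservation: non-interpolated points = detections kept
  tr <- straight_track(40, 5, 5, 2.5, 1)
  det <- det_table(tr[, c("frame", "x", "y")])
  det <- det[!det$frame %in% c(12, 25), ]
  fs <- link_sequence(det)
  traj <- merge_fragments(fs$fragments,
                          match_fragments(fs$unmatched_sources,
                                          fs$unmatched_targets))
  expect_equal(sum(!traj$interpolated), nrow(det) - nrow(fs$rejected_noise))
  expect_equal(sum(traj$interpolated), 2)
})

test_that("crossing-pair scenes are recovered or split exactly at the window", {
  # bridgeable gap: two identities, interpolated gap, no swaps
  gt <- fixture_crossing(3)
  cfg <- attr(gt, "config")
  res <- track_frames(render_frames(gt, cfg))
  expect_equal(length(unique(res$trajectories$track_id)), 2)
  rep <- evaluate_tracking(res$trajectories, gt,
                           eval_config(gate = 2 * cfg$organism_radius))
  expect_equal(sum(rep$per_frame$id_swaps), 0)
  occl <- attr(gt, "occluded_frames")
  expect_equal(sort(res$trajectories$frame[res$trajectories$interpolated]),
               occl)

  # gap beyond the window: intentionally left unbridged
  gt7 <- fixture_crossing(7)
  res7 <- track_frames(render_frames(gt7, attr(gt7, "config")))
  expect_gt(length(unique(res7$trajectories$track_id)), 2)
})
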