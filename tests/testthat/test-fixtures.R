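test_that("trajectory simulation is deterministic and respects the no-motion case", {
  cfg <- small_scene(seed = 4, n_frames = 40)
  expect_identical(simulate_trajectories(cfg), simulate_trajectories(cfg))

  quiet <- small_scene(seed = 2, n_frames = 40, p_start_move = 0)
  gt <- simulate_trajectories(quiet)
  for (id in unique(gt$track_id)) {
    p <- gt[gt$track_id == id, ]
    expect_equal(diff(p$x), rep(0, nrow(p) - 1))
    expect_equal(diff(p$y), rep(0, nrow(p) - 1))
  }
})

test_that("ground truth has one in-bounds position per identity per frame", {
  cfg <- small_scene(seed = 9, n_frames = 80, n_organisms = 3)
  gt <- simulate_trajectories(cfg)
  expect_equal(nrow(gt), 3 * 80)
  expect_false(anyDuplicated(gt[, c("track_id", "frame")]) > 0)
  expect_true(all(gt$x >= 0 & gt$x < cfg$frame_width))
  expect_true(all(gt$y >= 0 & gt$y < cfg$frame_height))
  # identities separated by construction (collision avoidance)
  for (f in unique(gt$frame)) {
    p <- gt[gt$frame == f, ]
    d <- stats::dist(p[, c("x", "y")])
    expect_gte(min(d), cfg$min_separation - 1e-9)
  }
})

test_that("activity fraction converges to the Markov stationary distribution", {
  # p_start/(p_start+p_stop) = 0.075
  cfg <- scene_config(frame_width = 400, frame_height = 300, n_frames = 10000,
                      n_organisms = 1, p_start_move = 0.06,
                      p_stop_move = 0.74, seed = 3)
  gt <- simulate_trajectories(cfg)
  moving <- diff(gt$x)^2 + diff(gt$y)^2 > 0
  expect_lt(abs(mean(moving) - 0.075), 0.01)
})

test_that("overcrowded placement fails with a clear error", {
  cfg <- scene_config(frame_width = 60, frame_height = 60, n_frames = 5,
                      n_organisms = 12, organism_radius = 6, seed = 1)
  expect_error(simulate_trajectories(cfg), "min_separation")
})

test_that("crossing pair merges for exactly gap_frames frames and is collinear", {
  for (g in c(1L, 5L)) {
    gt <- fixture_crossing(g)
    cfg <- attr(gt, "config")
    occl <- attr(gt, "occluded_frames")
    expect_length(occl, g)
    expect_equal(occl, seq(min(occl), by = 1, length.out = g))
    fr <- render_frames(gt, cfg)
    thr <- (cfg$organism_intensity + cfg$background_intensity) / 2
    ncomp <- vapply(seq_along(fr), function(t) {
      max(msotrack:::label_components8(fr[[t]] < thr))
    }, numeric(1))
    expect_equal(which(ncomp == 1) - 1L, occl)
    # occluded organism's true gap positions lie on the segment between its
    # last and next visible positions
    b <- gt[gt$track_id == 2L, ]
    pre <- b[b$frame == min(occl) - 1L, ]
    post <- b[b$frame == max(occl) + 1L, ]
    for (f in occl) {
      lambda <- (f - pre$frame) / (post$frame - pre$frame)
      p <- b[b$frame == f, ]
      expect_equal(p$x, pre$x + lambda * (post$x - pre$x), tolerance = 1e-12)
      expect_equal(p$y, pre$y + lambda * (post$y - pre$y), tolerance = 1e-12)
    }
    expect_true(all(b$visible[b$frame %in% occl] == 0))
  }
  expect_error(make_crossing_pair(small_scene(n_frames = 5), 10), "gap_frames")
})

test_that("rendering matches its ground truth", {
  # organism-free, noise-free scene renders the constant background
  cfg0 <- small_scene(seed = 2, n_frames = 3, n_organisms = 0,
                      additive_noise_sd = 0)
  fr0 <- render_frames(simulate_trajectories(cfg0), cfg0)
  for (f in fr0) expect_true(all(f == cfg0$background_intensity))

  # thresholding a static single-organism frame recovers the blob centroid
  cfg1 <- scene_config(frame_width = 120, frame_height = 100, n_frames = 2,
                       n_organisms = 1, organism_radius = 9,
                       p_start_move = 0, additive_noise_sd = 0, seed = 5,
                       init_positions = cbind(61.4, 48.8))
  gt1 <- simulate_trajectories(cfg1)
  fr1 <- render_frames(gt1, cfg1)
  m <- fr1[[1]] < 115
  idx <- which(m, arr.ind = TRUE)
  expect_lt(abs(mean(idx[, "col"] - 1) - gt1$x[1]), 0.5)
  expect_lt(abs(mean(idx[, "row"] - 1) - gt1$y[1]), 0.5)

  # two organisms closer than 2 radii render as one connected component
  cfg2 <- scene_config(frame_width = 120, frame_height = 100, n_frames = 2,
                       n_organisms = 2, organism_radius = 8,
                       p_start_move = 0, additive_noise_sd = 0,
                       min_separation = 0, seed = 6,
                       init_positions = rbind(c(50, 50), c(60, 50)))
  fr2 <- render_frames(simulate_trajectories(cfg2), cfg2)
  expect_equal(max(msotrack:::label_components8(fr2[[1]] < 115)), 1)

  # rendering is deterministic given the seed
  cfg3 <- small_scene(seed = 8, n_frames = 5, n_noise_fragments = 2,
                      noise_drift = 1)
  gt3 <- simulate_trajectories(cfg3)
  expect_identical(render_frames(gt3, cfg3), render_frames(gt3, cfg3))
})

test_that("isolated rendered blobs sit within half a pixel of ground truth", {
  cfg <- small_scene(seed = 13, n_frames = 30, n_organisms = 3,
                     additive_noise_sd = 0, frame_width = 300,
                     frame_height = 240)
  gt <- simulate_trajectories(cfg)
  fr <- render_frames(gt, cfg)
  for (t in c(1, 15, 30)) {
    lab <- msotrack:::label_components8(fr[[t]] < 115)
    g <- gt[gt$frame == t - 1, ]
    for (k in seq_len(max(lab))) {
      idx <- which(lab == k, arr.ind = TRUE)
      cx <- mean(idx[, "col"] - 1); cy <- mean(idx[, "row"] - 1)
      expect_lt(min(sqrt((g$x - cx)^2 + (g$y - cy)^2)), 0.5)
    }
  }
})
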