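test_that("a fully static scene is absorbed into the background", {
  cfg <- small_scene(seed = 4, n_frames = 50, p_start_move = 0)
  fr <- render_frames(simulate_trajectories(cfg), cfg)
  sc <- seg_config(organism_area = 200)
  masks <- estimate_foreground(fr, sc)
  for (t in (sc$burn_in_frames + 1):length(masks)) {
    expect_lte(mean(masks[[t]]), 0.001)
  }
})

test_that("a moving blob is captured almost entirely while it moves", {
  T <- 60
  x <- pmin(15 + (seq_len(T) - 1) * 6, 180)
  gt <- data.frame(track_id = 1L, frame = 0:(T - 1), x = x, y = 60,
                   visible = 1L)
  cfg <- scene_config(frame_width = 200, frame_height = 120, n_frames = T,
                      n_organisms = 1, organism_radius = 8,
                      additive_noise_sd = 2, seed = 6)
  fr <- render_frames(gt, cfg)
  masks <- estimate_foreground(fr, seg_config(organism_area = 200))
  for (t in 27:29) {   # moving frames after burn-in
    rendered <- disk_mask(120, 200, x[t], 60, 8)
    expect_gte(sum(masks[[t]] & rendered) / sum(rendered), 0.8)
  }
})

test_that("a stopped blob stays detected for about log(1-c_f)/log(1-alpha) frames", {
  # alpha = 0.005, c_f = 0.25 -> ~57 frames, tolerance +/-30%
  T <- 170
  x <- pmin(20 + (seq_len(T) - 1) * 7, 293)
  gt <- data.frame(track_id = 1L, frame = 0:(T - 1), x = x, y = 60,
                   visible = 1L)
  cfg <- scene_config(frame_width = 340, frame_height = 120, n_frames = T,
                      n_organisms = 1, additive_noise_sd = 2, seed = 6)
  fr <- render_frames(gt, cfg)
  sc <- seg_config(alpha = 0.005, c_f = 0.25)
  det <- detect_sequence(clean_mask(estimate_foreground(fr, sc), sc))
  stop_frame <- which(x == 293)[1] - 1
  persist <- sum(vapply(stop_frame:(T - 1),
                        function(f) any(det$frame == f), logical(1)))
  expected <- log(1 - sc$c_f) / log(1 - sc$alpha)
  expect_gte(persist, 0.7 * expected)
  expect_lte(persist, 1.3 * expected)
})

test_that("clean_mask applies median, diamond erosion and size filtering in order", {
  sc <- seg_config(min_area = 3, max_area = 1e4, organism_area = 12)
  empty <- matrix(FALSE, 20, 20)
  expect_equal(clean_mask(empty, sc), empty)

  # a single isolated pixel is removed by the 3x3 median
  single <- empty; single[10, 10] <- TRUE
  expect_equal(sum(clean_mask(single, seg_config(erosion_radius = 0,
                                                 min_area = 0, max_area = 10,
                                                 organism_area = 4))), 0)

  # two 4x4 blobs connected by a 1-px bridge separate after erosion r=1
  m <- matrix(FALSE, 20, 20)
  m[5:8, 3:6] <- TRUE
  m[5:8, 12:15] <- TRUE
  m[6, 7:11] <- TRUE
  cleaned <- clean_mask(m, seg_config(median_window = 1, erosion_radius = 1,
                                      min_area = 1, max_area = 400,
                                      organism_area = 4))
  expect_equal(max(msotrack:::label_components8(cleaned)), 2)
})

test_that("the size filter is idempotent", {
  set.seed(42)
  m <- matrix(stats::runif(40 * 40) < 0.3, 40, 40)
  once <- msotrack:::filter_by_area(m, 5, 60)
  expect_identical(msotrack:::filter_by_area(once, 5, 60), once)
})

test_that("detect_organisms reports 8-connected centroids in raster order", {
  expect_equal(nrow(detect_organisms(matrix(FALSE, 10, 10))), 0)

  # 5x5 square with top-left pixel at x=10, y=20 (0-based) -> centroid (12, 22)
  m <- matrix(FALSE, 40, 40)
  m[21:25, 11:15] <- TRUE
  d <- detect_organisms(m, frame_index = 7L)
  expect_equal(d$frame, 7L)
  expect_equal(d$x, 12)
  expect_equal(d$y, 22)

  # two disjoint blobs -> ids 1, 2; count equals component count
  m2 <- m; m2[5:6, 5:6] <- TRUE
  d2 <- detect_organisms(m2)
  expect_equal(d2$det_id, c(1L, 2L))
  expect_equal(nrow(d2), max(msotrack:::label_components8(m2)))

  # diagonal contact is one component under 8-connectivity
  m3 <- matrix(FALSE, 6, 6)
  m3[2, 2] <- TRUE; m3[3, 3] <- TRUE
  expect_equal(nrow(detect_organisms(m3)), 1)
})

test_that("estimate_foreground validates its inputs", {
  fr <- lapply(1:5, function(i) matrix(100, 10, 10))
  expect_error(estimate_foreground(list(), seg_config()), "empty")
  expect_error(estimate_foreground(fr, seg_config(burn_in_frames = 10)),
               "burn_in")
  bad <- fr; bad[[3]] <- matrix(100, 8, 10)
  expect_error(estimate_foreground(bad, seg_config(burn_in_frames = 2)),
               "dimensions")
})

test_that("noiseless well-separated organisms are recovered frame-perfect", {
  cfg <- scene_config(frame_width = 320, frame_height = 240, n_frames = 80,
                      n_organisms = 3, additive_noise_sd = 0, seed = 21)
  gt <- simulate_trajectories(cfg)
  fr <- render_frames(gt, cfg)
  sc <- seg_config()
  det <- detect_sequence(clean_mask(estimate_foreground(fr, sc), sc))
  burn <- sc$burn_in_frames
  for (f in burn:(cfg$n_frames - 1)) {
    d <- det[det$frame == f, ]
    g <- gt[gt$frame == f, ]
    expect_equal(nrow(d), cfg$n_organisms)
    for (i in seq_len(nrow(d))) {
      expect_lt(min(sqrt((g$x - d$x[i])^2 + (g$y - d$y[i])^2)), 2)
    }
  }
})
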