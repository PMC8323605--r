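# Independent oracles and shared fixture builders.

# all permutations of a vector (for the brute-force assignment oracle)
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, ncol = length(v)))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]))
  }))
}

# exhaustive minimum-cost one-to-one matching over all injections
brute_assignment_cost <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(0)
  if (n > m) return(brute_assignment_cost(t(cost)))
  best <- Inf
  for (cols in utils::combn(m, n, simplify = FALSE)) {
    pp <- all_perms(cols)
    for (r in seq_len(nrow(pp))) {
      best <- min(best, sum(cost[cbind(seq_len(n), pp[r, ])]))
    }
  }
  best
}

# rasterised disk mask oracle (0-based centre coordinates)
disk_mask <- function(h, w, x, y, r) {
  cols <- matrix(0:(w - 1), h, w, byrow = TRUE)
  rows <- matrix(0:(h - 1), h, w)
  (cols - x)^2 + (rows - y)^2 <= r^2
}

# a small fast scene for unit tests (organism area ~200 px)
small_scene <- function(seed = 1, n_frames = 60, n_organisms = 2,
                        frame_width = 200, frame_height = 160,
                        additive_noise_sd = 2, ...) {
  scene_config(frame_width = frame_width, frame_height = frame_height,
               n_frames = n_frames, n_organisms = n_organisms,
               organism_radius = 8, additive_noise_sd = additive_noise_sd,
               seed = seed, ...)
}

# study-condition fixtures shared by property and acceptance tests ----------

# clean scene: 5 well-separated bursty organisms, default Daphnia-scale frame
fixture_clean_scene <- function(seed) {
  scene_config(n_frames = 200, n_organisms = 5, additive_noise_sd = 2,
               seed = seed)
}

# crossing pair with an engineered occlusion of `gap` frames
fixture_crossing <- function(gap, seed = 5) {
  cfg <- scene_config(frame_width = 640, frame_height = 480, n_frames = 90,
                      n_organisms = 2, additive_noise_sd = 2, seed = seed)
  make_crossing_pair(cfg, gap)
}

# three organisms confined to a small housing well plus five peripheral
# blinking noise fragments; analysed with delta = 2 (see vignette)
fixture_noise_scene <- function(seed) {
  scene_config(n_frames = 151, n_organisms = 3, organism_radius = 11,
               p_start_move = 0.03, burst_speed = 3,
               arena = c(280, 200, 360, 280),
               n_noise_fragments = 5, noise_fragment_area = 200,
               noise_appear_prob = 0.12, noise_drift = 0,
               additive_noise_sd = 2, seed = seed,
               init_positions = rbind(c(290, 210), c(320, 270), c(352, 215)),
               noise_positions = rbind(c(25, 25), c(615, 25), c(25, 455),
                                       c(615, 455), c(25, 100)))
}

# straight-line track data frame helper
straight_track <- function(n, x0 = 0, y0 = 0, dx = 1, dy = 0, id = 1L) {
  data.frame(track_id = id, frame = 0:(n - 1),
             x = x0 + dx * (0:(n - 1)), y = y0 + dy * (0:(n - 1)),
             interpolated = FALSE)
}
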