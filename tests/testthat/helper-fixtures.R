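# Shared fixtures: compact phantoms and keypoint-set builders.

# Half-resolution phantom (scaled intrinsics) for fast unit tests; the
# camera distance of 1.9 m keeps the tallest bodies and the hoof-adjacent
# ground inside the vertical frustum of the sensor model.
test_spec <- function(...) {
  phantom_spec(camera_distance_m = 1.9,
               image_size = c(424L, 240L),
               intrinsics = camera_intrinsics(262.5, 262.5, 159.75, 119.75),
               ...)
}

full_spec <- function(...) phantom_spec(camera_distance_m = 1.9, ...)

# The 20 seeded specifications spanning the study's trait ranges
# (heights 1.24-1.48 m, lengths 1.39-1.78 m, cannon 18-24 cm girth).
recovery_specs <- function(...) {
  lapply(1:20, function(i) {
    wh <- 1.24 + (1.48 - 1.24) * (i - 1) / 19
    hh <- wh + 0.04 * ifelse(i %% 2 == 1, 1, -0.5)
    L <- 1.39 + (1.78 - 1.39) * ((i * 7) %% 20) / 19
    circ_cm <- 18 + 6 * ((i * 3) %% 20) / 19
    phantom_spec(withers_height_m = wh, hip_height_m = hh,
                 body_length_m = L, cannon_diameter_m = circ_cm / 100 / pi,
                 camera_distance_m = 1.9, seed = i, ...)
  })
}

sigmoid_ref <- function(x) 1 / (1 + exp(-x))

# Plain numeric matrix from a depth_map (drops class and diagnostics).
plain <- function(d) {
  d <- unclass(d)
  attr(d, "passes_used") <- NULL
  attr(d, "unfilled") <- NULL
  d
}

# Quick keypoint-set builder: all six canonical landmarks at given coords.
make_kps <- function(u, v, visibility = 2L, confidence = 1, bbox_area = 10000) {
  keypoint_set(data.frame(name = keypoint_names(), u = u, v = v,
                          visibility = visibility, confidence = confidence,
                          stringsAsFactors = FALSE),
               bbox_area = bbox_area)
}

# Brute-force single-pass ring-mean completion: explicitly enumerates the
# 16 offsets at Chebyshev distance 2. Independent oracle for complete_depth.
brute_ring_pass <- function(d) {
  out <- d
  H <- nrow(d); W <- ncol(d)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (d[i, j] != 0) next
    vals <- c()
    for (m in (i - 2):(i + 2)) for (n in (j - 2):(j + 2)) {
      if (max(abs(m - i), abs(n - j)) != 2) next
      if (m < 1 || m > H || n < 1 || n > W) next
      if (d[m, n] > 0) vals <- c(vals, d[m, n])
    }
    if (length(vals)) out[i, j] <- mean(vals)
  }
  out
}

# Random sparse-hole depth map for oracle comparisons.
random_holey_map <- function(h = 20, w = 20, hole_frac = 0.2) {
  d <- matrix(stats::runif(h * w, 0.5, 4.5), h, w)
  holes <- sample(h * w, round(hole_frac * h * w))
  d[holes] <- 0
  d
}
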