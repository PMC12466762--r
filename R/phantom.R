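# Parametric quadruped phantom rendered by analytic ray casting.
#
# World frame: x runs along the body, y along the camera optical axis, z is
# up with the ground plane at z = 0. The camera sits at (0, 0, camera_height)
# looking along +y; the camera-to-world rotation maps camera x to world x,
# camera z (optical axis) to world y, and camera -y to world z (up).

#' Phantom specification
#'
#' Defines a standing quadruped of exactly known dimensions viewed from the
#' side, plus the depth degradations to simulate. Trait dimensions are the
#' ground truth by construction. The trunk is a pair of axis-aligned boxes
#' (front section topped at the withers height, rear section at the hip
#' height); the four legs are vertical square prisms whose cross-section
#' side equals the cannon diameter, so the bilateral cannon landmark pair
#' sits on the camera-facing leg face separated by exactly that diameter.
#'
#' @param withers_height_m,hip_height_m Heights of the two dorsal
#'   landmarks above the ground (meters).
#' @param body_length_m Shoulder-point to pin-bone distance (meters).
#' @param cannon_diameter_m Forelimb cannon diameter; the circumference
#'   ground truth is pi times this value.
#' @param camera_distance_m Distance from the camera to the near body
#'   surface (meters); must lie inside the pass-through range.
#' @param camera_height_m Camera elevation above the ground.
#' @param image_size c(width, height) in pixels.
#' @param intrinsics `camera_intrinsics`.
#' @param dropout_rate Fraction of valid depth pixels zeroed at random.
#' @param depth_noise_sd_m Additive Gaussian depth noise (meters).
#' @param hole_mode "uniform" scatters the dropout over all valid pixels;
#'   "structured" additionally cuts a contiguous blob between the front and
#'   hind limbs (for multi-pass completion tests).
#' @param seed RNG seed controlling dropout and noise.
#' @param trunk_width_m,belly_height_m,cannon_height_m,leg_stagger_m
#'   Secondary body-shape parameters: trunk depth along the optical axis,
#'   belly clearance, height of the cannon landmark pair, and the
#'   along-body offset of the far leg pair.
#' @return List of class `phantom_spec`.
#' @export
phantom_spec <- function(withers_height_m = 1.30, hip_height_m = 1.34,
                         body_length_m = 1.60, cannon_diameter_m = 0.07,
                         camera_distance_m = 1.5, camera_height_m = 0.8,
                         image_size = c(848L, 480L),
                         intrinsics = default_intrinsics(),
                         dropout_rate = 0, depth_noise_sd_m = 0,
                         hole_mode = c("uniform", "structured"),
                         seed = 1L,
                         trunk_width_m = 0.35, belly_height_m = 0.60,
                         cannon_height_m = 0.22, leg_stagger_m = 0.12) {
  hole_mode <- match.arg(hole_mode)
  dims <- c(withers_height_m, hip_height_m, body_length_m, cannon_diameter_m,
            camera_distance_m, camera_height_m, trunk_width_m,
            belly_height_m, cannon_height_m)
  if (any(dims <= 0)) stop_bovi("all phantom dimensions must be positive",
                                class = "phantom_error")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_bovi("dropout_rate must lie in [0, 1]", class = "phantom_error")
  if (camera_distance_m <= 0.1 || camera_distance_m >= 5)
    stop_bovi("camera distance must lie inside the pass-through range (0.1, 5) m",
              class = "phantom_error")
  if (belly_height_m >= min(withers_height_m, hip_height_m))
    stop_bovi("belly must sit below the trunk top", class = "phantom_error")
  structure(list(withers_height_m = withers_height_m, hip_height_m = hip_height_m,
                 body_length_m = body_length_m,
                 cannon_diameter_m = cannon_diameter_m,
                 camera_distance_m = camera_distance_m,
                 camera_height_m = camera_height_m,
                 image_size = as.integer(image_size), intrinsics = intrinsics,
                 dropout_rate = dropout_rate,
                 depth_noise_sd_m = depth_noise_sd_m,
                 hole_mode = hole_mode, seed = as.integer(seed),
                 trunk_width_m = trunk_width_m, belly_height_m = belly_height_m,
                 cannon_height_m = cannon_height_m,
                 leg_stagger_m = leg_stagger_m),
            class = "phantom_spec")
}

# Scene layout in world coordinates, derived from a phantom_spec.
phantom_scene <- function(spec) {
  L <- spec$body_length_m
  x0 <- -L / 2
  y0 <- spec$camera_distance_m
  w <- spec$trunk_width_m
  r <- spec$cannon_diameter_m / 2
  leg_y_near <- y0 + 0.10
  leg_y_far <- y0 + w - 0.10
  xf <- x0 + 0.15 * L   # front legs
  xh <- x0 + 0.85 * L   # hind legs
  list(
    x0 = x0, y0 = y0, w = w, r = r,
    z_belly = spec$belly_height_m,
    boxes = list(
      front = list(lo = c(x0, y0, spec$belly_height_m),
                   hi = c(x0 + L / 2, y0 + w, spec$withers_height_m)),
      rear = list(lo = c(x0 + L / 2, y0, spec$belly_height_m),
                  hi = c(x0 + L, y0 + w, spec$hip_height_m))),
    legs = list(
      c(xf, leg_y_near), c(xh, leg_y_near),
      c(xf + spec$leg_stagger_m, leg_y_far),
      c(xh - spec$leg_stagger_m, leg_y_far)),
    leg_x_front = xf, leg_x_hind = xh, leg_y_near = leg_y_near,
    ground = list(xlim = c(x0 - 0.6, x0 + L + 0.6),
                  ylim = c(y0 - 0.5, y0 + w + 0.3)))
}

# Landmark positions in world coordinates (all on camera-facing surfaces).
phantom_landmarks <- function(spec, scene) {
  L <- spec$body_length_m
  z_sh <- (spec$belly_height_m + min(spec$withers_height_m, spec$hip_height_m)) / 2
  rbind(
    withers_top = c(scene$x0 + 0.25 * L, scene$y0, spec$withers_height_m),
    hip_top = c(scene$x0 + 0.75 * L, scene$y0, spec$hip_height_m),
    shoulder_point = c(scene$x0, scene$y0, z_sh),
    pin_bone = c(scene$x0 + L, scene$y0, z_sh),
    cannon_medial = c(scene$leg_x_front - scene$r, scene$leg_y_near - scene$r,
                      spec$cannon_height_m),
    cannon_lateral = c(scene$leg_x_front + scene$r, scene$leg_y_near - scene$r,
                       spec$cannon_height_m))
}

phantom_extrinsics <- function(spec) {
  R <- rbind(c(1, 0, 0),   # world x <- camera x
             c(0, 0, 1),   # world y <- camera z (optical axis)
             c(0, -1, 0))  # world z <- camera -y (up)
  extrinsics(R, c(0, 0, spec$camera_height_m))
}

# Ray-cast the scene: returns an H x W depth matrix (camera Z in meters;
# 0 where no surface is hit) and a primitive-id matrix for coloring.
raycast_phantom <- function(spec, scene) {
  W <- spec$image_size[1]; H <- spec$image_size[2]
  K <- spec$intrinsics
  du <- ((0:(W - 1)) - K$cx) / K$fx
  dv <- ((0:(H - 1)) - K$cy) / K$fy
  # world-frame ray directions (camera dir (du, dv, 1) through the fixed R)
  DX <- matrix(du, H, W, byrow = TRUE)
  DZ <- matrix(-dv, H, W)          # world up component
  # DY = 1 everywhere
  o <- c(0, 0, spec$camera_height_m)
  t_best <- matrix(Inf, H, W)
  id <- matrix(0L, H, W)

  hit <- function(t, code) {
    t[is.na(t)] <- Inf
    better <- t < t_best
    t_best[better] <<- t[better]
    id[better] <<- code
  }
  ray_box <- function(lo, hi) {
    t1x <- (lo[1] - o[1]) / DX; t2x <- (hi[1] - o[1]) / DX
    tx_lo <- pmin(t1x, t2x); tx_hi <- pmax(t1x, t2x)
    t1y <- lo[2] - o[2]; t2y <- hi[2] - o[2]  # DY = 1
    t1z <- (lo[3] - o[3]) / DZ; t2z <- (hi[3] - o[3]) / DZ
    tz_lo <- pmin(t1z, t2z); tz_hi <- pmax(t1z, t2z)
    tmin <- pmax(tx_lo, t1y, tz_lo)
    tmax <- pmin(tx_hi, t2y, tz_hi)
    t <- ifelse(tmax >= tmin & tmin > 0, tmin, Inf)
    t
  }
  ray_ground <- function(g) {
    t <- ifelse(DZ < 0, -o[3] / DZ, Inf)
    x <- o[1] + t * DX; y <- o[2] + t  # DY = 1
    ifelse(t > 0 & x >= g$xlim[1] & x <= g$xlim[2] &
             y >= g$ylim[1] & y <= g$ylim[2], t, Inf)
  }

  hit(ray_box(scene$boxes$front$lo, scene$boxes$front$hi), 1L)
  hit(ray_box(scene$boxes$rear$lo, scene$boxes$rear$hi), 1L)
  for (leg in scene$legs)
    hit(ray_box(c(leg[1] - scene$r, leg[2] - scene$r, 0),
                c(leg[1] + scene$r, leg[2] + scene$r, scene$z_belly)), 2L)
  hit(ray_ground(scene$ground), 3L)

  t_best[!is.finite(t_best)] <- 0
  list(depth = t_best, id = id)
}

#' Render the synthetic quadruped phantom
#'
#' Ray-casts the parametric body into an aligned RGB-D frame at the given
#' intrinsics, places the six canonical landmarks at analytically known
#' surface points, projects them to subpixel image coordinates, and applies
#' seeded depth dropout and noise. The returned trait ground truth equals
#' the specification by construction.
#'
#' @param spec `phantom_spec`.
#' @return List with `frame` (`rgbd_frame`), `keypoints` (ground-truth
#'   `keypoint_set`), `truth` (named list of the four trait values in cm),
#'   `extrinsics`, `landmarks_world` (6 x 3 matrix) and `spec`.
#' @export
render_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  scene <- phantom_scene(spec)
  lm <- phantom_landmarks(spec, scene)
  ext <- phantom_extrinsics(spec)
  W <- spec$image_size[1]; H <- spec$image_size[2]

  uv <- project(to_camera(lm, ext), spec$intrinsics)
  margin <- 3
  if (any(uv[, 1] < margin) || any(uv[, 1] > W - 1 - margin) ||
      any(uv[, 2] < margin) || any(uv[, 2] > H - 1 - margin))
    stop_bovi("phantom landmarks fall outside the camera frustum; ",
              "increase camera_distance_m (or adjust camera_height_m)",
              class = "visibility_error")

  rc <- raycast_phantom(spec, scene)
  depth <- rc$depth

  with_local_seed(spec$seed, {
    valid <- which(depth > 0)
    if (spec$depth_noise_sd_m > 0)
      depth[valid] <- pmax(depth[valid] +
                             stats::rnorm(length(valid), sd = spec$depth_noise_sd_m),
                           0.011)
    if (spec$hole_mode == "structured") {
      # contiguous blob between the front and hind limbs, below the belly
      blob <- to_camera(rbind(
        c(scene$leg_x_front + scene$r + 0.05, scene$leg_y_near, 0.05),
        c(scene$leg_x_hind - scene$r - 0.05, scene$leg_y_near,
          scene$z_belly - 0.05)), ext)
      buv <- project(blob, spec$intrinsics)
      rows <- max(1, round(min(buv[, 2]))):min(H, round(max(buv[, 2])))
      cols <- max(1, round(min(buv[, 1]))):min(W, round(max(buv[, 1])))
      # a blob of rows spanning more than the 5x5 ring, so one pass cannot
      # close it
      mid <- rows[ceiling(length(rows) / 2)]
      rows <- max(1, mid - 5):min(H, mid + 5)
      depth[rows + H * (rep(cols, each = length(rows)) - 1)] <- 0
    }
    if (spec$dropout_rate > 0) {
      valid <- which(depth > 0)
      k <- round(spec$dropout_rate * length(valid))
      if (k > 0) depth[sample(valid, k)] <- 0
    }
  })

  # simple diffuse coloring by primitive id
  color <- array(0.15, c(H, W, 3))
  body <- rc$id == 1L | rc$id == 2L
  grnd <- rc$id == 3L
  for (ch in 1:3) {
    pl <- color[, , ch]
    pl[body] <- c(0.55, 0.40, 0.28)[ch]
    pl[grnd] <- c(0.35, 0.45, 0.30)[ch]
    color[, , ch] <- pl
  }

  kp <- keypoint_set(
    data.frame(name = rownames(lm), u = uv[, 1], v = uv[, 2],
               visibility = 2L, confidence = 1, stringsAsFactors = FALSE),
    bbox_area = phantom_bbox_area(spec, scene))

  truth <- list(
    withers_height_cm = spec$withers_height_m * 100,
    hip_height_cm = spec$hip_height_m * 100,
    body_length_cm = spec$body_length_m * 100,
    cannon_circumference_cm = pi * spec$cannon_diameter_m * 100)

  list(frame = rgbd_frame(color, depth, spec$intrinsics),
       keypoints = kp, truth = truth, extrinsics = ext,
       landmarks_world = lm, spec = spec)
}

# Tight image-plane bounding box of the whole body (trunk + legs).
phantom_bbox_area <- function(spec, scene) {
  K <- spec$intrinsics
  u1 <- K$fx * scene$x0 / scene$y0 + K$cx
  u2 <- K$fx * (scene$x0 + spec$body_length_m) / scene$y0 + K$cx
  v_top <- K$cy - K$fy * (max(spec$withers_height_m, spec$hip_height_m) -
                            spec$camera_height_m) / scene$y0
  v_bot <- K$cy + K$fy * spec$camera_height_m / scene$leg_y_near
  (u2 - u1) * (v_bot - v_top)
}

#' Jitter ground-truth keypoints
#'
#' Displaces every visible keypoint by seeded pixel noise, preserving
#' visibility flags and the bounding box. Two displacement models:
#' "gaussian" adds independent N(0, sd_px^2) noise to u and v (so
#' E d^2 = 2 sd_px^2); "ring" displaces by exactly `sd_px` pixels in a
#' uniformly random direction (d^2 = sd_px^2 exactly), which is the
#' calibrated-jitter mode used to realize a prescribed OKS level.
#'
#' @param gt `keypoint_set`.
#' @param sd_px Noise scale in pixels (>= 0): Gaussian standard deviation,
#'   or the exact displacement radius for "ring".
#' @param seed RNG seed.
#' @param method "gaussian" or "ring".
#' @return A perturbed `keypoint_set`.
#' @export
perturb_keypoints <- function(gt, sd_px, seed = 1L,
                              method = c("gaussian", "ring")) {
  method <- match.arg(method)
  stopifnot(inherits(gt, "keypoint_set"), sd_px >= 0)
  k <- gt$keypoints
  vis <- which(k$visibility > 0L)
  with_local_seed(seed, {
    if (method == "gaussian") {
      k$u[vis] <- k$u[vis] + stats::rnorm(length(vis), sd = sd_px)
      k$v[vis] <- k$v[vis] + stats::rnorm(length(vis), sd = sd_px)
    } else {
      th <- stats::runif(length(vis), 0, 2 * pi)
      k$u[vis] <- k$u[vis] + sd_px * cos(th)
      k$v[vis] <- k$v[vis] + sd_px * sin(th)
    }
  })
  keypoint_set(k[k$visibility > 0L, , drop = FALSE], bbox_area = gt$bbox_area)
}
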