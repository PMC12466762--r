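# Pinhole back-projection, rigid transforms, point-cloud filtering and
# ground-plane estimation.

#' Construct a point cloud
#'
#' @param points n x 3 numeric matrix (columns X, Y, Z in meters).
#' @param frame Coordinate frame tag, "camera" or "world".
#' @return Object of class `point_cloud`.
#' @export
point_cloud <- function(points, frame = c("camera", "world")) {
  frame <- match.arg(frame)
  if (is.null(points) || !length(points)) points <- matrix(numeric(0), 0, 3)
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) && any(!is.finite(points)))
    stop_bovi("point cloud contains non-finite coordinates", class = "geometry_error")
  colnames(points) <- c("X", "Y", "Z")
  structure(list(points = points, frame = frame), class = "point_cloud")
}

#' Back-project pixels to camera-frame 3D points
#'
#' Inverse pinhole model: X = (u - cx) Z / fx, Y = (v - cy) Z / fy, Z = Z.
#' Vectorized over pixels.
#'
#' @param u,v 0-based pixel coordinates (column, row); subpixel values
#'   allowed.
#' @param Z Depth in meters along the optical axis (must be > 0).
#' @param intrinsics `camera_intrinsics`.
#' @return n x 3 matrix of camera-frame coordinates (meters).
#' @export
backproject <- function(u, v, Z, intrinsics = default_intrinsics()) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  if (any(!is.finite(Z)) || any(Z <= 0)) {
    bad <- which(!is.finite(Z) | Z <= 0)[1]
    stop_bovi(sprintf("missing depth at pixel (u=%.1f, v=%.1f)",
                      u[bad], v[bad]), class = "missing_depth_error")
  }
  cbind(X = (u - intrinsics$cx) * Z / intrinsics$fx,
        Y = (v - intrinsics$cy) * Z / intrinsics$fy,
        Z = Z)
}

#' Project camera-frame 3D points to pixels (forward pinhole model)
#'
#' @param p n x 3 matrix of camera-frame points (Z > 0).
#' @param intrinsics `camera_intrinsics`.
#' @return n x 2 matrix of (u, v) pixel coordinates.
#' @export
project <- function(p, intrinsics = default_intrinsics()) {
  p <- matrix(as.numeric(p), ncol = 3)
  if (any(p[, 3] <= 0))
    stop_bovi("cannot project points at or behind the camera", class = "geometry_error")
  cbind(u = p[, 1] / p[, 3] * intrinsics$fx + intrinsics$cx,
        v = p[, 2] / p[, 3] * intrinsics$fy + intrinsics$cy)
}

#' Convert an RGB-D frame to a camera-frame point cloud
#'
#' One point per valid-depth pixel, sampled every `stride` pixels in both
#' directions; missing pixels are skipped.
#'
#' @param frame `rgbd_frame`.
#' @param stride Positive integer sampling stride.
#' @return `point_cloud` in the camera frame.
#' @export
frame_to_cloud <- function(frame, stride = 1L) {
  stopifnot(inherits(frame, "rgbd_frame"), is_scalar_number(stride), stride >= 1)
  d <- unclass(frame$depth)
  rows <- seq(1L, nrow(d), by = stride)
  cols <- seq(1L, ncol(d), by = stride)
  sub <- d[rows, cols, drop = FALSE]
  keep <- which(sub > 0, arr.ind = TRUE)
  if (!nrow(keep)) return(point_cloud(NULL, "camera"))
  v <- rows[keep[, 1]] - 1  # 0-based pixel rows
  u <- cols[keep[, 2]] - 1
  point_cloud(backproject(u, v, sub[keep], frame$intrinsics), "camera")
}

#' Pass-through filter along the optical axis
#'
#' Retains exactly the points whose Z lies in the open interval (z1, z2);
#' the default upper bound removes invalid points with depth beyond 5 m.
#'
#' @param cloud Camera-frame `point_cloud`.
#' @param z1,z2 Interval bounds in meters (z1 < z2).
#' @return Filtered `point_cloud`; attributes `n_kept` and `n_removed`
#'   always satisfy n_kept + n_removed = input size.
#' @export
passthrough_filter <- function(cloud, z1 = 0.1, z2 = 5.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$frame != "camera")
    stop_bovi("pass-through filtering operates on camera-frame clouds",
              class = "geometry_error")
  if (!(z1 < z2)) stop_bovi("need z1 < z2", class = "geometry_error")
  keep <- cloud$points[, 3] > z1 & cloud$points[, 3] < z2
  out <- point_cloud(cloud$points[keep, , drop = FALSE], "camera")
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Transform points from the camera frame to the world frame
#'
#' Applies p_world = R p_cam + T to every point.
#'
#' @param x `point_cloud` (camera frame) or n x 3 matrix of camera-frame
#'   points.
#' @param ext `extrinsics`.
#' @return Same shape as the input, in world coordinates (clouds get their
#'   frame tag updated).
#' @export
to_world <- function(x, ext) {
  stopifnot(inherits(ext, "extrinsics"))
  if (inherits(x, "point_cloud")) {
    if (x$frame != "camera")
      stop_bovi("input cloud is already in the world frame", class = "geometry_error")
    return(point_cloud(to_world(x$points, ext), "world"))
  }
  p <- matrix(as.numeric(x), ncol = 3)
  t(ext$R %*% t(p) + ext$T)
}

#' Inverse transform: world frame to camera frame
#'
#' @inheritParams to_world
#' @param x n x 3 matrix of world-frame points.
#' @return n x 3 matrix of camera-frame points.
#' @export
to_camera <- function(x, ext) {
  stopifnot(inherits(ext, "extrinsics"))
  p <- matrix(as.numeric(x), ncol = 3)
  t(crossprod(ext$R, t(p) - ext$T))
}

#' Estimate the ground reference plane from hoof-adjacent points
#'
#' Candidate points are those within `radius` (meters, 3D) of any hoof
#' hint. To reject limb points mixed into the neighborhood, the upper half
#' of the candidates (by height) is discarded and the ground elevation is
#' the median height of the remaining lower half. The plane normal is the
#' world up axis.
#'
#' @param cloud World-frame `point_cloud`.
#' @param hoof_hints n x 3 matrix (or single 3-vector) of world points near
#'   the hooves.
#' @param radius Neighborhood radius in meters.
#' @param min_support Minimum number of candidate points required.
#' @param up_axis Index of the height coordinate in the world frame.
#' @return List of class `ground_plane` with `z0` (ground elevation,
#'   meters), `normal` (unit up vector) and `support_count`.
#' @export
estimate_ground <- function(cloud, hoof_hints, radius = 0.15,
                            min_support = 50L, up_axis = 3L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (cloud$frame != "world")
    stop_bovi("ground estimation needs a world-frame cloud", class = "geometry_error")
  if (!nrow(cloud$points)) stop_bovi("empty point cloud", class = "ground_error")
  hints <- matrix(as.numeric(hoof_hints), ncol = 3)
  if (!nrow(hints)) stop_bovi("at least one hoof hint is required", class = "ground_error")
  p <- cloud$points
  near <- rep(FALSE, nrow(p))
  for (i in seq_len(nrow(hints))) {
    d2 <- (p[, 1] - hints[i, 1])^2 + (p[, 2] - hints[i, 2])^2 + (p[, 3] - hints[i, 3])^2
    near <- near | d2 <= radius^2
  }
  cand <- p[near, up_axis]
  if (length(cand) < min_support)
    stop_bovi("only ", length(cand), " points near the hoof hints (need ",
              min_support, "); try a larger radius", class = "ground_error")
  lower <- cand[cand <= stats::median(cand)]
  z0 <- stats::median(lower)
  normal <- c(0, 0, 0); normal[up_axis] <- 1
  structure(list(z0 = z0, normal = normal, support_count = length(cand)),
            class = "ground_plane")
}

#' Look up depth for a keypoint in a (completed) depth map
#'
#' Subpixel keypoint coordinates are rounded to the nearest pixel only for
#' indexing. The returned depth is the median of the valid depths in the
#' 3x3 window around that pixel: on a locally smooth surface this equals
#' the surface depth, while staying robust both to sensor noise and to the
#' depth discontinuity when a landmark sits on a silhouette edge. When the
#' indexed pixel itself is missing the same median is used but the lookup
#' is flagged as depth-interpolated; if the whole 3x3 window is empty the
#' fallback widens to the 5x5 window.
#'
#' @param depth `depth_map` (meters), normally after [complete_depth()].
#' @param u,v 0-based keypoint pixel coordinates.
#' @return List with `Z` (meters, NA when no valid depth is available) and
#'   `interpolated` (logical).
#' @export
lookup_depth <- function(depth, u, v) {
  d <- unclass(depth)
  i <- round(v) + 1L  # row
  j <- round(u) + 1L  # column
  if (i < 1L || i > nrow(d) || j < 1L || j > ncol(d))
    return(list(Z = NA_real_, interpolated = FALSE))
  window_valid <- function(halfwidth) {
    ri <- max(1L, i - halfwidth):min(nrow(d), i + halfwidth)
    ci <- max(1L, j - halfwidth):min(ncol(d), j + halfwidth)
    w <- d[ri, ci]
    w[w > 0]
  }
  w3 <- window_valid(1L)
  if (length(w3))
    return(list(Z = stats::median(w3), interpolated = d[i, j] == 0))
  w5 <- window_valid(2L)
  if (!length(w5)) return(list(Z = NA_real_, interpolated = FALSE))
  list(Z = stats::median(w5), interpolated = TRUE)
}
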