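# The four body traits from world-frame landmarks and the ground plane.

height_above_ground <- function(point, ground, up_axis = 3L) {
  as.numeric(point[up_axis]) - ground$z0
}

#' Withers height in centimeters
#'
#' Height of the withers landmark above the ground reference plane,
#' measured as the coordinate difference along the world up axis.
#'
#' @param withers_point World-frame 3-vector (meters).
#' @param ground `ground_plane` from [estimate_ground()].
#' @param up_axis Index of the world height coordinate.
#' @return Height in centimeters.
#' @export
withers_height <- function(withers_point, ground, up_axis = 3L) {
  h <- height_above_ground(withers_point, ground, up_axis)
  if (h <= 0)
    stop_bovi("non-positive height above ground (", round(h, 4),
              " m); check the world up-axis convention", class = "orientation_error")
  h * 100
}

#' Hip height in centimeters
#'
#' Same contract as [withers_height()], applied to the hip landmark.
#'
#' @param hip_point World-frame 3-vector (meters).
#' @inheritParams withers_height
#' @return Height in centimeters.
#' @export
hip_height <- function(hip_point, ground, up_axis = 3L) {
  withers_height(hip_point, ground, up_axis)
}

#' Body length in centimeters
#'
#' 3D Euclidean distance between the point of the shoulder and the
#' posterior edge of the pin bone.
#'
#' @param p1,p2 3-vectors in the same coordinate frame (meters).
#' @return Length in centimeters.
#' @export
body_length <- function(p1, p2) {
  stopifnot(length(p1) == 3L, length(p2) == 3L)
  sqrt(sum((as.numeric(p1) - as.numeric(p2))^2)) * 100
}

#' Cannon circumference in centimeters
#'
#' The distance between the two bilateral surface points at the narrowest
#' section of the forelimb cannon is taken as the diameter of an
#' approximately circular cross-section; the circumference is pi times
#' that diameter.
#'
#' @inheritParams body_length
#' @return Circumference in centimeters.
#' @export
cannon_circumference <- function(p1, p2) {
  d <- body_length(p1, p2) / 100
  if (d <= 0)
    stop_bovi("cannon landmarks coincide; circumference undefined",
              class = "degenerate_landmark_error")
  pi * d * 100
}

#' Relative error in percent
#'
#' @param gt Ground-truth value (> 0).
#' @param pred Predicted value.
#' @return |pred - gt| / gt * 100, rounded to two decimals.
#' @export
relative_error <- function(gt, pred) {
  if (any(gt <= 0)) stop_bovi("ground truth must be positive", class = "measure_error")
  round(abs(pred - gt) / gt * 100, 2)
}

#' Measurement pipeline configuration
#'
#' Bundles the printed processing constants: pass-through range (0.1, 5) m,
#' default sensor intrinsics, depth-completion passes, cloud sampling
#' stride, and the ground-estimation recipe (hint radius, minimum support).
#'
#' @param z1,z2 Pass-through bounds in meters.
#' @param max_passes Depth-completion passes.
#' @param stride Cloud sampling stride in pixels.
#' @param ground_radius Hoof-hint neighborhood radius in meters.
#' @param min_support Minimum ground support points.
#' @param up_axis World height coordinate index.
#' @param complete Whether [measure_animal()] runs depth completion itself.
#' @return List of class `measure_config`.
#' @export
measure_config <- function(z1 = 0.1, z2 = 5.0, max_passes = 5L, stride = 2L,
                           ground_radius = 0.15, min_support = 50L,
                           up_axis = 3L, complete = TRUE) {
  structure(list(z1 = z1, z2 = z2, max_passes = max_passes, stride = stride,
                 ground_radius = ground_radius, min_support = min_support,
                 up_axis = up_axis, complete = complete),
            class = "measure_config")
}

# Derive a ground hint under a hoof from the cloud itself: keep points in a
# horizontal disc around (x, y), take a low height quantile as the hint
# elevation. The hint only seeds estimate_ground()'s neighborhood search.
derive_hoof_hint <- function(points, x, y, horiz_radius = 0.35, up_axis = 3L) {
  horiz <- setdiff(1:3, up_axis)
  d2 <- (points[, horiz[1]] - c(x, y)[1])^2 + (points[, horiz[2]] - c(x, y)[2])^2
  near <- points[d2 <= horiz_radius^2, , drop = FALSE]
  if (!nrow(near)) return(NULL)
  zlo <- stats::quantile(near[, up_axis], 0.02, names = FALSE)
  low <- near[near[, up_axis] <= zlo + 0.02, , drop = FALSE]
  hint <- colMeans(low)
  hint[up_axis] <- zlo
  hint
}

#' Measure the four body traits of one animal
#'
#' Full measurement chain: depth completion (unless disabled), per-keypoint
#' depth lookup with 5x5 median fallback, pinhole back-projection at the
#' subpixel keypoint coordinates, rigid transform to the world frame,
#' ground-plane estimation from hoof-adjacent points, then the four trait
#' computations. Per-trait quality flags record every fallback used; a
#' missing landmark degrades only the traits that need it.
#'
#' @param frame `rgbd_frame`.
#' @param keypoints `keypoint_set` with the six canonical landmarks.
#' @param ext `extrinsics` mapping camera to world coordinates (world up
#'   axis per config).
#' @param ground_config Optional list; `hoof_hints` (n x 3 world matrix)
#'   overrides the hints otherwise derived from the cannon landmarks, and
#'   `radius` / `min_support` override the config values.
#' @param config `measure_config`.
#' @return Object of class `body_measurements`: the four `*_cm` trait
#'   values (NA when not measurable), `flags` (named list of character
#'   vectors), `keypoints_world` (6 x 3 matrix), `ground` and cloud-filter
#'   counts.
#' @export
measure_animal <- function(frame, keypoints, ext,
                           ground_config = list(), config = measure_config()) {
  stopifnot(inherits(frame, "rgbd_frame"), inherits(keypoints, "keypoint_set"),
            inherits(ext, "extrinsics"))
  kp <- keypoints$keypoints
  if (!any(kp$visibility > 0L))
    stop_bovi("all six landmarks are invisible; nothing to measure",
              class = "no_measurement_error")

  depth <- frame$depth
  fill_fraction <- NA_real_
  if (isTRUE(config$complete)) {
    before <- depth
    depth <- suppressWarnings(complete_depth(depth, config$max_passes))
    fill_fraction <- hole_statistics(before, depth)$fill_fraction
    frame$depth <- depth  # downstream stages use the optimized map
  }

  # Landmark 3D coordinates (world frame), via subpixel back-projection.
  flags <- stats::setNames(vector("list", nrow(kp)), kp$name)
  pw <- matrix(NA_real_, nrow(kp), 3, dimnames = list(kp$name, c("X", "Y", "Z")))
  for (i in seq_len(nrow(kp))) {
    if (kp$visibility[i] == 0L) { flags[[i]] <- "missing_landmark"; next }
    look <- lookup_depth(depth, kp$u[i], kp$v[i])
    if (is.na(look$Z)) { flags[[i]] <- "missing_depth"; next }
    if (look$interpolated) flags[[i]] <- "depth_interpolated"
    pc <- backproject(kp$u[i], kp$v[i], look$Z, frame$intrinsics)
    pw[i, ] <- to_world(pc, ext)
  }

  # Scene cloud for ground-plane referencing.
  cloud <- frame_to_cloud(frame, stride = config$stride)
  filtered <- passthrough_filter(cloud, config$z1, config$z2)
  world <- to_world(filtered, ext)

  hints <- ground_config$hoof_hints
  if (is.null(hints)) {
    horiz <- setdiff(1:3, config$up_axis)
    anchors <- list()
    for (nm in c("cannon_medial", "cannon_lateral", "shoulder_point", "pin_bone"))
      if (!is.na(pw[nm, 1])) anchors[[nm]] <- pw[nm, horiz]
    hints <- NULL
    for (a in anchors) {
      h <- derive_hoof_hint(world$points, a[1], a[2], up_axis = config$up_axis)
      if (!is.null(h)) hints <- rbind(hints, h)
    }
  }
  ground <- NULL
  ground_flag <- character()
  if (!is.null(hints)) {
    ground <- tryCatch(
      estimate_ground(world, hints,
                      radius = ground_config$radius %||% config$ground_radius,
                      min_support = ground_config$min_support %||% config$min_support,
                      up_axis = config$up_axis),
      bovimetry_error = function(e) { ground_flag <<- conditionMessage(e); NULL })
  } else ground_flag <- "no ground hints available"

  trait <- function(value_fn, needed, trait_flags = character()) {
    miss <- needed[is.na(pw[needed, 1])]
    if (length(miss))
      return(list(value = NA_real_,
                  flags = c(trait_flags, paste0("unavailable_landmark:", miss))))
    f <- c(trait_flags, unlist(flags[needed], use.names = FALSE))
    val <- tryCatch(value_fn(), bovimetry_error = function(e) {
      f <<- c(f, conditionMessage(e)); NA_real_
    })
    list(value = val, flags = f)
  }
  need_ground <- if (is.null(ground)) c("ground_unavailable", ground_flag) else character()
  wh <- trait(function() if (is.null(ground)) NA_real_ else
    withers_height(pw["withers_top", ], ground, config$up_axis),
    "withers_top", need_ground)
  hh <- trait(function() if (is.null(ground)) NA_real_ else
    hip_height(pw["hip_top", ], ground, config$up_axis),
    "hip_top", need_ground)
  bl <- trait(function() body_length(pw["shoulder_point", ], pw["pin_bone", ]),
              c("shoulder_point", "pin_bone"))
  cc <- trait(function() cannon_circumference(pw["cannon_medial", ],
                                              pw["cannon_lateral", ]),
              c("cannon_medial", "cannon_lateral"))

  structure(list(
    withers_height_cm = wh$value,
    hip_height_cm = hh$value,
    body_length_cm = bl$value,
    cannon_circumference_cm = cc$value,
    flags = list(withers_height = wh$flags, hip_height = hh$flags,
                 body_length = bl$flags, cannon_circumference = cc$flags),
    keypoints_world = pw,
    ground = ground,
    fill_fraction = fill_fraction,
    n_kept = attr(filtered, "n_kept"),
    n_removed = attr(filtered, "n_removed")),
    class = "body_measurements")
}

#' @export
print.body_measurements <- function(x, ...) {
  cat("Body measurements (cm):\n")
  for (tr in c("withers_height_cm", "hip_height_cm", "body_length_cm",
               "cannon_circumference_cm")) {
    v <- x[[tr]]
    fl <- x$flags[[sub("_cm$", "", tr)]]
    cat(sprintf("  %-24s %s%s\n", tr,
                if (is.na(v)) "(not measurable)" else sprintf("%7.2f", v),
                if (length(fl)) paste0("  [", paste(fl, collapse = "; "), "]") else ""))
  }
  invisible(x)
}
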