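#' Canonical lateral-view landmark names
#'
#' The six anatomical landmarks used for body measurement, in canonical
#' order: top of the withers, top of the back at the hip, point of the
#' shoulder, posterior edge of the pin bone (ischium), and the two bilateral
#' surface points at the narrowest section of the forelimb cannon.
#'
#' @return Character vector of length 6.
#' @export
keypoint_names <- function() {
  c("withers_top", "hip_top", "shoulder_point", "pin_bone",
    "cannon_medial", "cannon_lateral")
}

#' Camera intrinsics
#'
#' Pinhole intrinsic parameters in pixels. Defaults are the calibration of
#' the RGB-D sensor used for 848x480 side-view capture.
#'
#' @param fx,fy Focal lengths in pixels (must be > 0).
#' @param cx,cy Principal point (column, row) in 0-based pixel coordinates.
#' @param width,height Optional image size used to validate the principal
#'   point.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx = 525, fy = 525, cx = 319.5, cy = 239.5,
                              width = NULL, height = NULL) {
  stopifnot(is_scalar_number(fx), is_scalar_number(fy),
            is_scalar_number(cx), is_scalar_number(cy))
  if (fx <= 0 || fy <= 0) stop_bovi("focal lengths must be positive", class = "intrinsics_error")
  if (cx < 0 || cy < 0) stop_bovi("principal point must be non-negative", class = "intrinsics_error")
  if (!is.null(width) && cx >= width)
    stop_bovi("cx must lie inside the image width", class = "intrinsics_error")
  if (!is.null(height) && cy >= height)
    stop_bovi("cy must lie inside the image height", class = "intrinsics_error")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy), class = "camera_intrinsics")
}

#' Default sensor intrinsics
#'
#' @return `camera_intrinsics` with fx = fy = 525, cx = 319.5, cy = 239.5.
#' @export
default_intrinsics <- function() camera_intrinsics()

#' Depth map constructor
#'
#' A depth map is an H x W numeric matrix of range values in meters; the
#' value 0 marks a missing measurement. `NA` values are treated as missing
#' on ingest.
#'
#' @param values Numeric matrix of depths in meters.
#' @return A numeric matrix of class `depth_map`.
#' @export
depth_map <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_bovi("depth map must be a numeric matrix", class = "depth_error")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop_bovi("depth map must be non-empty", class = "depth_error")
  values[!is.finite(values)] <- 0
  if (any(values < 0))
    stop_bovi("depth values must be non-negative", class = "depth_error")
  structure(values, class = c("depth_map", "matrix", "array"))
}

#' Aligned RGB-D frame
#'
#' @param color H x W x 3 numeric array in [0, 1] (8-bit color image).
#' @param depth `depth_map` (or numeric matrix) of identical H x W.
#' @param intrinsics `camera_intrinsics`.
#' @return Object of class `rgbd_frame` with elements color, depth,
#'   intrinsics.
#' @export
rgbd_frame <- function(color, depth, intrinsics = default_intrinsics()) {
  if (!inherits(depth, "depth_map")) depth <- depth_map(depth)
  if (!(is.array(color) && length(dim(color)) == 3L && dim(color)[3] == 3L))
    stop_bovi("color must be an H x W x 3 array", class = "io_error")
  if (dim(color)[1] != nrow(depth) || dim(color)[2] != ncol(depth))
    stop_bovi("color and depth dimensions differ: color ",
              dim(color)[1], "x", dim(color)[2], ", depth ",
              nrow(depth), "x", ncol(depth), class = "alignment_error")
  stopifnot(inherits(intrinsics, "camera_intrinsics"))
  structure(list(color = color, depth = depth, intrinsics = intrinsics),
            class = "rgbd_frame")
}

#' Keypoint set for one animal
#'
#' Holds the six canonical landmarks with 0-based subpixel coordinates
#' (u = column, v = row, origin top-left), COCO-style visibility flags
#' (0 absent, 1 labeled-not-visible, 2 visible) and detector confidences.
#'
#' @param keypoints data.frame with columns name, u, v, visibility,
#'   confidence. Rows are matched to the canonical landmark order by name;
#'   absent landmarks get visibility 0 and confidence 0.
#' @param bbox_area Object bounding-box area in squared pixels. When `NULL`,
#'   computed as the tight box over visible keypoints.
#' @return Object of class `keypoint_set`.
#' @export
keypoint_set <- function(keypoints, bbox_area = NULL) {
  canon <- keypoint_names()
  stopifnot(is.data.frame(keypoints))
  req <- c("name", "u", "v")
  if (!all(req %in% names(keypoints)))
    stop_bovi("keypoints need columns name, u, v", class = "schema_error")
  unknown <- setdiff(keypoints$name, canon)
  if (length(unknown))
    stop_bovi("unknown landmark name(s): ", paste(unknown, collapse = ", "),
              "; accepted names are: ", paste(canon, collapse = ", "),
              class = "schema_error")
  if (anyDuplicated(keypoints$name))
    stop_bovi("duplicate landmark names", class = "schema_error")
  if (is.null(keypoints$visibility)) keypoints$visibility <- 2L
  if (is.null(keypoints$confidence)) keypoints$confidence <- 1
  df <- data.frame(name = canon, u = NA_real_, v = NA_real_,
                   visibility = 0L, confidence = 0,
                   stringsAsFactors = FALSE)
  idx <- match(keypoints$name, canon)
  df$u[idx] <- keypoints$u
  df$v[idx] <- keypoints$v
  df$visibility[idx] <- as.integer(keypoints$visibility)
  df$confidence[idx] <- keypoints$confidence
  if (!all(df$visibility %in% 0:2))
    stop_bovi("visibility flags must be 0, 1 or 2", class = "schema_error")
  df$u[df$visibility == 0L] <- NA_real_
  df$v[df$visibility == 0L] <- NA_real_
  vis <- df$visibility > 0L
  if (!any(vis)) warning("keypoint set has no visible landmarks")
  if (is.null(bbox_area)) {
    bbox_area <- if (sum(vis) >= 2L) {
      du <- diff(range(df$u[vis])); dv <- diff(range(df$v[vis]))
      max(du * dv, 1)
    } else if (any(vis)) 1 else 0
  }
  if (any(vis) && bbox_area <= 0)
    stop_bovi("bbox_area must be positive when keypoints are visible",
              class = "schema_error")
  structure(list(keypoints = df, bbox_area = bbox_area), class = "keypoint_set")
}

#' Rigid camera-to-world extrinsics
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1).
#' @param T Numeric translation 3-vector in meters (the camera center in
#'   world coordinates).
#' @param tol Orthonormality tolerance.
#' @return Object of class `extrinsics`.
#' @export
extrinsics <- function(R = diag(3), T = c(0, 0, 0), tol = 1e-9) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3L, 3L)), length(T) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop_bovi("R must be a proper rotation (orthonormal, det +1)",
              class = "extrinsics_error")
  structure(list(R = R, T = as.numeric(T)), class = "extrinsics")
}

#' Read an aligned RGB-D frame from image files
#'
#' The color image must decode to 3 channels and the depth image to a single
#' channel of the same size. Depth files may be 16-bit PNG or 16-bit/float
#' TIFF; stored units are converted to meters by `depth_scale` (0.001 for
#' millimeter-encoded sensors).
#'
#' @param color_path Path to the color PNG.
#' @param depth_path Path to the depth PNG/TIFF.
#' @param intrinsics `camera_intrinsics`.
#' @param depth_scale Meters per stored depth unit.
#' @return An `rgbd_frame` with depth in meters.
#' @export
read_frame <- function(color_path, depth_path,
                       intrinsics = default_intrinsics(),
                       depth_scale = 0.001) {
  if (!file.exists(color_path)) stop_bovi("color file not found: ", color_path, class = "io_error")
  if (!file.exists(depth_path)) stop_bovi("depth file not found: ", depth_path, class = "io_error")
  color <- png::readPNG(color_path)
  if (length(dim(color)) == 3L && dim(color)[3] == 4L) color <- color[, , 1:3]
  if (length(dim(color)) == 2L) color <- array(rep(color, 3L), c(dim(color), 3L))
  if (dim(color)[3] != 3L)
    stop_bovi("color image must have 3 channels", class = "io_error")
  depth <- read_depth(depth_path, depth_scale = depth_scale)
  rgbd_frame(color, depth, intrinsics)
}

#' Read a depth map from a 16-bit PNG or TIFF file
#'
#' PNG samples are decoded by the reader to [0, 1] and rescaled by 65535
#' before applying `depth_scale`; 16-bit TIFF likewise. Float TIFF values
#' are taken as stored units directly.
#'
#' @inheritParams read_frame
#' @param path Depth image path (.png, .tif or .tiff).
#' @return A `depth_map` in meters.
#' @export
read_depth <- function(path, depth_scale = 0.001) {
  if (!file.exists(path)) stop_bovi("depth file not found: ", path, class = "io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    d <- png::readPNG(path)
    if (length(dim(d)) == 3L) d <- d[, , 1]
    d <- round(d * 65535)
  } else if (ext %in% c("tif", "tiff")) {
    d <- tiff::readTIFF(path)
    if (length(dim(d)) == 3L) d <- d[, , 1]
    mx <- max(d)
    # 16-bit integer TIFFs decode to [0,1]; float TIFFs carry raw units
    if (mx <= 1 + 1e-12) d <- round(d * 65535)
  } else {
    stop_bovi("unsupported depth format: .", ext, class = "io_error")
  }
  depth_map(d * depth_scale)
}

#' Write a depth map as a 16-bit TIFF in millimeters
#'
#' @param depth `depth_map` (meters).
#' @param path Output path (.tif).
#' @param depth_scale Meters per stored unit (default millimeters).
#' @return Invisibly, `path`.
#' @export
write_depth <- function(depth, path, depth_scale = 0.001) {
  stored <- round(unclass(depth) / depth_scale)
  if (max(stored) > 65535)
    stop_bovi("depth exceeds the 16-bit range at this depth_scale", class = "io_error")
  tiff::writeTIFF(stored / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read keypoint annotations (Labelme or COCO dialect)
#'
#' Landmarks are mapped to the canonical order by name (after optional alias
#' resolution); landmarks absent from the file get visibility 0. The
#' bounding-box area is taken from the annotation when present, otherwise
#' computed as the tight box over visible keypoints.
#'
#' @param path JSON annotation path.
#' @param dialect "labelme" (one object per file, point shapes) or "coco"
#'   (keypoint triplets per annotation record).
#' @param aliases Named character vector mapping annotation labels to
#'   canonical names, e.g. `c(withers = "withers_top")`.
#' @return List of `keypoint_set` (one per annotated animal).
#' @export
read_keypoints <- function(path, dialect = c("labelme", "coco"), aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_bovi("annotation file not found: ", path, class = "io_error")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  resolve <- function(nm) {
    if (!is.null(aliases) && nm %in% names(aliases)) unname(aliases[[nm]]) else nm
  }
  if (dialect == "labelme") {
    shapes <- doc$shapes %||% list()
    pts <- Filter(function(s) identical(s$shape_type %||% "point", "point"), shapes)
    rects <- Filter(function(s) identical(s$shape_type, "rectangle"), shapes)
    df <- do.call(rbind, lapply(pts, function(s) {
      p <- s$points[[1]]
      data.frame(name = resolve(s$label), u = as.numeric(p[[1]]),
                 v = as.numeric(p[[2]]), visibility = 2L,
                 confidence = 1, stringsAsFactors = FALSE)
    }))
    bbox_area <- NULL
    if (length(rects)) {
      p <- rects[[1]]$points
      bbox_area <- abs((p[[2]][[1]] - p[[1]][[1]]) * (p[[2]][[2]] - p[[1]][[2]]))
    }
    if (is.null(df) || !nrow(df)) {
      warning("annotation contains no visible keypoints")
      return(list(keypoint_set(data.frame(name = character(), u = numeric(),
                                          v = numeric()), bbox_area = 0)))
    }
    list(keypoint_set(df, bbox_area = bbox_area))
  } else {
    cats <- doc$categories %||% list()
    kp_names <- if (length(cats)) unlist(cats[[1]]$keypoints) else keypoint_names()
    kp_names <- vapply(kp_names, resolve, character(1))
    anns <- doc$annotations %||% list()
    lapply(anns, function(a) {
      k <- unlist(a$keypoints)
      if (length(k) %% 3L != 0L)
        stop_bovi("COCO keypoints must be (x, y, v) triplets", class = "schema_error")
      n <- length(k) %/% 3L
      df <- data.frame(name = kp_names[seq_len(n)],
                       u = k[seq(1, by = 3, length.out = n)],
                       v = k[seq(2, by = 3, length.out = n)],
                       visibility = as.integer(k[seq(3, by = 3, length.out = n)]),
                       confidence = 1, stringsAsFactors = FALSE)
      if (!is.null(a$confidence)) df$confidence <- unlist(a$confidence)
      df <- df[df$visibility > 0L, , drop = FALSE]
      if (!nrow(df)) warning("annotation contains no visible keypoints")
      bbox_area <- if (!is.null(a$bbox)) {
        b <- unlist(a$bbox); b[3] * b[4]
      } else if (!is.null(a$area)) a$area else NULL
      keypoint_set(df, bbox_area = bbox_area)
    })
  }
}

#' Write a keypoint set to JSON
#'
#' Inverse of [read_keypoints()] for both dialects; coordinates and
#' visibility flags round-trip exactly.
#'
#' @param ks `keypoint_set` (or list of them for "coco").
#' @param path Output JSON path.
#' @param dialect "labelme" or "coco".
#' @param image_size Optional c(width, height) recorded in the file header.
#' @return Invisibly, `path`.
#' @export
write_keypoints <- function(ks, path, dialect = c("labelme", "coco"),
                            image_size = NULL) {
  dialect <- match.arg(dialect)
  if (inherits(ks, "keypoint_set")) ks <- list(ks)
  if (dialect == "labelme") {
    k <- ks[[1]]$keypoints
    vis <- k[k$visibility > 0L, , drop = FALSE]
    shapes <- lapply(seq_len(nrow(vis)), function(i) {
      list(label = vis$name[i], points = list(c(vis$u[i], vis$v[i])),
           shape_type = "point")
    })
    doc <- list(version = "5.5.0", shapes = shapes,
                imageWidth = image_size[1] %||% NA,
                imageHeight = image_size[2] %||% NA)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    anns <- lapply(seq_along(ks), function(i) {
      k <- ks[[i]]$keypoints
      u <- ifelse(k$visibility > 0L, k$u, 0)
      v <- ifelse(k$visibility > 0L, k$v, 0)
      list(id = i, image_id = i, category_id = 1,
           keypoints = as.numeric(rbind(u, v, k$visibility)),
           confidence = k$confidence,
           area = ks[[i]]$bbox_area,
           num_keypoints = sum(k$visibility > 0L))
    })
    doc <- list(
      images = lapply(seq_along(ks), function(i)
        list(id = i, width = image_size[1] %||% NA, height = image_size[2] %||% NA)),
      annotations = anns,
      categories = list(list(id = 1, name = "cattle",
                             keypoints = keypoint_names())))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Write a measurement report CSV
#'
#' One row per animal: id, the four traits in centimeters, and per-trait
#' relative error (percent) when ground truth is supplied. Traits that could
#' not be measured are written as empty cells, never as 0.
#'
#' @param measurements Non-empty list of `body_measurements` (optionally
#'   named by animal id; each element may carry a `gt` attribute with
#'   ground-truth trait values for relative-error columns).
#' @param path Output CSV path.
#' @return Invisibly, the report data.frame.
#' @export
write_report <- function(measurements, path) {
  if (!length(measurements))
    stop_bovi("measurement list is empty", class = "io_error")
  traits <- c("withers_height_cm", "hip_height_cm", "body_length_cm",
              "cannon_circumference_cm")
  has_gt <- any(vapply(measurements, function(m) !is.null(attr(m, "gt")), logical(1)))
  ids <- names(measurements) %||% as.character(seq_along(measurements))
  if (is.null(names(measurements))) ids <- as.character(seq_along(measurements))
  rows <- lapply(seq_along(measurements), function(i) {
    m <- measurements[[i]]
    vals <- vapply(traits, function(tr) {
      v <- m[[tr]]
      if (is.null(v) || is.na(v)) NA_real_ else v
    }, numeric(1))
    row <- c(list(id = ids[i]), as.list(vals))
    if (has_gt) {
      gt <- attr(m, "gt")
      res <- vapply(traits, function(tr) {
        g <- gt[[tr]]
        if (is.null(g) || is.na(g) || is.na(vals[[tr]])) NA_real_
        else relative_error(g, vals[[tr]])
      }, numeric(1))
      names(res) <- paste0(sub("_cm$", "", traits), "_re_pct")
      row <- c(row, as.list(res))
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  num <- vapply(report, is.numeric, logical(1))
  report[num] <- lapply(report[num], function(x) ifelse(is.na(x), "", sprintf("%.2f", x)))
  ok <- tryCatch({ utils::write.csv(report, path, row.names = FALSE, quote = FALSE); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop_bovi("cannot write report to ", path, class = "io_error")
  invisible(report)
}
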