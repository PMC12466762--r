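test_that("back-projection follows the inverse pinhole model", {
  K <- default_intrinsics()
  expect_equal(backproject(319.5, 239.5, 2.0, K), cbind(X = 0, Y = 0, Z = 2.0))
  p <- backproject(844.5, 239.5, 1.0, K)
  expect_equal(unname(p), cbind(1.0, 0, 1.0))  # (844.5 - 319.5) / 525 = 1
  expect_error(backproject(100, 100, 0, K), class = "missing_depth_error")
  expect_error(backproject(100, 100, 0, K), regexp = "u=100")
})

test_that("projecting a back-projected pixel recovers it to 1e-9 px", {
  K <- default_intrinsics()
  set.seed(5)
  u <- runif(500, 0, 847); v <- runif(500, 0, 479); Z <- runif(500, 0.2, 6)
  uv <- project(backproject(u, v, Z, K), K)
  expect_lt(max(abs(uv[, 1] - u)), 1e-9)
  expect_lt(max(abs(uv[, 2] - v)), 1e-9)
})

test_that("frame-to-cloud samples valid pixels at the requested stride", {
  color <- array(0.5, c(4, 4, 3))
  d <- matrix(1.0, 4, 4)
  K <- camera_intrinsics(10, 10, 2, 2)
  fr <- rgbd_frame(color, d, K)
  expect_equal(nrow(frame_to_cloud(fr)$points), 16L)
  expect_true(all(frame_to_cloud(fr)$points[, 3] == 1.0))

  d2 <- d; d2[c(1, 6, 11)] <- 0
  fr2 <- rgbd_frame(color, d2, K)
  expect_equal(nrow(frame_to_cloud(fr2)$points), 13L)
  expect_equal(nrow(frame_to_cloud(fr, stride = 2)$points), 4L)
})

test_that("pass-through keeps the open interval and conserves points", {
  z <- c(0.5, 2.0, 4.9, 5.1, 6.0)
  cloud <- point_cloud(cbind(0, 0, z), "camera")
  out <- passthrough_filter(cloud, 0.1, 5.0)
  expect_equal(nrow(out$points), 3L)
  expect_equal(attr(out, "n_kept") + attr(out, "n_removed"), 5L)

  # exact boundary Z = z2 is removed (open interval)
  bnd <- passthrough_filter(point_cloud(cbind(0, 0, 5.0), "camera"), 0.1, 5.0)
  expect_equal(nrow(bnd$points), 0L)
  lo <- passthrough_filter(point_cloud(cbind(0, 0, 0.1), "camera"), 0.1, 5.0)
  expect_equal(nrow(lo$points), 0L)

  empty <- passthrough_filter(point_cloud(NULL, "camera"))
  expect_equal(nrow(empty$points), 0L)

  set.seed(7)
  for (rep in 1:5) {
    zz <- runif(200, 0, 8)
    f <- passthrough_filter(point_cloud(cbind(0, 0, zz), "camera"), 0.1, 5)
    expect_equal(attr(f, "n_kept") + attr(f, "n_removed"), 200L)
  }
})

test_that("rigid camera-to-world transforms behave and validate", {
  p <- cbind(0, 0, 2)
  expect_equal(to_world(p, extrinsics()), p)
  expect_equal(to_world(p, extrinsics(T = c(0, 0, 1)))[3], 3)

  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  ext <- extrinsics(R, c(0.3, -0.2, 1.1))
  set.seed(13)
  pts <- matrix(runif(30, -2, 2), 10, 3)
  w <- to_world(pts, ext)
  expect_equal(to_camera(w, ext), pts, tolerance = 1e-9)
  # pairwise distances preserved
  expect_equal(as.numeric(dist(w)), as.numeric(dist(pts)), tolerance = 1e-9)

  expect_error(extrinsics(matrix(1, 3, 3)), class = "extrinsics_error")
  # reflection (det -1) rejected
  expect_error(extrinsics(diag(c(1, 1, -1))), class = "extrinsics_error")
})

test_that("ground estimation takes the lower-half median near hoof hints", {
  # flat floor at 0 with hints on it
  set.seed(17)
  floor_pts <- cbind(runif(300, -0.1, 0.1), runif(300, -0.1, 0.1), 0)
  cloud <- point_cloud(floor_pts, "world")
  g <- estimate_ground(cloud, c(0, 0, 0), radius = 0.2, min_support = 50)
  expect_equal(g$z0, 0)
  expect_equal(sum(g$normal^2), 1)
  expect_gte(g$support_count, 50)

  # floor at 0.05 m plus limb points at 0.3 m within the radius
  floor2 <- cbind(runif(120, -0.1, 0.1), runif(120, -0.1, 0.1),
                  0.05 + rnorm(120, sd = 0.002))
  limb <- cbind(runif(40, -0.02, 0.02), runif(40, -0.02, 0.02), 0.3)
  g2 <- estimate_ground(point_cloud(rbind(floor2, limb), "world"),
                        c(0, 0, 0.05), radius = 0.35, min_support = 50)
  expect_lt(abs(g2$z0 - 0.05), 0.01)

  # duplicated floor points do not move the median
  g3 <- estimate_ground(point_cloud(rbind(floor2, floor2, floor2, limb), "world"),
                        c(0, 0, 0.05), radius = 0.35, min_support = 50)
  expect_lt(abs(g3$z0 - g2$z0), 0.002)

  expect_error(estimate_ground(cloud, c(5, 5, 5), radius = 0.1),
               class = "ground_error")
  expect_error(estimate_ground(cloud, c(5, 5, 5), radius = 0.1),
               regexp = "larger radius")
})

test_that("keypoint depth lookup rounds, falls back to the 5x5 median, and flags it", {
  d <- matrix(2, 9, 9)
  expect_equal(lookup_depth(depth_map(d), 4.4, 3.6), list(Z = 2, interpolated = FALSE))
  d2 <- d; d2[5, 5] <- 0; d2[4, 4] <- 1.7; d2[6, 6] <- 2.3
  got <- lookup_depth(depth_map(d2), 4, 4)  # 0-based -> matrix [5,5]
  expect_true(got$interpolated)
  expect_equal(got$Z, 2)  # median of the 24 valid window values
  none <- lookup_depth(depth_map(matrix(0, 9, 9)), 4, 4)
  expect_true(is.na(none$Z))
})
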