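test_that("OKS matches its closed form on identity, calibrated and limit cases", {
  gt <- make_kps(u = c(10, 50, 90, 130, 170, 210), v = rep(100, 6),
                 bbox_area = 40000)
  cfg <- oks_config()
  expect_equal(oks(gt, gt, cfg), 1)

  # one visible keypoint displaced so d^2 = 2 s^2 sigma^2 -> exp(-1)
  s <- sqrt(40000); sig <- 0.05
  one <- keypoint_set(data.frame(name = "withers_top", u = 10, v = 100),
                      bbox_area = 40000)
  moved <- keypoint_set(data.frame(name = "withers_top",
                                   u = 10 + sqrt(2) * s * sig, v = 100),
                        bbox_area = 40000)
  expect_equal(oks(moved, one, cfg), exp(-1))

  # two visible keypoints, one exact and one far away -> 0.5
  two_gt <- keypoint_set(data.frame(name = c("withers_top", "hip_top"),
                                    u = c(10, 50), v = c(100, 100)),
                         bbox_area = 40000)
  two_pred <- keypoint_set(data.frame(name = c("withers_top", "hip_top"),
                                      u = c(10, 1e7), v = c(100, 100)),
                           bbox_area = 40000)
  expect_equal(oks(two_pred, two_gt, cfg), 0.5)

  none <- suppressWarnings(keypoint_set(
    data.frame(name = keypoint_names(), u = 0, v = 0, visibility = 0L),
    bbox_area = 1))
  expect_error(oks(gt, none, cfg), class = "undefined_oks_error")
})

test_that("OKS is translation-invariant and scale-compensated", {
  set.seed(41)
  cfg <- oks_config()
  for (rep in 1:10) {
    u <- runif(6, 50, 400); v <- runif(6, 50, 400)
    gt <- make_kps(u, v, bbox_area = 35000)
    pred <- make_kps(u + rnorm(6, sd = 4), v + rnorm(6, sd = 4), bbox_area = 35000)
    base <- oks(pred, gt, cfg)
    shift_gt <- make_kps(u + 37, v - 12, bbox_area = 35000)
    shift_pred <- make_kps(pred$keypoints$u + 37, pred$keypoints$v - 12,
                           bbox_area = 35000)
    expect_equal(oks(shift_pred, shift_gt, cfg), base, tolerance = 1e-12)

    k <- runif(1, 0.5, 3)
    sc_gt <- make_kps(k * u, k * v, bbox_area = k^2 * 35000)
    sc_pred <- make_kps(k * pred$keypoints$u, k * pred$keypoints$v,
                        bbox_area = k^2 * 35000)
    expect_equal(oks(sc_pred, sc_gt, cfg), base, tolerance = 1e-12)
  }
})

test_that("threshold AP counts strict exceedances and is monotone in T", {
  expect_equal(ap_at_threshold(c(0.9, 0.6, 0.3), 0.5), 2 / 3)
  expect_equal(ap_at_threshold(c(0.9, 0.8), 0.5), 1)
  expect_equal(ap_at_threshold(c(0.5), 0.5), 0)  # tie does not count
  expect_error(ap_at_threshold(numeric(0), 0.5), class = "eval_error")

  set.seed(43)
  grid <- seq(0.5, 0.95, 0.05)
  for (rep in 1:20) {
    vals <- runif(sample(1:30, 1))
    ap <- vapply(grid, function(T) ap_at_threshold(vals, T), numeric(1))
    expect_true(all(diff(ap) <= 0))
  }
})

test_that("mAP is the arithmetic mean over categories or the 10-threshold grid", {
  expect_equal(mean_ap(c(0.8, 0.6)), 0.7)
  expect_equal(mean_ap(0.42), 0.42)
  expect_error(mean_ap(numeric(0)), class = "eval_error")

  vals <- c(0.97, 0.93, 0.88, 0.81, 0.52, 0.49, 0.2)
  grid <- seq(0.50, 0.95, by = 0.05)
  expect_length(grid, 10L)
  ap <- vapply(grid, function(T) ap_at_threshold(vals, T), numeric(1))
  manual <- mean(vapply(grid, function(T) mean(vals > T), numeric(1)))
  expect_equal(mean_ap(ap), manual)
})

test_that("precision and recall follow the count definitions with flagged 0/0", {
  pr <- precision_recall(8, 2, 2)
  expect_equal(pr$precision, 0.8)
  expect_equal(pr$recall, 0.8)
  z <- precision_recall(0, 0, 3)
  expect_equal(z$precision, 0)
  expect_true(z$degenerate["precision"])
  perfect <- precision_recall(5, 0, 0)
  expect_equal(c(perfect$precision, perfect$recall), c(1, 1))
  expect_error(precision_recall(-1, 0, 0), class = "eval_error")
})

test_that("greedy matching handles surplus, missing and multiple instances", {
  gt1 <- make_kps(u = 1:6 * 20, v = rep(50, 6), bbox_area = 10000)
  pred1 <- make_kps(u = 1:6 * 20 + 0.5, v = rep(50, 6), bbox_area = 10000)
  m <- match_predictions(list(pred1), list(gt1))
  expect_equal(length(m$oks), 1L)
  expect_equal(m$unmatched_pred, 0L)
  expect_equal(m$unmatched_gt, 0L)
  expect_equal(m$fn, 0L)

  far <- make_kps(u = 1:6 * 20 + 3000, v = rep(50, 6), bbox_area = 10000)
  m2 <- match_predictions(list(pred1, far), list(gt1))
  expect_equal(m2$unmatched_pred, 1L)

  m3 <- match_predictions(list(), list(gt1))
  expect_equal(m3$fn, 6L)
  expect_equal(m3$unmatched_gt, 1L)
})

test_that("greedy matching agrees with exhaustive max-OKS enumeration on separated scenes", {
  cfg <- oks_config()
  set.seed(47)
  for (rep in 1:8) {
    n <- sample(2:3, 1)
    centers <- seq(200, by = 1500, length.out = n)[sample(n)]
    gts <- lapply(centers, function(cc)
      make_kps(u = cc + 1:6 * 10, v = rep(100, 6), bbox_area = 8000))
    preds <- lapply(centers, function(cc)
      make_kps(u = cc + 1:6 * 10 + rnorm(6, sd = 3),
               v = 100 + rnorm(6, sd = 3), bbox_area = 8000,
               confidence = runif(1, 0.5, 1)))
    preds <- preds[sample(n)]
    got <- match_predictions(preds, gts, cfg)

    perms <- if (n == 2) list(1:2, 2:1) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    best <- -Inf; best_perm <- NULL
    for (pm in perms) {
      tot <- sum(vapply(seq_len(n), function(i) oks(preds[[i]], gts[[pm[i]]], cfg),
                        numeric(1)))
      if (tot > best) { best <- tot; best_perm <- pm }
    }
    expect_equal(sum(got$oks), best, tolerance = 1e-9)
    ord <- order(got$matches[, "pred"])
    expect_equal(unname(got$matches[ord, "gt"]), best_perm)
  }
})

test_that("evaluation summary aggregates AP, mAP, precision and recall coherently", {
  gt <- make_kps(u = 1:6 * 30, v = rep(80, 6), bbox_area = 20000)
  pred <- perturb_keypoints(gt, sd_px = 2, seed = 9)
  s <- evaluate_keypoints(list(pred), list(gt))
  expect_true(all(s$ap >= 0 & s$ap <= 1))
  expect_equal(s$map, mean(s$ap))
  expect_equal(s$tp + s$fn, 6L)  # one gt instance, six visible landmarks
  expect_s3_class(s, "eval_summary")
})

test_that("AP-delta and split arithmetic utilities", {
  expect_equal(ap_improvement(0.9310, 0.9096), 2.14)
  expect_equal(split_counts(7077), c(train = 4954, validation = 1415, test = 708))
  expect_equal(sum(split_counts(7077)), 7077)
  expect_equal(split_counts(10, c(7, 2, 1)), c(train = 7, validation = 2, test = 1))
})
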