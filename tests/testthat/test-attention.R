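test_that("all five attention operators preserve the feature-map shape", {
  set.seed(61)
  shapes <- list(c(1L, 8L, 4L, 6L), c(2L, 16L, 8L, 8L), c(1L, 64L, 5L, 5L))
  for (dm in shapes) {
    x <- array(rnorm(prod(dm)), dm)
    cfg <- block_config(channels = dm[2], num_heads = 4, reduction = 4)
    expect_identical(dim(simam_forward(x)), dm)
    expect_identical(dim(coord_attention_forward(x, reduction = 4)), dm)
    expect_identical(dim(casimam_forward(x, cfg)), dm)
    expect_identical(dim(mhsa_forward(x, num_heads = 4)), dm)
    expect_identical(dim(dramit_forward(x, cfg)), dm)
  }
})

test_that("SimAM gates a constant channel uniformly and adds no parameters", {
  x <- array(0, c(1, 2, 4, 4))
  x[1, 1, , ] <- 3.7      # constant channel: all energies equal
  x[1, 2, , ] <- rnorm(16)
  y <- simam_forward(x)
  expect_equal(y[1, 1, , ], x[1, 1, , ] * sigmoid_ref(0.5), tolerance = 1e-12)

  # parameter census: the operator consumes no weight list at all
  expect_equal(n_parameters(NULL), 0L)
  expect_gt(n_parameters(init_coord_attention(16, 4)), 0)
  expect_gt(n_parameters(init_mhsa(16, 4)), 0)

  expect_error(simam_forward(x, lambda = 0), class = "attention_error")
  expect_error(simam_forward(array(1, c(1, 1, 1, 1))), class = "attention_error")
})

test_that("coordinate attention gates lie in (0,1), zero maps to zero, batches are independent", {
  set.seed(67)
  x <- array(rnorm(2 * 16 * 8 * 8), c(2, 16, 8, 8))
  w <- init_coord_attention(16, 4, seed = 2)
  y <- coord_attention_forward(x, reduction = 4, weights = w)
  ratio <- abs(y[abs(x) > 1e-8] / x[abs(x) > 1e-8])
  expect_true(all(ratio > 0 & ratio < 1))

  zero <- array(0, c(1, 16, 8, 8))
  expect_true(all(coord_attention_forward(zero, 4, weights = w) == 0))

  perm <- x[2:1, , , , drop = FALSE]
  yp <- coord_attention_forward(perm, reduction = 4, weights = w)
  expect_equal(yp[2, , , ], y[1, , , ], tolerance = 1e-12)

  expect_error(coord_attention_forward(x, reduction = 32), class = "attention_error")
})

test_that("CASimAM is exactly coordinate attention after SimAM", {
  set.seed(71)
  x <- array(rnorm(1 * 16 * 6 * 6), c(1, 16, 6, 6))
  cfg <- block_config(channels = 16, reduction = 4, seed = 5)
  w <- init_coord_attention(16, 4, seed = 5)
  expect_equal(casimam_forward(x, cfg, weights = w),
               coord_attention_forward(simam_forward(x, cfg$lambda),
                                       reduction = 4, weights = w),
               tolerance = 1e-12)
  # deterministic for fixed weights and input
  expect_identical(casimam_forward(x, cfg, weights = w),
                   casimam_forward(x, cfg, weights = w))
})

test_that("MHSA attention is row-stochastic and degenerates correctly", {
  set.seed(73)
  x <- array(rnorm(1 * 16 * 4 * 5), c(1, 16, 4, 5))
  res <- mhsa_forward(x, num_heads = 4, seed = 3, return_attention = TRUE)
  for (A in res$attention[[1]]) {
    expect_equal(dim(A), c(20, 20))
    expect_equal(rowSums(A), rep(1, 20), tolerance = 1e-6)
    expect_true(all(A >= 0))
  }
  expect_identical(dim(res$out), dim(x))

  # single spatial position: the attention weight is exactly 1 and the
  # output is the fused value projection
  x1 <- array(rnorm(16), c(1, 16, 1, 1))
  w <- init_mhsa(16, 4, seed = 3)
  r1 <- mhsa_forward(x1, num_heads = 4, weights = w, return_attention = TRUE)
  expect_equal(r1$attention[[1]][[1]], matrix(1, 1, 1))
  manual <- as.numeric(matrix(x1, 1, 16) %*% w$wv %*% w$wo + w$bo)
  expect_equal(as.numeric(r1$out), manual, tolerance = 1e-9)

  expect_error(mhsa_forward(x, num_heads = 3), class = "attention_error")
})

test_that("the dual-branch transformer respects its mixing gate and stays finite", {
  set.seed(79)
  x <- array(rnorm(1 * 8 * 5 * 5), c(1, 8, 5, 5))
  cfg <- block_config(channels = 8, num_heads = 2, reduction = 2, seed = 7)
  w <- init_dramit(8, seed = 7)

  # gate saturated toward the spatial branch: corrupting the channel
  # branch weights must not change the output
  w_sp <- w; w_sp$gate_logit <- rep(40, 8)
  w_sp2 <- w_sp; w_sp2$channel$wv <- w_sp2$channel$wv * 100 + 3
  expect_equal(dramit_forward(x, cfg, weights = w_sp),
               dramit_forward(x, cfg, weights = w_sp2), tolerance = 1e-9)
  # and symmetrically for the channel branch
  w_ch <- w; w_ch$gate_logit <- rep(-40, 8)
  w_ch2 <- w_ch; w_ch2$spatial$wq <- w_ch2$spatial$wq + 5
  expect_equal(dramit_forward(x, cfg, weights = w_ch),
               dramit_forward(x, cfg, weights = w_ch2), tolerance = 1e-9)

  expect_identical(dramit_forward(x, cfg, weights = w),
                   dramit_forward(x, cfg, weights = w))
})

test_that("operators map bounded inputs to finite outputs", {
  set.seed(83)
  x <- array(runif(1 * 8 * 6 * 6, -1e3, 1e3), c(1, 8, 6, 6))
  cfg <- block_config(channels = 8, num_heads = 2, reduction = 2)
  expect_true(all(is.finite(simam_forward(x))))
  expect_true(all(is.finite(coord_attention_forward(x, 2))))
  expect_true(all(is.finite(casimam_forward(x, cfg))))
  expect_true(all(is.finite(mhsa_forward(x, 2))))
  expect_true(all(is.finite(dramit_forward(x, cfg))))
})

test_that("block configs validate and export the three insertion points", {
  expect_error(block_config(channels = 10, num_heads = 4), class = "attention_error")
  expect_error(block_config(lambda = -1), class = "attention_error")
  ip <- insertion_points()
  expect_setequal(names(ip), c("casimam", "dramit_transformer", "mhsa_c2f"))
  expect_equal(ip$dramit_transformer, "p3_head_layer15")

  tmp <- withr::local_tempdir()
  cfg_path <- file.path(tmp, "blocks.yaml")
  write_block_config(cfg_path)
  y <- yaml::read_yaml(cfg_path)
  expect_equal(y$casimam$insertion_point, "backbone")
  expect_equal(y$mhsa_c2f$insertion_point, "pre_detect_head")
})
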