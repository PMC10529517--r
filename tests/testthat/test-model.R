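test_that("backbone taps halve resolution per stage with the set channels", {
  m <- hc_model(input_size = 64, seed = 1)
  x <- array(runif(64 * 64 * 5), c(64, 64, 5, 1))
  taps <- extract_stage_features(m, x)
  expect_length(taps, 4)
  expect_equal(vapply(taps, function(t) dim(t)[1], 0), c(32, 16, 8, 4))
  expect_equal(vapply(taps, function(t) dim(t)[3], 0), c(16, 32, 64, 128))
  # eval-mode determinism
  taps2 <- extract_stage_features(m, x)
  expect_identical(taps, taps2)
})

test_that("hypercolumn concatenates channels at the first tap's resolution", {
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(8, 16, 32),
                seed = 2)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2, 1))
  hc <- build_hypercolumn(m, x)
  expect_equal(dim(hc), c(16, 16, 56, 1))
  # constant maps stay constant through bilinear resampling: feed a
  # constant directly through the resampler used for stacking
  const <- array(3.7, c(4, 4, 2, 1))
  up <- hypercam:::cpp_resize_bilinear(const, 16L, 16L)
  expect_equal(as.vector(up), rep(3.7, 16 * 16 * 2), tolerance = 1e-12)
})

test_that("identity CBAM gates reduce the model to a plain hypercolumn", {
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 3)
  plain <- m
  plain$config$cbam_gate <- "identity"
  x <- array(runif(32 * 32 * 2), c(32, 32, 2, 1))
  hc_gated <- build_hypercolumn(m, x)
  hc_plain <- build_hypercolumn(plain, x)
  # identical taps, but the gated version is attenuated by attention in (0,1)
  expect_equal(dim(hc_gated), dim(hc_plain))
  expect_false(isTRUE(all.equal(hc_gated, hc_plain)))
  expect_lte(max(abs(hc_gated)), max(abs(hc_plain)) + 1e-12)
})

test_that("classification head: zero weights give probability one half", {
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 4)
  m$params$fc_w[] <- 0
  m$params$fc_b <- 0
  x <- array(runif(32 * 32 * 2 * 3), c(32, 32, 2, 3))
  expect_equal(predict_hc(m, x)$prob, rep(0.5, 3))
})

test_that("probabilities stay in (0,1) and batch order permutes outputs", {
  set.seed(5)
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 5)
  x <- array(runif(32 * 32 * 2 * 8), c(32, 32, 2, 8))
  p <- predict_hc(m, x)$prob
  expect_true(all(p > 0 & p < 1))
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  p2 <- predict_hc(m, x[, , , perm])$prob
  expect_equal(p2, p[perm], tolerance = 1e-12)
})

test_that("coordinate head emits canonical normalized corners", {
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                with_coords = TRUE, seed = 6)
  x <- array(runif(32 * 32 * 2 * 4), c(32, 32, 2, 4))
  out <- predict_hc(m, x)
  b <- out$boxes_norm
  expect_equal(dim(b), c(4, 4))
  expect_true(all(b >= 0 & b <= 1))
  expect_true(all(b["x_min", ] <= b["x_max", ]))
  expect_true(all(b["y_min", ] <= b["y_max", ]))
})

test_that("autodiff matches finite differences end to end", {
  m <- hc_model(input_size = 16, input_channels = 2, channels = c(4, 6),
                reduction = 2, seed = 7)
  set.seed(7)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  fw <- hypercam:::hc_forward(m, x)
  bw <- hypercam:::hc_backward(m, fw$cache, dlogit = 1)
  eps <- 1e-5
  idx <- sample(length(x), 6)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    fd <- (hypercam:::hc_forward(m, xp)$logit -
             hypercam:::hc_forward(m, xm)$logit) / (2 * eps)
    expect_equal(bw$dx[i], fd, tolerance = 1e-3)
  }
  # the input gradient of a real model is not identically zero
  expect_gt(max(abs(bw$dx)), 0)
  # spot-check parameter gradients across layers
  for (nm in c("s1_conv1_w", "s2_conv2_w", "s1_cbam_ch_W0", "s2_cbam_sp_w",
               "fc_w")) {
    pv <- m$params[[nm]]
    i <- sample(length(pv), 1)
    mp <- m; mp$params[[nm]][i] <- pv[i] + eps
    mm <- m; mm$params[[nm]][i] <- pv[i] - eps
    fd <- (hypercam:::hc_forward(mp, x)$logit -
             hypercam:::hc_forward(mm, x)$logit) / (2 * eps)
    expect_equal(bw$grads[[nm]][i], fd, tolerance = 1e-3)
  }
})

test_that("the coordinate loss gradient matches finite differences", {
  m <- hc_model(input_size = 16, input_channels = 2, channels = c(4, 6),
                reduction = 2, with_coords = TRUE, seed = 11)
  set.seed(11)
  x <- array(runif(16 * 16 * 2 * 2), c(16, 16, 2, 2))
  tgt <- matrix(runif(8), 4, 2)
  loss_of <- function(model) {
    f <- hypercam:::hc_forward(model, x)
    smooth_l1(f$coords_raw, tgt)
  }
  f0 <- hypercam:::hc_forward(m, x)
  dc <- hypercam:::smooth_l1_grad(f0$coords_raw, tgt)
  bw <- hypercam:::hc_backward(m, f0$cache, dlogit = c(0, 0),
                               dcoords_raw = dc)
  eps <- 1e-5
  for (nm in c("coord_w", "s1_conv1_w", "s2_cbam_ch_W1")) {
    pv <- m$params[[nm]]
    for (i in sample(length(pv), 2)) {
      mp <- m; mp$params[[nm]][i] <- pv[i] + eps
      mm <- m; mm$params[[nm]][i] <- pv[i] - eps
      fd <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      expect_equal(bw$grads[[nm]][i], fd, tolerance = 1e-3)
    }
  }
})

test_that("nearest upsampling and post-upsample gating stay differentiable", {
  set.seed(9)
  x <- array(runif(16 * 16 * 2), c(16, 16, 2, 1))
  for (variant in list(list(upsample = "nearest", after = FALSE),
                       list(upsample = "bilinear", after = TRUE))) {
    m <- hc_model(input_size = 16, input_channels = 2, channels = c(4, 6),
                  reduction = 2, upsample = variant$upsample,
                  cbam_after_upsample = variant$after, seed = 9)
    fw <- hypercam:::hc_forward(m, x)
    expect_equal(dim(fw$cache$hc), c(8, 8, 10, 1))
    bw <- hypercam:::hc_backward(m, fw$cache, dlogit = 1)
    eps <- 1e-5
    for (i in sample(length(x), 3)) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      fd <- (hypercam:::hc_forward(m, xp)$logit -
               hypercam:::hc_forward(m, xm)$logit) / (2 * eps)
      expect_equal(bw$dx[i], fd, tolerance = 1e-3)
    }
  }
  # nearest resampling of a constant stays constant
  const <- array(2.5, c(4, 4, 1, 1))
  up <- hypercam:::resize_fwd(const, 8, 8, "nearest")
  expect_true(all(up == 2.5))
})

test_that("checkpoints round-trip through disk", {
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 8)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(m2$params, m$params)
  expect_equal(m2$config, m$config)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2, 1))
  expect_identical(predict_hc(m, x)$prob, predict_hc(m2, x)$prob)
})
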