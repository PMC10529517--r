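test_that("heatmap normalization attains 0 and 255 unless degenerate", {
  set.seed(1)
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 1)
  for (i in 1:5) {
    x <- array(runif(32 * 32 * 2), c(32, 32, 2))
    h <- grad_cam(m, x)
    if (!h$degenerate) {
      expect_equal(min(h$values), 0L)
      expect_equal(max(h$values), 255L)
    }
    expect_true(all(h$values >= 0 & h$values <= 255))
    expect_equal(dim(h$values), c(32, 32))
  }
})

test_that("a flat raw surface yields an all-zero degenerate heatmap", {
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 2)
  # zero head weights kill the gradient, so every channel weight is zero
  m$params$fc_w[] <- 0
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  h <- grad_cam(m, x)
  expect_true(h$degenerate)
  expect_true(all(h$values == 0L))
})

test_that("score = spatial mean of one channel makes the CAM that channel", {
  # head reads only the average pool of hypercolumn channel 3, so the
  # class score is its spatial mean and all gradient weight lands there
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(4, 8),
                seed = 3)
  m$params$fc_w[] <- 0
  m$params$fc_b <- 0
  k <- 3
  m$params$fc_w[1, k] <- 1 # avg-pool slot of channel k
  set.seed(3)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  hc <- build_hypercolumn(m, x)
  h <- grad_cam(m, x)
  expected <- hc[, , k, 1] # already >= 0 downstream of ReLU and gates
  up <- matrix(hypercam:::cpp_resize_bilinear(
    array(expected, c(dim(expected), 1)), 32L, 32L), 32, 32)
  # proportionality of the raw surface
  expect_gt(stats::cor(as.vector(h$raw), as.vector(up)), 1 - 1e-9)
  ratio <- h$raw[up > 1e-8] / up[up > 1e-8]
  expect_lt(diff(range(ratio)), 1e-6 * max(ratio))
})

test_that("grad-cam channel weights match an independent head recomputation", {
  # with max-pool weights zeroed, d(score)/d(hc[h,w,c]) = w_avg[c] / (H W),
  # so the raw map must equal sum_c w_avg[c] A_c / (H W)
  m <- hc_model(input_size = 32, input_channels = 2, channels = c(2, 2),
                reduction = 2, seed = 4)
  Call <- 4
  m$params$fc_w[] <- 0
  set.seed(4)
  m$params$fc_w[1, seq_len(Call)] <- rnorm(Call)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2))
  hc <- build_hypercolumn(m, x)
  d <- dim(hc)
  manual <- matrix(0, d[1], d[2])
  for (c in seq_len(Call))
    manual <- manual + m$params$fc_w[1, c] * hc[, , c, 1] / (d[1] * d[2])
  manual <- pmax(manual, 0)
  up <- matrix(hypercam:::cpp_resize_bilinear(array(manual, c(d[1], d[2], 1)),
                                              32L, 32L), 32, 32)
  h <- grad_cam(m, x)
  expect_equal(h$raw, up, tolerance = 1e-3)
})

test_that("heatmap_to_boxes finds components, orders by peak, obeys min_area", {
  h <- matrix(0L, 100, 100)
  expect_equal(nrow(heatmap_to_boxes(h)), 0)
  h[41:50, 61:70] <- 255L
  b <- heatmap_to_boxes(h, threshold = 230)
  expect_equal(nrow(b), 1)
  expect_equal(unlist(b[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 60, y_min = 40, x_max = 70, y_max = 50))
  # second, weaker blob: ordered after the bright one
  h[10:14, 10:14] <- 240L
  b2 <- heatmap_to_boxes(h, threshold = 230)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$peak, c(255, 240))
  expect_equal(b2$x_min[2], 9)
  # a tiny 2-pixel component is dropped by min_area = 4
  h2 <- matrix(0L, 20, 20)
  h2[5, 5:6] <- 255L
  expect_equal(nrow(heatmap_to_boxes(h2)), 0)
  expect_equal(nrow(heatmap_to_boxes(h2, min_area = 2)), 1)
})

test_that("raising the threshold never enlarges a surviving box", {
  set.seed(5)
  h <- matrix(as.integer(pmin(255, pmax(0, 128 + 90 * matrix(
    as.vector(stats::filter(rnorm(40 * 40), rep(1 / 3, 3), sides = 2,
                            circular = TRUE)), 40)))), 40, 40)
  for (th in c(140, 180, 220)) {
    lo <- heatmap_to_boxes(h, threshold = th, min_area = 1)
    hi <- heatmap_to_boxes(h, threshold = th + 20, min_area = 1)
    for (i in seq_len(nrow(hi))) {
      # each surviving high-threshold box nests inside some low-threshold box
      contained <- vapply(seq_len(nrow(lo)), function(j)
        hi$x_min[i] >= lo$x_min[j] && hi$x_max[i] <= lo$x_max[j] &&
          hi$y_min[i] >= lo$y_min[j] && hi$y_max[i] <= lo$y_max[j], TRUE)
      expect_true(any(contained))
    }
  }
})

test_that("overlay blends the jet colormap over the image", {
  px <- matrix(128, 10, 10)
  cold <- overlay_heatmap(px, matrix(0L, 10, 10), alpha = 1)
  hot <- overlay_heatmap(px, matrix(255L, 10, 10), alpha = 1)
  expect_gt(mean(cold[, , 3]), mean(cold[, , 1])) # blue end
  expect_gt(mean(hot[, , 1]), mean(hot[, , 3]))   # red end
  ident <- overlay_heatmap(px, matrix(100L, 10, 10), alpha = 0)
  expect_equal(ident[, , 1], px)
  expect_equal(dim(cold), c(10, 10, 3))
  expect_error(overlay_heatmap(px, matrix(0L, 5, 5)), "size")
})
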