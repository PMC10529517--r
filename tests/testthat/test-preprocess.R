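test_that("clahe_stack returns five channels with the input untouched first", {
  set.seed(1)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  st <- clahe_stack(img)
  expect_equal(dim(st), c(64, 64, 5))
  expect_identical(st[, , 1], img)
  expect_error(clahe_stack(st), "single-channel")
})

test_that("higher clip limits give at least as much contrast", {
  # low-contrast image, tiles large enough that the clip limit bites
  set.seed(2)
  img <- matrix(runif(128 * 128, 80, 170), 128)
  st <- clahe_stack(img, preprocess_config(tile_grid = c(4, 4)))
  sds <- apply(st[, , 2:5], 3, sd)
  expect_true(all(diff(sds) > -1e-6))
})

test_that("preprocess_config validates its invariants", {
  expect_error(preprocess_config(clip_limits = c(1, 2, 3)), "exactly 4")
  expect_error(preprocess_config(clip_limits = c(0.5, 1, 2, 3)), "exactly 4")
  expect_error(preprocess_config(clip_limits = c(4, 3, 2, 1)), "ascending")
  expect_error(preprocess_config(rotation_range = c(-10, 30)), "symmetric")
})

test_that("otsu_crop recovers a centred bone and remaps boxes", {
  set.seed(3)
  cfg <- phantom_config(image_size = 96, style = "mura_like",
                        fracture_fraction = 1, seed = 31)
  rec <- generate_phantom_dataset(cfg, 1)$records[[1]]
  oc <- otsu_crop(rec, frame = 96)
  # the crop zooms into the bone: foreground occupies far more of the frame
  expect_gt(mean(oc$record$pixels > 50), 1.5 * mean(rec$pixels > 50))
  expect_equal(dim(oc$record$pixels), c(96, 96))
  # threshold separates background from bone
  expect_gt(oc$record$meta$otsu_threshold, min(rec$pixels))
  expect_lt(oc$record$meta$otsu_threshold, max(rec$pixels))
  # box survived and stayed in-bounds
  expect_equal(nrow(oc$record$boxes), 1)
  b <- oc$record$boxes
  expect_true(b$x_min >= 0 && b$x_max <= 96 && b$x_min < b$x_max)
  # the transform round-trips exactly (before any frame clipping)
  fwd <- apply_crop_transform(rec$boxes, oc$transform)
  back <- apply_crop_transform(fwd, invert_crop_transform(oc$transform))
  expect_lt(max(abs(unlist(back) - unlist(rec$boxes))), 1e-8)
  expect_error(otsu_crop(image_record(matrix(5, 8, 8), 0)), "variance")
})

test_that("augmentation identities hold", {
  set.seed(4)
  cfg <- phantom_config(image_size = 64, fracture_fraction = 1, seed = 41)
  rec <- generate_phantom_dataset(cfg, 1)$records[[1]]
  id_cfg <- preprocess_config(rotation_range = c(0, 0), hflip_prob = 0,
                              invert_prob = 0)
  out <- augment_record(rec, id_cfg)
  expect_identical(out$pixels, rec$pixels)
  expect_equal(out$boxes, rec$boxes)
  expect_identical(out$label, rec$label)
})

test_that("horizontal flip reflects boxes and double inversion is identity", {
  px <- matrix(runif(32 * 32, 0, 255), 32, 32)
  boxes <- boxes_df(x_min = 5, y_min = 10, x_max = 12, y_max = 20)
  a <- hypercam:::augment_tensor(array(px, c(32, 32, 1)), boxes, flip = TRUE)
  expect_equal(a$boxes$x_min, 32 - 12)
  expect_equal(a$boxes$x_max, 32 - 5)
  expect_equal(a$boxes$y_min, 10)
  inv2 <- hypercam:::augment_tensor(
    hypercam:::augment_tensor(array(px, c(32, 32, 1)), boxes,
                              invert = TRUE)$x,
    boxes, invert = TRUE)
  expect_equal(inv2$x[, , 1], px)
})

test_that("rotation commutes with box remapping within a pixel", {
  # rotate a synthetic blob and check its box tracks the blob's pixels
  px <- matrix(0, 64, 64)
  px[28:36, 40:50] <- 200
  boxes <- boxes_df(x_min = 39, y_min = 27, x_max = 50, y_max = 36)
  for (ang in c(15, -30, 90)) {
    a <- hypercam:::augment_tensor(array(px, c(64, 64, 1)), boxes,
                                   angle = ang)
    ii <- which(a$x[, , 1] > 100, arr.ind = TRUE)
    obs <- c(min(ii[, 2]) - 1, min(ii[, 1]) - 1, max(ii[, 2]), max(ii[, 1]))
    exp_b <- unlist(a$boxes[1, c("x_min", "y_min", "x_max", "y_max")])
    expect_lt(max(abs(obs - exp_b)), 1.8)
  }
})

test_that("mixup interpolates pixels and labels exactly", {
  set.seed(5)
  xa <- array(runif(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  xb <- array(runif(8 * 8 * 2 * 4), c(8, 8, 2, 4))
  ya <- c(1, 0, 1, 0); yb <- c(0, 0, 1, 1)
  # forced lambda = 1 returns batch a exactly
  m1 <- mixup_batch(xa, ya, xb, yb, lambda = 1)
  expect_identical(m1$x, xa)
  expect_identical(m1$y, ya)
  # identical batches are a fixed point for any lambda
  m2 <- mixup_batch(xa, ya, xa, ya, alpha = 0.01)
  expect_equal(m2$x, xa)
  expect_equal(m2$y, ya)
  # labels are the exact convex combination
  m3 <- mixup_batch(xa, ya, xb, yb, alpha = 0.5)
  expect_equal(m3$y, m3$lambda * ya + (1 - m3$lambda) * yb)
  expect_error(mixup_batch(xa, ya, xb[, , , 1:2], yb[1:2], 0.5), "shape")
})

test_that("alpha = 0.01 mixing weights are nearly always extreme", {
  set.seed(6)
  xa <- array(0, c(2, 2, 1, 10000)); ya <- numeric(10000)
  m <- mixup_batch(xa, ya, xa, ya, alpha = 0.01)
  expect_gt(mean(m$lambda < 0.01 | m$lambda > 0.99), 0.95)
})
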