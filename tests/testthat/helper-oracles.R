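# Independent oracles and shared fixtures for the test suite.

# literal per-element recomputation of channel attention:
# sigmoid(W1 relu(W0 avg) + W1 relu(W0 max)) with explicit loops
oracle_channel_attention <- function(f, params) {
  C <- dim(f)[3]
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(f[, , c])
    mx[c] <- max(f[, , c])
  }
  mlp <- function(v) {
    h <- as.vector(params$ch_W0 %*% v)
    h[h < 0] <- 0
    as.vector(params$ch_W1 %*% h)
  }
  1 / (1 + exp(-(mlp(avg) + mlp(mx))))
}

# literal recomputation of spatial attention: channel mean/max maps,
# 7x7 convolution by explicit summation, sigmoid
oracle_spatial_attention <- function(f, params) {
  H <- dim(f)[1]; W <- dim(f)[2]
  avg <- apply(f, c(1, 2), mean)
  mx <- apply(f, c(1, 2), max)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    acc <- params$sp_b
    for (ky in 1:7) for (kx in 1:7) {
      iy <- y + ky - 4; ix <- x + kx - 4
      if (iy >= 1 && iy <= H && ix >= 1 && ix <= W)
        acc <- acc + avg[iy, ix] * params$sp_w[ky, kx, 1, 1] +
          mx[iy, ix] * params$sp_w[ky, kx, 2, 1]
    }
    out[y, x] <- 1 / (1 + exp(-acc))
  }
  out
}

oracle_cbam <- function(f, params) {
  mc <- oracle_channel_attention(f, params)
  f1 <- f
  for (c in seq_len(dim(f)[3])) f1[, , c] <- f[, , c] * mc[c]
  ms <- oracle_spatial_attention(f1, params)
  f2 <- f1
  for (c in seq_len(dim(f)[3])) f2[, , c] <- f1[, , c] * ms
  f2
}

# O(n^2) Mann-Whitney pairwise-comparison probability
oracle_auc_mann_whitney <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# downsample a gray matrix to 32x32 (bilinear)
down32 <- function(px) {
  matrix(hypercam:::cpp_resize_bilinear(array(px, c(dim(px), 1)), 32L, 32L),
         32, 32)
}

random_feature_map <- function(C = 3, H = 8, W = 8) {
  array(rnorm(H * W * C), c(H, W, C))
}

# one uniformly random box inside a frame
random_box <- function(frame) {
  cc <- sort(runif(2, 0, frame)); rr <- sort(runif(2, 0, frame))
  data.frame(x_min = cc[1], y_min = rr[1], x_max = cc[2], y_max = rr[2])
}

# small grazped-style dataset prepared for training, memoized per-session
.fixture_env <- new.env(parent = emptyenv())

small_train_fixture <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- phantom_config(image_size = 64, style = "grazped_like",
                          fracture_fraction = 0.5, seed = 71)
    ds <- generate_phantom_dataset(cfg, 80)
    prep <- prepare_dataset(ds$records, frame = 64)
    .fixture_env$small <- prep
  }
  .fixture_env$small
}

subset_data <- function(d, idx) {
  list(x = d$x[, , , idx, drop = FALSE], y = d$y[idx], boxes = d$boxes[idx])
}

# The study-scale training runs shared by the acceptance tests: 400
# grazped-style phantoms, 300/100 split, 20 epochs. Trained once per session.
acceptance_fixture <- function() {
  if (is.null(.fixture_env$accept)) {
    cfg <- phantom_config(image_size = 64, style = "grazped_like",
                          fracture_fraction = 0.5, seed = 101)
    ds <- generate_phantom_dataset(cfg, 400)
    prep <- prepare_dataset(ds$records, frame = 64)
    tr <- subset_data(prep, 1:300)
    va <- subset_data(prep, 301:400)
    fit <- train_model(hc_model(input_size = 64, seed = 101), tr, va,
                       train_config(epochs = 20, lr0 = 5e-4, seed = 101))
    pos_cfg <- phantom_config(image_size = 64, style = "grazped_like",
                              fracture_fraction = 1, seed = 202)
    pos <- generate_phantom_dataset(pos_cfg, 100)
    ppos <- prepare_dataset(pos$records, frame = 64)
    .fixture_env$accept <- list(train = tr, val = va, fit = fit, pos = ppos)
  }
  .fixture_env$accept
}

acceptance_coord_fit <- function() {
  if (is.null(.fixture_env$accept_coord)) {
    ax <- acceptance_fixture()
    .fixture_env$accept_coord <- train_model(
      hc_model(input_size = 64, with_coords = TRUE, seed = 101),
      ax$train, ax$val, train_config(epochs = 20, lr0 = 5e-4, seed = 101))
  }
  .fixture_env$accept_coord
}
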