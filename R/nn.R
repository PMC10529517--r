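# Internal tensor helpers for the hand-rolled network. Layout: H x W x C x N.

# broadcast a C x N matrix over the spatial dims -> H x W x C x N
bcast_channel <- function(v, H, W) {
  array(rep(as.vector(v), each = H * W), c(H, W, nrow(v), ncol(v)))
}

# broadcast an H x W x N array over the channel dim -> H x W x C x N
bcast_spatial <- function(m, C) {
  d <- dim(m)
  aperm(array(m, c(d[1], d[2], d[3], C)), c(1, 2, 4, 3))
}

# scatter per-channel values onto each channel's spatial argmax
# v, which: C x N; returns H x W x C x N
scatter_spatial_max <- function(v, which, H, W) {
  C <- nrow(v); N <- ncol(v)
  out <- array(0, c(H, W, C, N))
  idx <- as.vector(which) + (seq_len(C * N) - 1L) * (H * W)
  out[idx] <- as.vector(v)
  out
}

# scatter per-pixel values onto each pixel's channel argmax
# m, whichc: H x W x N; returns H x W x C x N
scatter_channel_max <- function(m, whichc, C) {
  d <- dim(m); H <- d[1]; W <- d[2]; N <- d[3]
  P <- H * W
  out <- array(0, c(H, W, C, N))
  nvec <- rep(seq_len(N), each = P)
  idx <- rep(seq_len(P), times = N) +
    P * ((as.vector(whichc) - 1L) + C * (nvec - 1L))
  out[idx] <- as.vector(m)
  out
}

# collapse H x W x C x N -> channel-major matrix (H*W*N rows, C cols)
to_channel_mat <- function(x4) {
  d <- dim(x4)
  matrix(aperm(x4, c(1, 2, 4, 3)), ncol = d[3])
}

from_channel_mat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

# Batch normalization over (H, W, N) per channel.
bn_forward <- function(x4, gamma, beta, run_mean, run_var,
                       train = FALSE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x4)
  xm <- to_channel_mat(x4)
  M <- nrow(xm)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    v <- pmax(v, 0)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean
    v <- run_var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
  ym <- xhat * rep(gamma, each = M) + rep(beta, each = M)
  list(y = from_channel_mat(ym, d),
       cache = list(xhat = xhat, istd = istd, d = d, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dy4, cache, gamma) {
  d <- cache$d
  dym <- to_channel_mat(dy4)
  M <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = M)
  if (cache$train) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dxm <- rep(cache$istd / M, each = M) *
      (M * dxhat - rep(s1, each = M) - cache$xhat * rep(s2, each = M))
  } else {
    dxm <- dxhat * rep(cache$istd, each = M)
  }
  list(dx = from_channel_mat(dxm, d), dgamma = dgamma, dbeta = dbeta)
}
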