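#' Initialize CBAM attention parameters
#'
#' The convolutional block attention module gates a feature map twice:
#' channel attention computes one scalar gate per channel from globally
#' pooled descriptors passed through a shared bottleneck MLP, and spatial
#' attention computes one gate per pixel from the channel-pooled mean/max
#' maps convolved with a 7x7 kernel. Both gates are sigmoids, so all
#' attention values lie strictly in (0, 1).
#'
#' The bottleneck MLP reduces `channels` to `ceiling(channels / reduction)`
#' (minimum 1) with a ReLU in between; its two weight matrices are shared
#' between the average-pool and max-pool branches and carry no biases. The
#' 7x7 convolution has a bias.
#'
#' @param channels number of input channels C.
#' @param reduction bottleneck reduction ratio r (default 16).
#' @param seed optional seed for reproducible initialization.
#' @return list with `ch_W0` (hidden x C), `ch_W1` (C x hidden), `sp_w`
#'   (7 x 7 x 2 x 1), `sp_b` (length 1).
#' @export
cbam_params <- function(channels, reduction = 16, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  hidden <- max(1L, ceiling(channels / reduction))
  list(
    ch_W0 = matrix(rnorm(hidden * channels, sd = sqrt(2 / channels)),
                   hidden, channels),
    ch_W1 = matrix(rnorm(channels * hidden, sd = sqrt(2 / hidden)),
                   channels, hidden),
    sp_w = array(rnorm(7 * 7 * 2, sd = sqrt(2 / (7 * 7 * 2))), c(7, 7, 2, 1)),
    sp_b = 0
  )
}

#' Channel attention gate
#'
#' Global average-pool and global max-pool the feature map to two C-vectors,
#' pass each through the shared two-layer MLP, sum, and apply a sigmoid.
#'
#' @param f feature map, array `H x W x C`.
#' @param params a [cbam_params()] list.
#' @return numeric vector of length C with entries in (0, 1).
#' @export
channel_attention <- function(f, params) {
  f4 <- ensure_hwcn(f)
  if (ncol(params$ch_W0) != dim(f4)[3])
    stop("channel_attention: params dimensioned for ", ncol(params$ch_W0),
         " channels, feature map has ", dim(f4)[3])
  sp <- cpp_pool_spatial(f4)
  mlp <- function(v) params$ch_W1 %*% relu(params$ch_W0 %*% v)
  as.vector(sigmoid(mlp(sp$avg) + mlp(sp$max)))
}

#' Spatial attention gate
#'
#' Channel-wise mean and max of the feature map are stacked into a 2-channel
#' map, convolved with a 7x7 kernel (padding 3, size preserved), and passed
#' through a sigmoid.
#'
#' @param f feature map, array `H x W x C`.
#' @param params a [cbam_params()] list.
#' @return `H x W` matrix with entries in (0, 1).
#' @export
spatial_attention <- function(f, params) {
  f4 <- ensure_hwcn(f)
  d <- dim(f4)
  cp <- cpp_pool_channel(f4)
  s2 <- array(0, c(d[1], d[2], 2, 1))
  s2[, , 1, 1] <- cp$avg
  s2[, , 2, 1] <- cp$max
  z <- cpp_conv2d_fwd(s2, params$sp_w, params$sp_b, 1L, 3L)
  matrix(sigmoid(z), d[1], d[2])
}

#' Apply a CBAM block to a feature map
#'
#' Sequential multiplicative gating: by default channel attention first
#' (broadcast over space), then spatial attention on the result (broadcast
#' over channels). Output shape equals input shape, and because both gates
#' are sigmoids the output sup-norm never exceeds the input's.
#'
#' @param f feature map, array `H x W x C`.
#' @param params a [cbam_params()] list.
#' @param order `"channel_first"` (default) or `"spatial_first"`.
#' @return gated feature map, same shape as `f`.
#' @export
cbam_apply <- function(f, params, order = c("channel_first", "spatial_first")) {
  order <- match.arg(order)
  d3 <- dim(f)
  f4 <- ensure_hwcn(f)
  out <- if (order == "channel_first") {
    cbam_forward(f4, params)$out
  } else {
    d <- dim(f4)
    ms <- spatial_attention(f, params)
    f1 <- f4 * bcast_spatial(array(ms, c(d[1], d[2], 1)), d[3])
    mc <- channel_attention(array(f1, d3), params)
    f1 * bcast_channel(matrix(mc, ncol = 1), d[1], d[2])
  }
  array(out, d3)
}

ensure_hwcn <- function(f) {
  d <- dim(f)
  if (length(d) == 3) array(f, c(d, 1)) else f
}

# Batched CBAM forward with cache (channel-then-spatial order).
cbam_forward <- function(x4, prm) {
  d <- dim(x4)
  H <- d[1]; W <- d[2]; C <- d[3]
  sp <- cpp_pool_spatial(x4)
  ha <- prm$ch_W0 %*% sp$avg
  hra <- relu(ha)
  hm <- prm$ch_W0 %*% sp$max
  hrm <- relu(hm)
  mc <- sigmoid(prm$ch_W1 %*% hra + prm$ch_W1 %*% hrm)
  f1 <- x4 * bcast_channel(mc, H, W)
  cp <- cpp_pool_channel(f1)
  s2 <- array(0, c(H, W, 2, d[4]))
  s2[, , 1, ] <- cp$avg
  s2[, , 2, ] <- cp$max
  zs <- cpp_conv2d_fwd(s2, prm$sp_w, prm$sp_b, 1L, 3L)
  ms <- sigmoid(zs) # H x W x 1 x N
  ms3 <- array(ms, c(H, W, d[4]))
  out <- f1 * bcast_spatial(ms3, C)
  list(out = out,
       cache = list(x = x4, sp = sp, ha = ha, hm = hm, hra = hra, hrm = hrm,
                    mc = mc, f1 = f1, cp = cp, s2 = s2, ms3 = ms3, d = d))
}

cbam_backward <- function(dout, cache, prm) {
  d <- cache$d
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ms3 <- cache$ms3
  # spatial gate
  dms <- array(rowSums(matrix(aperm(dout * cache$f1, c(1, 2, 4, 3)),
                              ncol = C)), c(H, W, N))
  df1 <- dout * bcast_spatial(ms3, C)
  dzs <- array(dms * ms3 * (1 - ms3), c(H, W, 1, N))
  cb <- cpp_conv2d_bwd(cache$s2, prm$sp_w, dzs, 1L, 3L)
  davg_map <- array(cb$dx[, , 1, ], c(H, W, N))
  dmax_map <- array(cb$dx[, , 2, ], c(H, W, N))
  df1 <- df1 + bcast_spatial(davg_map / C, C) +
    scatter_channel_max(dmax_map, cache$cp$which, C)
  # channel gate
  dmc <- matrix(colSums(matrix(df1 * cache$x, nrow = H * W)), C, N)
  dx <- df1 * bcast_channel(cache$mc, H, W)
  dz <- dmc * cache$mc * (1 - cache$mc)
  dW1 <- dz %*% t(cache$hra) + dz %*% t(cache$hrm)
  dh_a <- (t(prm$ch_W1) %*% dz) * (cache$ha > 0)
  dh_m <- (t(prm$ch_W1) %*% dz) * (cache$hm > 0)
  dW0 <- dh_a %*% t(cache$sp$avg) + dh_m %*% t(cache$sp$max)
  davg <- t(prm$ch_W0) %*% dh_a
  dmaxv <- t(prm$ch_W0) %*% dh_m
  dx <- dx + bcast_channel(davg / (H * W), H, W) +
    scatter_spatial_max(dmaxv, cache$sp$which, H, W)
  list(dx = dx,
       grads = list(ch_W0 = dW0, ch_W1 = dW1, sp_w = cb$dw, sp_b = cb$db))
}
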