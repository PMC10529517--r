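#' Build a hypercolumn attention classifier
#'
#' The reference desk-scale backbone has one stage per spatial-resolution
#' drop: each stage is a stride-2 3x3 convolution followed by a stride-1
#' 3x3 convolution, both with batch normalization and ReLU, and the stage
#' output is the tap fed to the hypercolumn. On a 64x64 input the four
#' default stages tap feature maps at 32, 16, 8, and 4 pixels with 16, 32,
#' 64, and 128 channels.
#'
#' Each tap passes through its own CBAM gate (channel then spatial
#' attention), is resampled bilinearly to the highest-resolution tap's
#' size, and all taps are concatenated along channels into the hypercolumn.
#' Global average and max pooling of the hypercolumn are concatenated and a
#' fully connected layer plus sigmoid produce the fracture probability.
#' With `with_coords = TRUE` a parallel linear head emits four normalized
#' box coordinates through a sigmoid; it reads the shared pooled vector
#' plus each hypercolumn channel's activation centroid, since globally
#' pooled magnitudes alone are position-invariant and carry no location.
#'
#' @param input_size square input side in pixels.
#' @param input_channels input channels (5 after CLAHE stacking).
#' @param channels per-stage channel counts (one stage per entry).
#' @param reduction CBAM bottleneck reduction ratio.
#' @param per_stage_cbam gate each tap with CBAM (TRUE) or stack raw taps.
#' @param upsample resampling mode for stacking: `"bilinear"` (default) or
#'   `"nearest"`.
#' @param cbam_after_upsample apply the CBAM gates after resampling to the
#'   target resolution instead of at each tap's native resolution
#'   (default FALSE: gating at native resolution is cheaper).
#' @param with_coords add the coordinate-regression head.
#' @param cbam_gate multiplier applied to replace attention with an
#'   all-pass gate for ablation: `"learned"` (default) uses the attention
#'   values, `"identity"` forces every gate to 1, reducing the model to a
#'   plain hypercolumn.
#' @param seed seed for weight initialization.
#' @return an object of class `hc_model`.
#' @export
hc_model <- function(input_size = 64, input_channels = 5,
                     channels = c(16, 32, 64, 128), reduction = 16,
                     per_stage_cbam = TRUE,
                     upsample = c("bilinear", "nearest"),
                     cbam_after_upsample = FALSE, with_coords = FALSE,
                     cbam_gate = c("learned", "identity"), seed = 1L) {
  cbam_gate <- match.arg(cbam_gate)
  upsample <- match.arg(upsample)
  if (length(channels) < 2) stop("need at least 2 backbone stages")
  if (input_size %% (2^length(channels)) != 0)
    stop("input_size must be divisible by 2^stages")
  set.seed(seed)
  params <- list()
  state <- list()
  cin <- input_channels
  he <- function(n, fan) rnorm(n, sd = sqrt(2 / fan))
  for (s in seq_along(channels)) {
    cs <- channels[s]
    p <- sprintf("s%d_", s)
    params[[paste0(p, "conv1_w")]] <- array(he(9 * cin * cs, 9 * cin),
                                            c(3, 3, cin, cs))
    params[[paste0(p, "conv1_b")]] <- numeric(cs)
    params[[paste0(p, "bn1_g")]] <- rep(1, cs)
    params[[paste0(p, "bn1_b")]] <- numeric(cs)
    params[[paste0(p, "conv2_w")]] <- array(he(9 * cs * cs, 9 * cs),
                                            c(3, 3, cs, cs))
    params[[paste0(p, "conv2_b")]] <- numeric(cs)
    params[[paste0(p, "bn2_g")]] <- rep(1, cs)
    params[[paste0(p, "bn2_b")]] <- numeric(cs)
    state[[paste0(p, "bn1_mean")]] <- numeric(cs)
    state[[paste0(p, "bn1_var")]] <- rep(1, cs)
    state[[paste0(p, "bn2_mean")]] <- numeric(cs)
    state[[paste0(p, "bn2_var")]] <- rep(1, cs)
    if (per_stage_cbam) {
      cb <- cbam_params(cs, reduction)
      for (nm in names(cb)) params[[paste0(p, "cbam_", nm)]] <- cb[[nm]]
    }
    cin <- cs
  }
  pooled_len <- 2 * sum(channels)
  params$fc_w <- matrix(he(pooled_len, pooled_len), 1, pooled_len)
  params$fc_b <- 0
  if (with_coords) {
    # pooled magnitudes plus per-channel activation centroids (2C + 2C)
    params$coord_w <- matrix(he(4 * 2 * pooled_len, 2 * pooled_len),
                             4, 2 * pooled_len)
    params$coord_b <- numeric(4)
  }
  structure(list(
    params = params, state = state,
    config = list(input_size = input_size, input_channels = input_channels,
                  channels = channels, reduction = reduction,
                  per_stage_cbam = per_stage_cbam, upsample = upsample,
                  cbam_after_upsample = cbam_after_upsample,
                  with_coords = with_coords,
                  cbam_gate = cbam_gate, seed = seed)),
    class = "hc_model")
}

#' @export
print.hc_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<hc_model %dx%dx%d -> stages (%s)%s%s, %d parameters>\n",
    cfg$input_size, cfg$input_size, cfg$input_channels,
    paste(cfg$channels, collapse = ","),
    if (cfg$per_stage_cbam) " + CBAM" else "",
    if (cfg$with_coords) " + coord head" else "",
    sum(vapply(x$params, length, 0L))))
  invisible(x)
}

stage_prefix <- function(s) sprintf("s%d_", s)

# Per-channel activation centroids of a non-negative H x W x C x N map,
# in normalized [0, 1] image coordinates. Returns C x N matrices plus the
# mass used for the backward pass.
hc_centroids <- function(hc, eps = 1e-8) {
  d <- dim(hc)
  H <- d[1]; W <- d[2]
  A <- matrix(hc, nrow = H * W) # columns = (channel, image) pairs
  xn <- rep((seq_len(W) - 0.5) / W, each = H)
  yn <- rep((seq_len(H) - 0.5) / H, times = W)
  S <- colSums(A) + eps
  cx <- matrix(colSums(A * xn) / S, d[3], d[4])
  cy <- matrix(colSums(A * yn) / S, d[3], d[4])
  list(cx = cx, cy = cy, S = matrix(S, d[3], d[4]), xn = xn, yn = yn)
}

# resampling dispatch: bilinear (compiled) or nearest neighbour
resize_fwd <- function(x4, H, W, mode) {
  if (all(dim(x4)[1:2] == c(H, W))) return(x4)
  if (mode == "bilinear") return(cpp_resize_bilinear(x4, H, W))
  d <- dim(x4)
  iy <- pmin(d[1], floor((seq_len(H) - 0.5) * d[1] / H) + 1)
  ix <- pmin(d[2], floor((seq_len(W) - 0.5) * d[2] / W) + 1)
  x4[iy, ix, , , drop = FALSE]
}

resize_bwd <- function(dy4, H, W, mode) {
  if (all(dim(dy4)[1:2] == c(H, W))) return(dy4)
  if (mode == "bilinear") return(cpp_resize_bilinear_bwd(dy4, H, W))
  d <- dim(dy4)
  iy <- pmin(H, floor((seq_len(d[1]) - 0.5) * H / d[1]) + 1)
  ix <- pmin(W, floor((seq_len(d[2]) - 0.5) * W / d[2]) + 1)
  dx <- array(0, c(H, W, d[3], d[4]))
  for (oy in seq_len(d[1]))
    for (ox in seq_len(d[2]))
      dx[iy[oy], ix[ox], , ] <- dx[iy[oy], ix[ox], , ] + dy4[oy, ox, , ]
  dx
}

# gradient of the centroids w.r.t. the map: dA = (coord - c) / S per entry
hc_centroids_bwd <- function(dcx, dcy, cent, d) {
  P <- d[1] * d[2]
  fx <- as.vector(dcx / cent$S)
  fy <- as.vector(dcy / cent$S)
  dA <- outer(cent$xn, fx) - rep(as.vector(dcx * cent$cx / cent$S), each = P) +
    outer(cent$yn, fy) - rep(as.vector(dcy * cent$cy / cent$S), each = P)
  array(dA, d)
}

cbam_prm <- function(params, s) {
  p <- stage_prefix(s)
  list(ch_W0 = params[[paste0(p, "cbam_ch_W0")]],
       ch_W1 = params[[paste0(p, "cbam_ch_W1")]],
       sp_w = params[[paste0(p, "cbam_sp_w")]],
       sp_b = params[[paste0(p, "cbam_sp_b")]])
}

# Full forward pass. x4: H x W x C x N in [0, 1]. Returns output, cache and
# (in train mode) updated BN running statistics.
hc_forward <- function(model, x4, train = FALSE) {
  cfg <- model$config
  if (is.null(cfg$upsample)) cfg$upsample <- "bilinear"
  prm <- model$params
  st <- model$state
  if (length(dim(x4)) == 3) x4 <- array(x4, c(dim(x4), 1))
  if (dim(x4)[3] != cfg$input_channels)
    stop("input has ", dim(x4)[3], " channels, model expects ",
         cfg$input_channels)
  S <- length(cfg$channels)
  stages <- vector("list", S)
  taps <- vector("list", S)
  xin <- x4
  for (s in seq_len(S)) {
    p <- stage_prefix(s)
    a <- cpp_conv2d_fwd(xin, prm[[paste0(p, "conv1_w")]],
                        prm[[paste0(p, "conv1_b")]], 2L, 1L)
    bn1 <- bn_forward(a, prm[[paste0(p, "bn1_g")]], prm[[paste0(p, "bn1_b")]],
                      st[[paste0(p, "bn1_mean")]], st[[paste0(p, "bn1_var")]],
                      train = train)
    st[[paste0(p, "bn1_mean")]] <- bn1$run_mean
    st[[paste0(p, "bn1_var")]] <- bn1$run_var
    r1 <- pmax(bn1$y, 0)
    b <- cpp_conv2d_fwd(r1, prm[[paste0(p, "conv2_w")]],
                        prm[[paste0(p, "conv2_b")]], 1L, 1L)
    bn2 <- bn_forward(b, prm[[paste0(p, "bn2_g")]], prm[[paste0(p, "bn2_b")]],
                      st[[paste0(p, "bn2_mean")]], st[[paste0(p, "bn2_var")]],
                      train = train)
    st[[paste0(p, "bn2_mean")]] <- bn2$run_mean
    st[[paste0(p, "bn2_var")]] <- bn2$run_var
    tap <- pmax(bn2$y, 0)
    stages[[s]] <- list(xin = xin, bn1 = bn1$cache, r1 = r1, bn2 = bn2$cache,
                        tap = tap)
    taps[[s]] <- tap
    xin <- tap
  }
  target <- dim(taps[[1]])[1:2]
  gate_on <- cfg$per_stage_cbam && cfg$cbam_gate == "learned"
  after <- isTRUE(cfg$cbam_after_upsample)
  cbam_caches <- vector("list", S)
  resized <- vector("list", S)
  for (s in seq_len(S)) {
    g <- taps[[s]]
    if (after) g <- resize_fwd(g, target[1], target[2], cfg$upsample)
    if (gate_on) {
      cf <- cbam_forward(g, cbam_prm(prm, s))
      cbam_caches[[s]] <- cf$cache
      g <- cf$out
    }
    if (!after) g <- resize_fwd(g, target[1], target[2], cfg$upsample)
    resized[[s]] <- g
  }
  N <- dim(x4)[4]
  hc <- array(0, c(target[1], target[2], sum(cfg$channels), N))
  off <- 0
  for (s in seq_len(S)) {
    cs <- cfg$channels[s]
    hc[, , off + seq_len(cs), ] <- resized[[s]]
    off <- off + cs
  }
  pool <- cpp_pool_spatial(hc)
  pooled <- rbind(pool$avg, pool$max) # 2C x N
  logit <- as.vector(prm$fc_w %*% pooled) + prm$fc_b
  prob <- sigmoid(logit)
  coords_raw <- NULL
  cent <- NULL
  if (cfg$with_coords) {
    # per-channel activation centroids: location information that global
    # pooling removes (the hypercolumn is non-negative downstream of ReLU)
    cent <- hc_centroids(hc)
    coords_raw <- sigmoid(prm$coord_w %*% rbind(pooled, cent$cx, cent$cy) +
                            prm$coord_b) # 4 x N
  }
  list(prob = prob, logit = logit, coords_raw = coords_raw,
       state = st,
       cache = list(x = x4, stages = stages, taps = taps,
                    cbam_caches = cbam_caches,
                    resized = resized, hc = hc, pool = pool,
                    pooled = pooled, prob = prob, coords_raw = coords_raw,
                    cent = cent, target = target))
}

# Backward pass from head gradients. dlogit: length-N vector of dL/dlogit;
# dcoords_raw: 4 x N matrix of dL/d(sigmoid coords) or NULL. Returns
# parameter gradients, input gradient, and the gradients at the hypercolumn
# and every stage tap (used by Grad-CAM).
hc_backward <- function(model, cache, dlogit, dcoords_raw = NULL) {
  cfg <- model$config
  prm <- model$params
  S <- length(cfg$channels)
  H <- cache$target[1]; W <- cache$target[2]
  N <- length(dlogit)
  Call <- sum(cfg$channels)
  grads <- list()

  dlogit <- matrix(dlogit, 1, N)
  grads$fc_w <- dlogit %*% t(cache$pooled)
  grads$fc_b <- sum(dlogit)
  dpooled <- t(prm$fc_w) %*% dlogit
  dhc_cent <- NULL
  if (!is.null(dcoords_raw)) {
    cr <- cache$coords_raw
    dzc <- dcoords_raw * cr * (1 - cr)
    feats <- rbind(cache$pooled, cache$cent$cx, cache$cent$cy)
    grads$coord_w <- dzc %*% t(feats)
    grads$coord_b <- rowSums(dzc)
    dfeats <- t(prm$coord_w) %*% dzc
    dpooled <- dpooled + dfeats[seq_len(2 * Call), , drop = FALSE]
    dhc_cent <- hc_centroids_bwd(
      dfeats[2 * Call + seq_len(Call), , drop = FALSE],
      dfeats[3 * Call + seq_len(Call), , drop = FALSE],
      cache$cent, dim(cache$hc))
  } else if (cfg$with_coords) {
    grads$coord_w <- matrix(0, 4, 4 * Call)
    grads$coord_b <- numeric(4)
  }

  davg <- dpooled[seq_len(Call), , drop = FALSE]
  dmax <- dpooled[Call + seq_len(Call), , drop = FALSE]
  dhc <- cpp_pool_spatial_bwd(davg, dmax, cache$pool$which, H, W)
  if (!is.null(dhc_cent)) dhc <- dhc + dhc_cent

  dtaps <- vector("list", S)
  gate_on <- cfg$per_stage_cbam && cfg$cbam_gate == "learned"
  after <- isTRUE(cfg$cbam_after_upsample)
  mode <- if (is.null(cfg$upsample)) "bilinear" else cfg$upsample
  dnext <- NULL # gradient flowing into the next-shallower stage's tap
  for (s in seq(S, 1)) {
    p <- stage_prefix(s)
    cs <- cfg$channels[s]
    off <- sum(cfg$channels[seq_len(s - 1)])
    dres <- dhc[, , off + seq_len(cs), , drop = FALSE]
    tdim <- dim(cache$taps[[s]])
    run_gate <- function(dz) {
      cb <- cbam_backward(dz, cache$cbam_caches[[s]], cbam_prm(prm, s))
      for (nm in names(cb$grads))
        grads[[paste0(p, "cbam_", nm)]] <<- cb$grads[[nm]]
      cb$dx
    }
    if (after) {
      if (gate_on) dres <- run_gate(dres)
      dtap <- resize_bwd(dres, tdim[1], tdim[2], mode)
    } else {
      dtap <- resize_bwd(dres, tdim[1], tdim[2], mode)
      if (gate_on) dtap <- run_gate(dtap)
    }
    if (!is.null(dnext)) dtap <- dtap + dnext
    dtaps[[s]] <- dtap

    stg <- cache$stages[[s]]
    dr2 <- dtap * (stg$tap > 0)
    bb2 <- bn_backward(dr2, stg$bn2, prm[[paste0(p, "bn2_g")]])
    grads[[paste0(p, "bn2_g")]] <- bb2$dgamma
    grads[[paste0(p, "bn2_b")]] <- bb2$dbeta
    cb2 <- cpp_conv2d_bwd(stg$r1, prm[[paste0(p, "conv2_w")]], bb2$dx, 1L, 1L)
    grads[[paste0(p, "conv2_w")]] <- cb2$dw
    grads[[paste0(p, "conv2_b")]] <- cb2$db
    dr1 <- cb2$dx * (stg$r1 > 0)
    bb1 <- bn_backward(dr1, stg$bn1, prm[[paste0(p, "bn1_g")]])
    grads[[paste0(p, "bn1_g")]] <- bb1$dgamma
    grads[[paste0(p, "bn1_b")]] <- bb1$dbeta
    cb1 <- cpp_conv2d_bwd(stg$xin, prm[[paste0(p, "conv1_w")]], bb1$dx, 2L, 1L)
    grads[[paste0(p, "conv1_w")]] <- cb1$dw
    grads[[paste0(p, "conv1_b")]] <- cb1$db
    dnext <- cb1$dx
  }
  list(grads = grads, dx = dnext, dhc = dhc, dtaps = dtaps)
}

# Forward in chunks, keeping probabilities (and coordinate outputs) only.
# Bounds peak memory: the full forward cache for a large batch dwarfs the
# outputs.
hc_predict_chunked <- function(model, x4, chunk = 32L) {
  if (length(dim(x4)) == 3) x4 <- array(x4, c(dim(x4), 1))
  N <- dim(x4)[4]
  prob <- numeric(N)
  coords <- if (model$config$with_coords) matrix(0, 4, N) else NULL
  for (s in seq(1, N, by = chunk)) {
    idx <- s:min(s + chunk - 1, N)
    fw <- hc_forward(model, x4[, , , idx, drop = FALSE], train = FALSE)
    prob[idx] <- fw$prob
    if (!is.null(coords)) coords[, idx] <- fw$coords_raw
  }
  list(prob = prob, coords_raw = coords)
}

#' Extract the backbone's per-resolution feature maps
#'
#' One feature map per spatial-resolution drop, in order of decreasing
#' resolution, before attention gating.
#'
#' @param model an [hc_model()].
#' @param x input array `H x W x C` (or `H x W x C x N`), values in `[0, 1]`.
#' @return list of feature-map arrays `h x w x c x N`.
#' @export
extract_stage_features <- function(model, x) {
  fw <- hc_forward(model, x, train = FALSE)
  fw$cache$taps
}

#' Stack per-stage feature maps into a hypercolumn
#'
#' Each tap is gated by its CBAM bank (when the model carries one), resampled
#' bilinearly to the first tap's resolution, and concatenated along channels,
#' so the output channel count is the sum of the stage channel counts.
#'
#' @param model an [hc_model()].
#' @param x input array (see [extract_stage_features()]).
#' @return hypercolumn array `H x W x sum(channels) x N`.
#' @export
build_hypercolumn <- function(model, x) {
  fw <- hc_forward(model, x, train = FALSE)
  fw$cache$hc
}

#' Classify from model input
#'
#' @param model an [hc_model()].
#' @param x input array `H x W x C` or batch `H x W x C x N`, in `[0, 1]`.
#' @return list with `prob` (vector of fracture probabilities), and when the
#'   model has a coordinate head, `boxes_norm`: a 4 x N matrix of normalized
#'   `x_min, y_min, x_max, y_max` canonicalized so min <= max.
#' @export
predict_hc <- function(model, x) {
  fw <- hc_predict_chunked(model, x)
  out <- list(prob = fw$prob)
  if (!is.null(fw$coords_raw)) {
    cr <- fw$coords_raw
    out$boxes_norm <- rbind(
      x_min = pmin(cr[1, ], cr[3, ]), y_min = pmin(cr[2, ], cr[4, ]),
      x_max = pmax(cr[1, ], cr[3, ]), y_max = pmax(cr[2, ], cr[4, ]))
  }
  out
}

#' Save / load a model checkpoint
#'
#' Single-file serialized parameter map with a format version tag and the
#' model configuration embedded.
#'
#' @param model an [hc_model()].
#' @param path checkpoint file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "hypercam-checkpoint-1", config = model$config,
               params = model$params, state = model$state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "hypercam-checkpoint-1"))
    stop("not a hypercam checkpoint: ", path)
  structure(list(params = ck$params, state = ck$state, config = ck$config),
            class = "hc_model")
}
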