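#' Grad-CAM heatmap for a model input
#'
#' Computes the gradient of the pre-sigmoid class score with respect to the
#' activations of the target layer, weights each channel by the spatial mean
#' of its gradient, sums the weighted channels, rectifies (negative evidence
#' is dropped unless `signed = TRUE`), upsamples to the input size, and
#' min--max normalizes to integers 0--255. A spatially flat raw surface
#' normalizes to all zeros and is flagged degenerate rather than erroring:
#' non-fracture images can legitimately produce flat maps.
#'
#' @param model an [hc_model()].
#' @param x one model input, array `H x W x C` in `[0, 1]`.
#' @param target_layer `"hypercolumn"` (the stacked attention-gated map,
#'   default) or `"stage<k>"` for the k-th backbone tap.
#' @param signed keep negative evidence instead of rectifying.
#' @return list of class `heatmap`: `values` (integer `H x W` matrix in
#'   0--255), `raw` (pre-normalization surface at input size), `degenerate`
#'   flag, and `source_layer`.
#' @export
grad_cam <- function(model, x, target_layer = "hypercolumn", signed = FALSE) {
  if (length(dim(x)) == 3) x <- array(x, c(dim(x), 1))
  if (dim(x)[4] != 1) stop("grad_cam expects a single image")
  fw <- hc_forward(model, x, train = FALSE)
  bw <- hc_backward(model, fw$cache, dlogit = 1)
  if (identical(target_layer, "hypercolumn")) {
    A <- fw$cache$hc
    G <- bw$dhc
  } else if (grepl("^stage[0-9]+$", target_layer)) {
    s <- as.integer(sub("stage", "", target_layer))
    if (s < 1 || s > length(fw$cache$taps))
      stop("no such layer: ", target_layer)
    A <- fw$cache$taps[[s]]
    G <- bw$dtaps[[s]]
  } else {
    stop("unknown target_layer: ", target_layer)
  }
  d <- dim(A)
  Amat <- matrix(A, nrow = d[1] * d[2])       # pixels x channels
  alpha <- colMeans(matrix(G, nrow = d[1] * d[2]))
  raw <- matrix(Amat %*% alpha, d[1], d[2])
  if (!signed) raw <- pmax(raw, 0)
  H <- dim(x)[1]; W <- dim(x)[2]
  if (any(dim(raw) != c(H, W)))
    raw <- matrix(cpp_resize_bilinear(array(raw, c(dim(raw), 1)), H, W), H, W)
  rng <- range(raw)
  degenerate <- diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))
  values <- if (degenerate) matrix(0L, H, W) else
    matrix(as.integer(round(255 * (raw - rng[1]) / diff(rng))), H, W)
  structure(list(values = values, raw = raw, degenerate = degenerate,
                 source_layer = target_layer),
            class = "heatmap")
}

#' Threshold a heatmap into predicted fracture boxes
#'
#' Binarizes the map above `threshold`, labels 8-connected components, and
#' returns the tight bounding box of every component with at least
#' `min_area` pixels, ordered by component peak value descending. The first
#' row is the primary fracture prediction; an empty table means no
#' prediction.
#'
#' @param h a `heatmap` from [grad_cam()], or an integer matrix in 0--255.
#' @param threshold activation cut in 0--255 (default 230).
#' @param min_area minimum component area in pixels (default 4).
#' @return box data frame (0-based half-open pixel coordinates) with an
#'   extra `peak` column.
#' @export
heatmap_to_boxes <- function(h, threshold = 230, min_area = 4) {
  values <- if (inherits(h, "heatmap")) h$values else h
  if (threshold < 0 || threshold > 255) stop("threshold must be in [0, 255]")
  mask <- values > threshold
  out <- cbind(empty_boxes(), peak = numeric(0))
  if (!any(mask)) return(out)
  lab <- cpp_label8(mask)
  ids <- seq_len(max(lab))
  rows <- lapply(ids, function(k) {
    ii <- which(lab == k, arr.ind = TRUE)
    if (nrow(ii) < min_area) return(NULL)
    data.frame(x_min = min(ii[, 2]) - 1, y_min = min(ii[, 1]) - 1,
               x_max = max(ii[, 2]), y_max = max(ii[, 1]),
               peak = max(values[ii]))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  res[order(res$peak, decreasing = TRUE), , drop = FALSE]
}

#' Overlay a heatmap on a grayscale image with the jet colormap
#'
#' @param pixels grayscale matrix in 0--255.
#' @param h a `heatmap` or integer matrix in 0--255, same size.
#' @param alpha blend weight of the colormap (0 = original image).
#' @return RGB array `H x W x 3` in 0--255.
#' @export
overlay_heatmap <- function(pixels, h, alpha = 0.4) {
  values <- if (inherits(h, "heatmap")) h$values else h
  if (!all(dim(pixels) == dim(values)))
    stop("image and heatmap sizes differ")
  lut <- jet_colors()
  idx <- as.integer(values) + 1L
  H <- nrow(pixels); W <- ncol(pixels)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * pixels + alpha * matrix(lut[idx, ch], H, W)
  out
}

# MATLAB-style jet lookup table, 256 levels, 0-255 per channel.
jet_colors <- function() {
  ramp <- grDevices::colorRamp(c("#00007F", "blue", "#007FFF", "cyan",
                                 "#7FFF7F", "yellow", "#FF7F00", "red",
                                 "#7F0000"))
  ramp(seq(0, 1, length.out = 256))
}
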