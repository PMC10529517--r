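#' Preprocessing and augmentation configuration
#'
#' Radiographs are sharpened with contrast-limited adaptive histogram
#' equalization (CLAHE) at four clip limits and stacked with the untouched
#' image into a five-channel input. The strongest CLAHE rendition also
#' drives Otsu's threshold to separate bone from background before the bone
#' is rescaled to fill the frame. Augmentation draws a rotation uniformly
#' from a symmetric interval and applies horizontal flips and gray-level
#' inversion independently; mix-up interpolates image/label pairs with a
#' Beta-distributed weight.
#'
#' @param clip_limits exactly four CLAHE clip limits, ascending, each at
#'   least 1 (the histogram-redistribution step is unstable below the
#'   average bin count).
#' @param tile_grid CLAHE tile grid `(rows, cols)`.
#' @param rotation_range rotation interval in degrees, symmetric about 0.
#' @param hflip_prob,invert_prob augmentation probabilities.
#' @param mixup_alpha Beta shape for mix-up (default 0.01; draws are nearly
#'   all close to 0 or 1, so mixed samples stay close to one parent).
#' @return a validated `preprocess_config` list.
#' @export
preprocess_config <- function(clip_limits = c(1, 2, 3, 4),
                              tile_grid = c(8, 8),
                              rotation_range = c(-30, 30),
                              hflip_prob = 0.5,
                              invert_prob = 0.5,
                              mixup_alpha = 0.01) {
  if (length(clip_limits) != 4 || any(clip_limits < 1))
    stop("clip_limits must be exactly 4 values >= 1")
  if (is.unsorted(clip_limits))
    stop("clip_limits must be ascending")
  if (length(rotation_range) != 2 ||
      abs(rotation_range[1] + rotation_range[2]) > 1e-9)
    stop("rotation_range must be symmetric about 0")
  stopifnot(length(tile_grid) == 2, all(tile_grid >= 1),
            hflip_prob >= 0, hflip_prob <= 1,
            invert_prob >= 0, invert_prob <= 1, mixup_alpha > 0)
  structure(list(clip_limits = clip_limits, tile_grid = as.integer(tile_grid),
                 rotation_range = rotation_range, hflip_prob = hflip_prob,
                 invert_prob = invert_prob, mixup_alpha = mixup_alpha),
            class = "preprocess_config")
}

#' Stack an image with its CLAHE renditions into five channels
#'
#' Channel 1 is the untouched input; channels 2--5 are CLAHE outputs at the
#' four clip limits in ascending order. Spatial size is unchanged.
#'
#' @param pixels single-channel numeric matrix in gray-levels 0--255.
#' @param config a [preprocess_config()].
#' @return array `H x W x 5` in gray-levels 0--255.
#' @export
clahe_stack <- function(pixels, config = preprocess_config()) {
  if (!is.matrix(pixels))
    stop("clahe_stack expects a single-channel image matrix")
  H <- nrow(pixels); W <- ncol(pixels)
  out <- array(0, c(H, W, 5))
  out[, , 1] <- pixels
  for (k in seq_along(config$clip_limits))
    out[, , k + 1] <- clahe_channel(pixels, config$clip_limits[k],
                                    config$tile_grid)
  out
}

clahe_channel <- function(pixels, limit, tile_grid) {
  img <- EBImage::Image(t(pixels) / 255)
  enh <- EBImage::clahe(img, nx = tile_grid[2], ny = tile_grid[1],
                        limit = limit)
  clamp(t(EBImage::imageData(enh)) * 255, 0, 255)
}

#' A crop-and-rescale transform
#'
#' Records the offset and scale mapping original pixel coordinates into the
#' cropped, rescaled frame, so ground-truth boxes survive the bone crop.
#'
#' @param offset numeric `(x, y)` crop origin in source pixels.
#' @param scale numeric `(sx, sy)` rescale factors (> 0).
#' @return a `crop_transform` list.
#' @export
crop_transform <- function(offset = c(0, 0), scale = c(1, 1)) {
  if (any(scale <= 0)) stop("scale components must be > 0")
  structure(list(offset = offset, scale = scale), class = "crop_transform")
}

#' Remap boxes through a crop transform (or its inverse)
#'
#' @param boxes box data frame in source pixel coordinates.
#' @param tf a [crop_transform()].
#' @param width,height destination frame size; when finite, boxes are
#'   clipped to the frame and boxes that collapse are dropped. With the
#'   default infinite bounds the mapping is the pure (invertible) affine.
#' @return remapped box data frame.
#' @export
apply_crop_transform <- function(boxes, tf, width = Inf, height = Inf) {
  if (!nrow(boxes)) return(boxes)
  b <- data.frame(
    x_min = (boxes$x_min - tf$offset[1]) * tf$scale[1],
    y_min = (boxes$y_min - tf$offset[2]) * tf$scale[2],
    x_max = (boxes$x_max - tf$offset[1]) * tf$scale[1],
    y_max = (boxes$y_max - tf$offset[2]) * tf$scale[2])
  if (is.finite(width) || is.finite(height)) {
    b$x_min <- clamp(b$x_min, 0, width)
    b$x_max <- clamp(b$x_max, 0, width)
    b$y_min <- clamp(b$y_min, 0, height)
    b$y_max <- clamp(b$y_max, 0, height)
    b <- b[b$x_min < b$x_max & b$y_min < b$y_max, , drop = FALSE]
  }
  b
}

#' @rdname apply_crop_transform
#' @export
invert_crop_transform <- function(tf) {
  crop_transform(offset = -tf$offset * tf$scale, scale = 1 / tf$scale)
}

#' Crop the bone foreground by Otsu's threshold and rescale to fill the frame
#'
#' The strongest CLAHE rendition drives Otsu's threshold; the largest
#' 8-connected above-threshold component defines the foreground, whose
#' bounding rectangle is cropped and rescaled to `frame` pixels. Boxes are
#' remapped through the returned transform.
#'
#' @param record an [image_record()].
#' @param config a [preprocess_config()].
#' @param frame output square side (default: the input's height).
#' @return list with `record` (cropped, rescaled) and `transform`
#'   (a [crop_transform()]).
#' @export
otsu_crop <- function(record, config = preprocess_config(), frame = NULL) {
  px <- record$pixels
  if (stats::var(as.vector(px)) == 0)
    stop("no foreground: image has zero intensity variance")
  if (is.null(frame)) frame <- nrow(px)
  enh <- clahe_channel(px, max(config$clip_limits), config$tile_grid)
  th <- EBImage::otsu(EBImage::Image(t(enh) / 255))
  mask <- enh / 255 > th
  if (!any(mask)) stop("no foreground above the Otsu threshold")
  lab <- cpp_label8(mask)
  counts <- tabulate(lab[lab > 0])
  keep <- lab == which.max(counts)
  ii <- which(keep, arr.ind = TRUE)
  # 0-based half-open crop rectangle
  x0 <- min(ii[, 2]) - 1; x1 <- max(ii[, 2])
  y0 <- min(ii[, 1]) - 1; y1 <- max(ii[, 1])
  cropped <- px[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
  sx <- frame / (x1 - x0)
  sy <- frame / (y1 - y0)
  resized <- array(cpp_resize_bilinear(array(cropped, c(dim(cropped), 1)),
                                       frame, frame), c(frame, frame))
  tf <- crop_transform(offset = c(x0, y0), scale = c(sx, sy))
  boxes <- apply_crop_transform(record$boxes, tf, frame, frame)
  out <- image_record(resized, record$label, boxes,
                      meta = c(record$meta, list(otsu_threshold = th * 255)))
  list(record = out, transform = tf)
}

# Core geometric augmentation on an H x W x C array plus boxes.
# `invert_max` is the gray-level ceiling used for inversion.
augment_tensor <- function(x, boxes, angle = 0, flip = FALSE, invert = FALSE,
                           invert_max = 255) {
  d <- dim(x)
  H <- d[1]; W <- d[2]
  if (angle != 0) {
    x <- cpp_rotate(x, angle, bg = min(x))
    if (nrow(boxes)) {
      th <- angle * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      cen <- c(W / 2, H / 2)
      newb <- lapply(seq_len(nrow(boxes)), function(i) {
        b <- boxes[i, ]
        corners <- rbind(c(b$x_min, b$y_min), c(b$x_max, b$y_min),
                         c(b$x_min, b$y_max), c(b$x_max, b$y_max))
        rot <- t(R %*% (t(corners) - cen) + cen)
        c(min(rot[, 1]), min(rot[, 2]), max(rot[, 1]), max(rot[, 2]))
      })
      newb <- do.call(rbind, newb)
      boxes <- data.frame(x_min = newb[, 1], y_min = newb[, 2],
                          x_max = newb[, 3], y_max = newb[, 4])
      boxes$x_min <- clamp(boxes$x_min, 0, W)
      boxes$x_max <- clamp(boxes$x_max, 0, W)
      boxes$y_min <- clamp(boxes$y_min, 0, H)
      boxes$y_max <- clamp(boxes$y_max, 0, H)
      boxes <- boxes[boxes$x_min < boxes$x_max & boxes$y_min < boxes$y_max, ,
                     drop = FALSE]
    }
  }
  if (flip) {
    x <- x[, W:1, , drop = FALSE]
    if (nrow(boxes)) {
      xm <- boxes$x_min
      boxes$x_min <- W - boxes$x_max
      boxes$x_max <- W - xm
    }
  }
  if (invert) x <- invert_max - x
  list(x = x, boxes = boxes)
}

#' Randomly augment an image record
#'
#' Rotation angle drawn uniformly from the configured interval; horizontal
#' flip and gray-level inversion applied independently with their
#' configured probabilities. Boxes are transformed consistently with the
#' geometric operations; the label never changes. Rotation fills exposed
#' corners with the image minimum so no bright artifact is introduced.
#'
#' @param record an [image_record()].
#' @param config a [preprocess_config()].
#' @return augmented [image_record()]; `meta$augment` records the draws.
#' @export
augment_record <- function(record, config = preprocess_config()) {
  angle <- runif(1, config$rotation_range[1], config$rotation_range[2])
  flip <- runif(1) < config$hflip_prob
  invert <- runif(1) < config$invert_prob
  d <- dim(record$pixels)
  a <- augment_tensor(array(record$pixels, c(d, 1)), record$boxes,
                      angle = angle, flip = flip, invert = invert,
                      invert_max = 255)
  image_record(array(a$x, d), record$label, a$boxes,
               meta = c(record$meta,
                        list(augment = list(angle = angle, flip = flip,
                                            invert = invert))))
}

#' Mix-up augmentation of two batches
#'
#' Draws one mixing weight per pair from `Beta(alpha, alpha)` and forms the
#' convex combination of both pixels and labels. Output labels equal
#' `lambda * y_a + (1 - lambda) * y_b` exactly.
#'
#' @param xa,xb image batches of identical shape, samples along the last
#'   dimension.
#' @param ya,yb numeric label vectors in `[0, 1]`.
#' @param alpha Beta shape parameter (> 0).
#' @param lambda optional fixed mixing weights (recycled), bypassing the
#'   Beta draw.
#' @return list with `x`, `y`, and the `lambda` used.
#' @export
mixup_batch <- function(xa, ya, xb, yb, alpha = 0.01, lambda = NULL) {
  if (!identical(dim(xa), dim(xb)) || length(ya) != length(yb))
    stop("mixup_batch: batch shapes must match")
  if (alpha <= 0) stop("alpha must be > 0")
  n <- length(ya)
  lam <- if (is.null(lambda)) rbeta(n, alpha, alpha) else rep(lambda,
                                                              length.out = n)
  per <- prod(dim(xa)) / n
  lam_arr <- array(rep(lam, each = per), dim(xa))
  list(x = xa * lam_arr + xb * (1 - lam_arr),
       y = lam * ya + (1 - lam) * yb,
       lambda = lam)
}

#' Prepare image records as model input tensors
#'
#' Runs the standard pipeline -- Otsu bone crop, CLAHE five-channel stack,
#' scaling to `[0, 1]` -- over a list of records.
#'
#' @param records list of [image_record()].
#' @param config a [preprocess_config()].
#' @param frame output frame side in pixels (default: first record's height).
#' @param crop apply the Otsu bone crop (default TRUE).
#' @return list with `x` (array `frame x frame x 5 x N` in `[0, 1]`), `y`
#'   (labels), `boxes` (list of remapped box tables), `transforms`.
#' @export
prepare_dataset <- function(records, config = preprocess_config(),
                            frame = NULL, crop = TRUE) {
  stopifnot(length(records) >= 1)
  if (is.null(frame)) frame <- nrow(records[[1]]$pixels)
  N <- length(records)
  x <- array(0, c(frame, frame, 5, N))
  y <- numeric(N)
  boxes <- vector("list", N)
  transforms <- vector("list", N)
  for (i in seq_len(N)) {
    rec <- records[[i]]
    if (crop) {
      oc <- otsu_crop(rec, config, frame = frame)
      rec <- oc$record
      transforms[[i]] <- oc$transform
    } else if (nrow(rec$pixels) != frame || ncol(rec$pixels) != frame) {
      tf <- crop_transform(scale = c(frame / ncol(rec$pixels),
                                     frame / nrow(rec$pixels)))
      rec <- image_record(
        array(cpp_resize_bilinear(array(rec$pixels, c(dim(rec$pixels), 1)),
                                  frame, frame), c(frame, frame)),
        rec$label, apply_crop_transform(rec$boxes, tf, frame, frame),
        rec$meta)
      transforms[[i]] <- tf
    } else {
      transforms[[i]] <- crop_transform()
    }
    x[, , , i] <- clahe_stack(rec$pixels, config) / 255
    y[i] <- rec$label
    boxes[[i]] <- rec$boxes
  }
  list(x = x, y = y, boxes = boxes, transforms = transforms, frame = frame)
}
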