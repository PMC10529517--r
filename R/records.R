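#' Construct an image record
#'
#' The unit of data in this package: one radiograph with its binary fracture
#' label, any ground-truth fracture boxes, and a provenance list recording
#' the transforms the image has been through.
#'
#' Pixels are stored as a numeric `H x W` matrix (rows = image y, columns =
#' image x) in gray-levels, 0--255 for 8-bit input. Boxes use 0-based pixel
#' coordinates, half-open on the max side: a box covering the single pixel
#' `(0, 0)` is `x_min = 0, x_max = 1, y_min = 0, y_max = 1`.
#'
#' @param pixels numeric matrix of gray-levels.
#' @param label 0 (non-fracture) or 1 (fracture).
#' @param boxes data frame with columns `x_min`, `y_min`, `x_max`, `y_max`
#'   (possibly zero rows).
#' @param meta named list of provenance information.
#' @return An object of class `xray_record`.
#' @export
image_record <- function(pixels, label, boxes = empty_boxes(), meta = list()) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  boxes <- validate_boxes(boxes, ncol(pixels), nrow(pixels))
  structure(list(pixels = pixels, label = as.integer(label),
                 boxes = boxes, meta = meta),
            class = "xray_record")
}

#' @export
print.xray_record <- function(x, ...) {
  cat(sprintf("<xray_record %dx%d label=%d boxes=%d>\n",
              nrow(x$pixels), ncol(x$pixels), x$label, nrow(x$boxes)))
  invisible(x)
}

#' An empty box table
#' @return Zero-row data frame with the box columns.
#' @export
empty_boxes <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0),
             x_max = numeric(0), y_max = numeric(0))
}

#' Construct a box table
#'
#' @param x_min,y_min,x_max,y_max vectors of 0-based pixel coordinates,
#'   half-open on the max side.
#' @return Data frame with one row per box.
#' @export
boxes_df <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (nrow(b) && any(b$x_min >= b$x_max | b$y_min >= b$y_max))
    stop("degenerate box: need x_min < x_max and y_min < y_max")
  b
}

validate_boxes <- function(boxes, width = Inf, height = Inf) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  if (!is.data.frame(boxes) || !all(need %in% names(boxes)))
    stop("boxes must be a data frame with columns x_min, y_min, x_max, y_max")
  boxes <- boxes[, need, drop = FALSE]
  if (nrow(boxes)) {
    if (any(boxes$x_min >= boxes$x_max | boxes$y_min >= boxes$y_max))
      stop("degenerate box: need x_min < x_max and y_min < y_max")
    if (any(boxes$x_min < 0 | boxes$y_min < 0 |
            boxes$x_max > width | boxes$y_max > height))
      stop("box outside image bounds")
  }
  boxes
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(z) 1 / (1 + exp(-z))

relu <- function(z) pmax(z, 0)
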