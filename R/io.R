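# Dataset interchange: PNG images, CSV manifests, YOLO-style box sidecars.
# One coordinate convention everywhere: 0-based pixel indices, boxes
# half-open on the max side.

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param pixels numeric matrix in gray-levels 0--255 (rows = y).
#' @param path output file.
#' @export
write_gray_png <- function(pixels, path) {
  img <- EBImage::Image(t(pixels) / 255)
  EBImage::writeImage(img, path, type = "png", bits.per.sample = 8)
  invisible(path)
}

#' Read a grayscale PNG/JPEG into a gray-level matrix
#'
#' Multi-channel files are averaged to one channel; values are rescaled to
#' 0--255 regardless of source bit depth.
#'
#' @param path image file.
#' @return numeric matrix (rows = y) in 0--255.
#' @export
read_gray_png <- function(path) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3) img <- EBImage::Image(apply(img, c(1, 2), mean))
  t(EBImage::imageData(img)) * 255
}

#' Write a dataset manifest
#'
#' @param manifest data frame with columns `path` and `label` (and
#'   optionally `boxes`).
#' @param path output CSV.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(all(c("path", "label") %in% names(manifest)))
  write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a dataset manifest
#'
#' Expects a CSV with header `path,label` (an optional third column `boxes`
#' names per-image sidecar files). Labels must be 0 or 1. Positives without
#' a box sidecar are allowed (image-level supervision only) and flagged in
#' the returned attribute `missing_boxes`.
#'
#' @param path manifest CSV.
#' @param check_paths verify that the image files exist (default TRUE).
#' @return data frame with `path`, `label`, `boxes` (NA when absent).
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have header path,label")
  bad <- which(!(m$label %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("manifest line %d: label must be 0 or 1 (got %s)",
                 bad[1] + 1L, m$label[bad[1]]))
  if (!"boxes" %in% names(m)) {
    root <- dirname(path)
    cand <- file.path(root, sub("\\.(png|jpg|jpeg)$", ".txt", m$path,
                                ignore.case = TRUE))
    m$boxes <- ifelse(file.exists(cand), sub("\\.(png|jpg|jpeg)$", ".txt",
                                             m$path, ignore.case = TRUE),
                      NA_character_)
  }
  if (check_paths) {
    full <- file.path(dirname(path), m$path)
    miss <- !file.exists(full)
    if (any(miss)) stop("missing image file(s): ",
                        paste(head(m$path[miss], 3), collapse = ", "))
  }
  attr(m, "missing_boxes") <- which(m$label == 1 & is.na(m$boxes))
  m
}

#' Write boxes as normalized YOLO-style lines
#'
#' Each line is `0 cx cy w h` with centre/size normalized to `[0, 1]` by the
#' image width and height.
#'
#' @param boxes box data frame in pixel coordinates.
#' @param path output text file.
#' @param width,height image size in pixels.
#' @export
write_boxes_file <- function(boxes, path, width, height) {
  lines <- character(0)
  if (nrow(boxes)) {
    cx <- (boxes$x_min + boxes$x_max) / 2 / width
    cy <- (boxes$y_min + boxes$y_max) / 2 / height
    w <- (boxes$x_max - boxes$x_min) / width
    h <- (boxes$y_max - boxes$y_min) / height
    lines <- sprintf("0 %.6f %.6f %.6f %.6f", cx, cy, w, h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a YOLO-style box sidecar into pixel-space boxes
#'
#' @param path text file of lines `cls cx cy w h`, coordinates normalized to
#'   `[0, 1]`.
#' @param width,height image size in pixels used to denormalize.
#' @param classes integer class IDs to keep (default 0, the fracture class).
#' @return box data frame in 0-based half-open pixel coordinates.
#' @export
read_boxes_file <- function(path, width, height, classes = 0L) {
  if (!file.exists(path)) stop("box file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty_boxes())
  vals <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) != 5 || anyNA(v))
      stop(sprintf("%s line %d: expected 'cls cx cy w h'", path, i))
    if (any(v[2:5] < 0) || any(v[2:5] > 1))
      stop(sprintf("%s line %d: normalized values outside [0, 1]", path, i))
    v
  })
  vals <- do.call(rbind, vals)
  vals <- vals[vals[, 1] %in% classes, , drop = FALSE]
  if (!nrow(vals)) return(empty_boxes())
  boxes_df(x_min = clamp((vals[, 2] - vals[, 4] / 2) * width, 0, width),
           y_min = clamp((vals[, 3] - vals[, 5] / 2) * height, 0, height),
           x_max = clamp((vals[, 2] + vals[, 4] / 2) * width, 0, width),
           y_max = clamp((vals[, 3] + vals[, 5] / 2) * height, 0, height))
}

#' Load a dataset directory into image records
#'
#' @param manifest_path path to a `manifest.csv` written by
#'   [generate_phantom_dataset()] or following the same layout.
#' @return list of [image_record()].
#' @export
load_dataset <- function(manifest_path) {
  m <- read_manifest(manifest_path)
  root <- dirname(manifest_path)
  lapply(seq_len(nrow(m)), function(i) {
    px <- read_gray_png(file.path(root, m$path[i]))
    boxes <- if (!is.na(m$boxes[i]))
      read_boxes_file(file.path(root, m$boxes[i]), ncol(px), nrow(px))
    else empty_boxes()
    image_record(px, m$label[i], boxes,
                 meta = list(path = m$path[i]))
  })
}
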