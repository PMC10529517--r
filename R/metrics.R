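#' Confusion counts for binary fracture predictions
#'
#' Class 1 (fracture) is the positive class.
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    stop("y_true and y_pred must have equal, nonzero length")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be 0/1")
  list(TP = sum(y_true == 1 & y_pred == 1),
       TN = sum(y_true == 0 & y_pred == 0),
       FP = sum(y_true == 0 & y_pred == 1),
       FN = sum(y_true == 1 & y_pred == 0))
}

#' Accuracy, precision, recall and F1 from confusion counts
#'
#' Zero-denominator cases (no predicted positives, no true positives, or
#' both) return 0 for the affected metric and are named in the `degenerate`
#' field rather than erroring, keeping batch evaluation total.
#'
#' @param cc counts from [confusion_counts()].
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `degenerate`
#'   (character vector of metrics whose denominator was zero).
#' @export
basic_metrics <- function(cc) {
  total <- cc$TP + cc$TN + cc$FP + cc$FN
  if (total == 0) stop("empty confusion counts")
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  precision <- safe(cc$TP, cc$TP + cc$FP, "precision")
  recall <- safe(cc$TP, cc$TP + cc$FN, "recall")
  f1 <- safe(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN, "f1")
  list(accuracy = (cc$TP + cc$TN) / total, precision = precision,
       recall = recall, f1 = f1, degenerate = degenerate)
}

#' Cohen's kappa for binary raters
#'
#' Chance-corrected agreement: `kappa = (P0 - PC) / (1 - PC)` where `P0` is
#' the observed agreement proportion and `PC` the agreement expected from
#' the two raters' marginals.
#'
#' @param y_true,y_pred equal-length binary vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || !length(y_true))
    stop("y_true and y_pred must have equal, nonzero length")
  n <- length(y_true)
  p0 <- mean(y_true == y_pred)
  pc <- sum(vapply(c(0, 1), function(k)
    mean(y_true == k) * mean(y_pred == k), 0))
  if (abs(1 - pc) < 1e-12)
    stop("kappa undefined: both raters constant and identical")
  (p0 - pc) / (1 - pc)
}

#' Intersection over union of two boxes
#'
#' @param a,b boxes: one-row data frames or named vectors with `x_min`,
#'   `y_min`, `x_max`, `y_max` (half-open).
#' @return IoU in `[0, 1]`; 0 when disjoint.
#' @export
box_iou <- function(a, b) {
  a <- as.list(a); b <- as.list(b)
  area <- function(z) (z$x_max - z$x_min) * (z$y_max - z$y_min)
  if (area(a) <= 0 || area(b) <= 0) stop("degenerate (zero-area) box")
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  inter <- max(iw, 0) * max(ih, 0)
  inter / (area(a) + area(b) - inter)
}

#' Per-image IoU of the primary prediction against the best truth box
#'
#' Images may carry several ground-truth fracture boxes; the primary
#' (first) predicted box is scored against its best-overlapping truth box.
#' No prediction scores 0.
#'
#' @param predicted box data frame ordered by confidence (first = primary).
#' @param truth non-empty box data frame.
#' @return IoU in `[0, 1]`.
#' @export
match_iou <- function(predicted, truth) {
  if (!nrow(truth)) stop("truth boxes must be non-empty")
  if (!nrow(predicted)) return(0)
  max(vapply(seq_len(nrow(truth)),
             function(j) box_iou(predicted[1, ], truth[j, ]), 0))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (ties included
#' simultaneously) and integrates the curve by the trapezoid rule.
#'
#' @param y_true binary labels (both classes must be present).
#' @param scores numeric scores, higher = more fracture-like.
#' @return list with `points` (data frame `fpr`, `tpr`, `threshold`) and
#'   `auc`.
#' @export
roc_auc <- function(y_true, scores) {
  if (length(y_true) != length(scores)) stop("length mismatch")
  np <- sum(y_true == 1)
  nn <- sum(y_true == 0)
  if (np == 0 || nn == 0)
    stop("AUC undefined: both classes must be present")
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & y_true == 1) / np, 0)
  fpr <- vapply(th, function(t) sum(scores >= t & y_true == 0) / nn, 0)
  points <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1),
                       threshold = c(Inf, th, -Inf))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  list(points = points, auc = auc)
}

#' Assemble a metrics report
#'
#' @param y_true binary labels.
#' @param scores predicted fracture probabilities.
#' @param ious per-image IoU values over the box-annotated subset (may be
#'   empty).
#' @param prob_threshold classification cut on the probability (default 0.5).
#' @return object of class `metrics_report`: confusion counts plus
#'   `accuracy`, `precision`, `recall`, `f1`, `kappa`, `auc`, `mean_iou`,
#'   `n`, `n_boxed`.
#' @export
metrics_report <- function(y_true, scores, ious = numeric(0),
                           prob_threshold = 0.5) {
  y_pred <- as.integer(scores >= prob_threshold)
  cc <- confusion_counts(y_true, y_pred)
  bm <- basic_metrics(cc)
  kap <- tryCatch(cohens_kappa(y_true, y_pred), error = function(e) NA_real_)
  auc <- tryCatch(roc_auc(y_true, scores)$auc, error = function(e) NA_real_)
  structure(list(counts = cc, accuracy = bm$accuracy,
                 precision = bm$precision, recall = bm$recall, f1 = bm$f1,
                 kappa = kap, auc = auc,
                 mean_iou = if (length(ious)) mean(ious) else NA_real_,
                 n = length(y_true), n_boxed = length(ious),
                 degenerate = bm$degenerate),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0(
    "metrics over n=%d (boxed subset n=%d)\n",
    "  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
    "  kappa %.3f  AUC %s  mean IoU %s\n"),
    x$n, x$n_boxed, x$accuracy, x$precision, x$recall, x$f1, x$kappa,
    ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
    ifelse(is.na(x$mean_iou), "NA", sprintf("%.3f", x$mean_iou))))
  invisible(x)
}

#' Serialize a metrics report
#'
#' @param report a [metrics_report()].
#' @param path output file.
#' @param format `"json"` or `"csv"`.
#' @export
write_metrics_report <- function(report, path, format = c("json", "csv")) {
  format <- match.arg(format)
  flat <- c(report$counts,
            report[c("accuracy", "precision", "recall", "f1", "kappa",
                     "auc", "mean_iou", "n", "n_boxed")])
  if (format == "json") {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    df <- data.frame(metric = names(flat),
                     value = vapply(flat, as.numeric, 0))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a JSON metrics report
#' @param path file written by [write_metrics_report()].
#' @return named list of metric values.
#' @export
read_metrics_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
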