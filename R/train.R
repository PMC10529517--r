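#' Training configuration
#'
#' Defaults follow the reference protocol: 120 epochs, batch size 32, Lion
#' optimizer at initial learning rate 1e-4, binary weighted cross-entropy,
#' and a plateau schedule that multiplies the learning rate by 0.1 when the
#' validation loss makes no new strict minimum for 10 epochs.
#'
#' @param epochs,batch_size training length and minibatch size.
#' @param lr0 initial learning rate.
#' @param plateau_patience epochs without improvement before decay.
#' @param plateau_factor multiplicative decay factor in (0, 1).
#' @param lion_betas Lion momentum coefficients `(beta1, beta2)`.
#' @param weight_decay decoupled weight decay.
#' @param class_weights `(w_neg, w_pos)` or `"auto"` (inverse class
#'   frequency, normalized to mean 1; balanced data gives `c(1, 1)`).
#' @param coord_loss_weight weight of the Smooth L1 coordinate loss.
#' @param mixup_prob probability a batch is mixed up.
#' @param augment apply rotation/flip/inversion augmentation.
#' @param seed RNG seed covering shuffling, augmentation and mix-up.
#' @return a validated `train_config` list.
#' @export
train_config <- function(epochs = 120, batch_size = 32, lr0 = 1e-4,
                         plateau_patience = 10, plateau_factor = 0.1,
                         lion_betas = c(0.9, 0.99), weight_decay = 0,
                         class_weights = "auto", coord_loss_weight = 1.0,
                         mixup_prob = 0.5, augment = TRUE, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0, plateau_patience >= 1,
            plateau_factor > 0, plateau_factor < 1,
            length(lion_betas) == 2, all(lion_betas > 0),
            all(lion_betas < 1), weight_decay >= 0, coord_loss_weight >= 0,
            mixup_prob >= 0, mixup_prob <= 1)
  if (!identical(class_weights, "auto"))
    stopifnot(length(class_weights) == 2, all(class_weights > 0))
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_factor = plateau_factor, lion_betas = lion_betas,
                 weight_decay = weight_decay, class_weights = class_weights,
                 coord_loss_weight = coord_loss_weight,
                 mixup_prob = mixup_prob, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary weighted cross-entropy
#'
#' `-mean(w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p))`, accepting
#' soft labels from mix-up. Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p predicted probabilities.
#' @param y labels in `[0, 1]`.
#' @param weights `(w_neg, w_pos)`.
#' @return scalar loss.
#' @export
weighted_bce <- function(p, y, weights = c(1, 1)) {
  stopifnot(length(p) == length(y), all(weights > 0))
  p <- clamp(p, 1e-7, 1 - 1e-7)
  -mean(weights[2] * y * log(p) + weights[1] * (1 - y) * log(1 - p))
}

# gradient of weighted_bce w.r.t. the pre-sigmoid logit
bce_dlogit <- function(p, y, weights = c(1, 1)) {
  p <- clamp(p, 1e-7, 1 - 1e-7)
  (-weights[2] * y * (1 - p) + weights[1] * (1 - y) * p) / length(p)
}

#' Smooth L1 (Huber) loss for box coordinates
#'
#' Per coordinate: `0.5 d^2 / delta` when `|d| < delta`, else
#' `|d| - 0.5 delta`; averaged over all coordinates.
#'
#' @param pred,true numeric arrays of identical shape (normalized
#'   coordinates).
#' @param delta transition point (default 1).
#' @return scalar loss.
#' @export
smooth_l1 <- function(pred, true, delta = 1.0) {
  stopifnot(length(pred) == length(true), delta > 0)
  d <- abs(pred - true)
  mean(ifelse(d < delta, 0.5 * d^2 / delta, d - 0.5 * delta))
}

smooth_l1_grad <- function(pred, true, delta = 1.0) {
  d <- pred - true
  g <- ifelse(abs(d) < delta, d / delta, sign(d))
  g / length(d)
}

#' One Lion optimizer step
#'
#' Sign-of-interpolated-momentum update:
#' `update = sign(beta1 * m + (1 - beta1) * g)`;
#' `param <- param - lr * (update + wd * param)`;
#' `m <- beta2 * m + (1 - beta2) * g`.
#'
#' @param params named list of parameter arrays.
#' @param grads matching named list of gradients.
#' @param state momentum state (named list; missing entries start at 0).
#' @param lr learning rate.
#' @param betas `(beta1, beta2)`.
#' @param weight_decay decoupled weight decay.
#' @return list with updated `params` and `state`.
#' @export
lion_step <- function(params, grads, state = list(), lr,
                      betas = c(0.9, 0.99), weight_decay = 0) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- state[[nm]]
    if (is.null(m)) m <- g * 0
    upd <- sign(betas[1] * m + (1 - betas[1]) * g)
    params[[nm]] <- params[[nm]] - lr * (upd + weight_decay * params[[nm]])
    state[[nm]] <- betas[2] * m + (1 - betas[2]) * g
  }
  list(params = params, state = state)
}

resolve_class_weights <- function(class_weights, y) {
  if (!identical(class_weights, "auto")) return(class_weights)
  n <- length(y)
  n1 <- sum(y == 1)
  n0 <- n - n1
  w <- c(n / (2 * n0), n / (2 * n1))
  w / mean(w)
}

# normalized corner targets (4 x N) for records with boxes; NA columns else
coord_targets <- function(boxes, frame) {
  out <- matrix(NA_real_, 4, length(boxes))
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    if (!is.null(b) && nrow(b))
      out[, i] <- c(b$x_min[1], b$y_min[1], b$x_max[1], b$y_max[1]) / frame
  }
  out
}

#' Train a hypercolumn attention model
#'
#' Runs shuffled minibatch epochs with geometric augmentation and mix-up,
#' weighted binary cross-entropy (plus Smooth L1 coordinate loss on
#' box-bearing positives when the model has a coordinate head), Lion
#' updates, and plateau learning-rate decay on the validation loss.
#' Mixed-up batches contribute only the classification loss, since an
#' interpolated label has no single box. Deterministic given the config
#' seed.
#'
#' @param model an [hc_model()].
#' @param train_data,val_data lists from [prepare_dataset()].
#' @param config a [train_config()].
#' @param preprocess a [preprocess_config()] supplying augmentation ranges.
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and `history` (data frame: epoch,
#'   lr, train_loss, val_loss, val_auc).
#' @export
train_model <- function(model, train_data, val_data, config = train_config(),
                        preprocess = preprocess_config(), verbose = FALSE) {
  y <- train_data$y
  if (length(unique(y[y %in% c(0, 1)])) < 2 && length(unique(y)) < 2)
    stop("training set must contain both classes")
  set.seed(config$seed)
  weights <- resolve_class_weights(config$class_weights, y)
  n <- length(y)
  frame <- dim(train_data$x)[1]
  with_coords <- model$config$with_coords
  targets <- coord_targets(train_data$boxes, frame)

  lr <- config$lr0
  best <- Inf
  last_improve <- 0L
  opt_state <- list()
  history <- data.frame(epoch = integer(0), lr = numeric(0),
                        train_loss = numeric(0), val_loss = numeric(0),
                        val_auc = numeric(0))

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_loss <- 0
    ep_n <- 0
    for (bi in batches) {
      xb <- train_data$x[, , , bi, drop = FALSE]
      yb <- y[bi]
      tb <- targets[, bi, drop = FALSE]
      if (config$augment) {
        for (k in seq_along(bi)) {
          ang <- runif(1, preprocess$rotation_range[1],
                       preprocess$rotation_range[2])
          fl <- runif(1) < preprocess$hflip_prob
          inv <- runif(1) < preprocess$invert_prob
          bx <- train_data$boxes[[bi[k]]]
          if (is.null(bx)) bx <- empty_boxes()
          a <- augment_tensor(xb[, , , k, drop = TRUE], bx, angle = ang,
                              flip = fl, invert = inv, invert_max = 1)
          xb[, , , k] <- a$x
          tb[, k] <- if (nrow(a$boxes))
            c(a$boxes$x_min[1], a$boxes$y_min[1],
              a$boxes$x_max[1], a$boxes$y_max[1]) / frame
          else NA_real_
        }
      }
      mixed <- runif(1) < config$mixup_prob && length(bi) > 1
      if (mixed) {
        perm <- sample(length(bi))
        mx <- mixup_batch(xb, yb, xb[, , , perm, drop = FALSE], yb[perm],
                          alpha = preprocess$mixup_alpha)
        xb <- mx$x
        yb <- mx$y
      }
      fw <- hc_forward(model, xb, train = TRUE)
      model$state <- fw$state
      loss <- weighted_bce(fw$prob, yb, weights)
      dlogit <- bce_dlogit(fw$prob, yb, weights)
      dcoords <- NULL
      if (with_coords && !mixed) {
        has_box <- which(!is.na(tb[1, ]))
        if (length(has_box)) {
          pc <- fw$coords_raw[, has_box, drop = FALSE]
          tc <- tb[, has_box, drop = FALSE]
          loss <- loss + config$coord_loss_weight * smooth_l1(pc, tc)
          dcoords <- matrix(0, 4, length(bi))
          dcoords[, has_box] <- config$coord_loss_weight *
            smooth_l1_grad(pc, tc)
        }
      }
      bw <- hc_backward(model, fw$cache, dlogit, dcoords)
      step <- lion_step(model$params, bw$grads, opt_state, lr,
                        config$lion_betas, config$weight_decay)
      model$params <- step$params
      opt_state <- step$state
      ep_loss <- ep_loss + loss * length(bi)
      ep_n <- ep_n + length(bi)
    }
    val <- hc_predict_chunked(model, val_data$x, config$batch_size)
    val_loss <- weighted_bce(val$prob, val_data$y, weights)
    val_auc <- tryCatch(roc_auc(val_data$y, val$prob)$auc,
                        error = function(e) NA_real_)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / ep_n,
      val_loss = val_loss, val_auc = val_auc))
    if (verbose)
      message(sprintf("epoch %3d lr %.2g train %.4f val %.4f auc %s",
                      epoch, lr, ep_loss / ep_n, val_loss,
                      ifelse(is.na(val_auc), "NA",
                             sprintf("%.3f", val_auc))))
    # plateau schedule: the first epoch sets the baseline; the LR drops when
    # `patience` epochs pass without a new strict minimum of the val loss
    if (val_loss < best) {
      best <- val_loss
      if (epoch > 1) last_improve <- epoch
    }
    if (epoch - last_improve >= config$plateau_patience) {
      lr <- lr * config$plateau_factor
      last_improve <- epoch
    }
  }
  list(model = model, history = history)
}

#' Simulate the plateau learning-rate schedule on a fixed loss sequence
#'
#' Pure schedule arithmetic, exposed so the decay rule can be inspected
#' without training: returns the learning rate in force at every epoch.
#'
#' @param losses per-epoch (validation) losses.
#' @param lr0 initial learning rate.
#' @param patience,factor plateau parameters.
#' @return numeric vector of learning rates, one per epoch.
#' @export
plateau_schedule <- function(losses, lr0 = 1e-4, patience = 10,
                             factor = 0.1) {
  lr <- lr0
  best <- Inf
  last_improve <- 0L
  out <- numeric(length(losses))
  for (epoch in seq_along(losses)) {
    out[epoch] <- lr
    if (losses[epoch] < best) {
      best <- losses[epoch]
      if (epoch > 1) last_improve <- epoch
    }
    if (epoch - last_improve >= patience) {
      lr <- lr * factor
      last_improve <- epoch
    }
  }
  out
}

#' Evaluate a model: classification metrics plus localization IoU
#'
#' Classification metrics are computed over every record; mean IoU is
#' computed over the box-annotated subset only, using the coordinate head
#' when the model has one, otherwise Grad-CAM boxes at the given threshold.
#'
#' @param model an [hc_model()].
#' @param data list from [prepare_dataset()].
#' @param cam_threshold heatmap cut for box extraction (default 230).
#' @param cam_layer Grad-CAM target layer.
#' @param prob_threshold classification cut (default 0.5).
#' @param localizer `"auto"` (coordinate head if present), `"cam"`, or
#'   `"coords"`.
#' @return a [metrics_report()].
#' @export
evaluate_model <- function(model, data, cam_threshold = 230,
                           cam_layer = "hypercolumn", prob_threshold = 0.5,
                           localizer = c("auto", "cam", "coords")) {
  localizer <- match.arg(localizer)
  if (localizer == "auto")
    localizer <- if (model$config$with_coords) "coords" else "cam"
  if (localizer == "coords" && !model$config$with_coords)
    stop("model has no coordinate head")
  fw <- hc_predict_chunked(model, data$x)
  frame <- dim(data$x)[1]
  boxed <- which(vapply(data$boxes,
                        function(b) !is.null(b) && nrow(b) > 0, TRUE))
  ious <- vapply(boxed, function(i) {
    pred <- if (localizer == "coords") {
      cr <- fw$coords_raw[, i]
      b <- data.frame(x_min = min(cr[1], cr[3]) * frame,
                      y_min = min(cr[2], cr[4]) * frame,
                      x_max = max(cr[1], cr[3]) * frame,
                      y_max = max(cr[2], cr[4]) * frame)
      if (b$x_min < b$x_max && b$y_min < b$y_max) b else empty_boxes()
    } else {
      h <- grad_cam(model, data$x[, , , i, drop = TRUE],
                    target_layer = cam_layer)
      heatmap_to_boxes(h, threshold = cam_threshold)
    }
    match_iou(pred, data$boxes[[i]])
  }, 0)
  metrics_report(data$y, fw$prob, ious, prob_threshold)
}
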