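#' Training-time augmentation
#'
#' Each transform is applied independently: horizontal flip with
#' probability 0.5; rotation by a uniform angle in `[0, 360)` degrees
#' (bilinear, reflective borders); optional HSV jitter (hue +-0.05,
#' saturation/value +-20%); random cutout -- with probability 0.5 one
#' rectangle with side uniform in 10--40% of the tile side is filled with
#' greyscale value 127 on all channels. Disabling everything returns the
#' input unchanged. Randomness draws from R's RNG, so results are
#' reproducible under `set.seed()`.
#'
#' @param pixels `H x W x 3` array, values 0--255.
#' @param flip,rotate,hsv,cutout logical switches per transform.
#' @return augmented pixel array (integer, 0--255).
#' @export
augment <- function(pixels, flip = TRUE, rotate = TRUE, hsv = FALSE,
                    cutout = TRUE) {
  if (flip && runif(1) < 0.5) pixels <- flip_h(pixels)
  if (rotate) pixels <- rotate_tile(pixels, runif(1, 0, 360))
  if (hsv) pixels <- hsv_jitter(pixels, runif(1, -0.05, 0.05),
                                runif(1, 0.8, 1.2), runif(1, 0.8, 1.2))
  if (cutout && runif(1) < 0.5) {
    side <- max(1L, round(dim(pixels)[1] * runif(1, 0.1, 0.4)))
    h0 <- sample.int(dim(pixels)[1] - side + 1, 1)
    w0 <- sample.int(dim(pixels)[2] - side + 1, 1)
    pixels <- cutout_rect(pixels, h0, w0, side)
  }
  pixels
}

#' @rdname augment
#' @export
flip_h <- function(pixels) pixels[, rev(seq_len(dim(pixels)[2])), , drop = FALSE]

#' @rdname augment
#' @param angle rotation angle in degrees (counter-clockwise).
#' @export
rotate_tile <- function(pixels, angle) {
  d <- dim(pixels)
  out <- rotate_bilinear(as.numeric(pixels), d[1], d[2], d[3], angle)
  out <- clip255(round(out))
  storage.mode(out) <- "integer"
  array(out, d)
}

#' @rdname augment
#' @param h0,w0 top-left corner (1-based) of the cutout rectangle.
#' @param side rectangle side in pixels; filled with greyscale 127.
#' @export
cutout_rect <- function(pixels, h0, w0, side) {
  pixels[h0:(h0 + side - 1), w0:(w0 + side - 1), ] <- 127L
  pixels
}

#' @rdname augment
#' @param dh additive hue shift (hue in `[0, 1]`).
#' @param sf,vf multiplicative saturation and value factors.
#' @export
hsv_jitter <- function(pixels, dh, sf, vf) {
  d <- dim(pixels)
  m <- matrix(as.numeric(pixels), ncol = 3)
  hsv <- grDevices::rgb2hsv(t(m), maxColorValue = 255)
  hsv[1, ] <- (hsv[1, ] + dh) %% 1
  hsv[2, ] <- clip01(hsv[2, ] * sf)
  hsv[3, ] <- clip01(hsv[3, ] * vf)
  cols <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  out <- t(grDevices::col2rgb(cols))
  out <- array(as.integer(out), d)
  out
}

# weighted softmax cross-entropy; returns loss and dlogits
softmax_xent <- function(logits, y, w) {
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  n <- nrow(logits)
  ll <- -log(pmax(p[cbind(seq_len(n), y)], 1e-12))
  loss <- sum(w * ll) / sum(w)
  dl <- p
  dl[cbind(seq_len(n), y)] <- dl[cbind(seq_len(n), y)] - 1
  dl <- dl * (w / sum(w))
  list(loss = loss, dlogits = dl)
}

#' Train the CNN with Adam, checkpointing and early stopping
#'
#' Pixels are scaled to `[0, 1]`; training tiles are augmented and
#' shuffled every epoch; mini-batches of `batch_size` are optimized with
#' Adam. The weights from the epoch with the lowest validation loss are
#' restored at the end (checkpointing). With `early_stop = TRUE` training
#' stops once the validation loss has not improved for `patience`
#' consecutive epochs. Class weights, when enabled, are inverse to the
#' training class frequencies (so a 2:1 imbalance gives the minority
#' class twice the per-sample weight).
#'
#' @param model a `histocnn` from [build_model()].
#' @param data a `tile_dataset` (uses `$train` and `$val`) or a list with
#'   `train` and `val` tile lists.
#' @param epochs maximum number of epochs.
#' @param lr,batch_size Adam learning rate and mini-batch size.
#' @param patience early-stopping patience on validation loss.
#' @param early_stop disable to always run `epochs` epochs.
#' @param class_weights use inverse-frequency class weights.
#' @param l2 L2 weight-penalty coefficient (applied to conv/dense
#'   weights, not biases).
#' @param augment_train apply training-time augmentation.
#' @param hsv_aug include HSV jitter in the augmentation.
#' @param seed RNG seed controlling shuffling and augmentation.
#' @param verbose print per-epoch progress.
#' @return a `histocnn_fit`: list with `model` (best weights), `history`
#'   (tibble: epoch, train_loss, val_loss, val_bacc), `best_epoch`,
#'   `epochs_run`.
#' @export
train_cnn <- function(model, data, epochs = 40, lr = 2e-4, batch_size = 32,
                      patience = 50, early_stop = TRUE, class_weights = TRUE,
                      l2 = 1e-4, augment_train = TRUE, hsv_aug = FALSE,
                      seed = 1, verbose = FALSE) {
  train <- data$train; val <- data$val
  if (!length(train) || !length(val)) stop("train and val must be non-empty")
  y_tr <- match(tile_labels(train), model$classes)
  y_va <- match(tile_labels(val), model$classes)
  cw <- c(1, 1)
  if (class_weights) {
    freq <- tabulate(y_tr, 2) / length(y_tr)
    cw <- ifelse(freq > 0, 1 / (2 * freq), 0)
  }
  names(cw) <- model$classes
  xva <- tiles_to_batch(val)
  params <- flatten_params(model)
  mstate <- lapply(params, function(p) p * 0)
  vstate <- mstate
  tstep <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  best <- list(loss = Inf, params = params, epoch = 0)
  wait <- 0
  hist <- list()
  epochs_run <- 0
  with_seed(derive_seed(seed, 99L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(train))
      tr_loss <- 0; nb <- 0
      for (s in seq(1, length(train), by = batch_size)) {
        idx <- ord[s:min(length(train), s + batch_size - 1)]
        px <- lapply(train[idx], function(t)
          if (augment_train) augment(t$pixels, hsv = hsv_aug) else t$pixels)
        x <- tiles_to_batch(px)
        fw <- nn_forward(model, x, keep_cache = TRUE, single = TRUE)
        sx <- softmax_xent(fw$logits, y_tr[idx], cw[y_tr[idx]])
        if (!is.finite(sx$loss))
          stop("training diverged (non-finite loss) at epoch ", ep)
        bw <- nn_backward(model, fw$caches, sx$dlogits, single = TRUE)
        g <- flatten_grads(model, bw$grads)
        tstep <- tstep + 1
        for (nmp in names(params)) {
          gp <- g[[nmp]]
          if (l2 > 0 && grepl("\\.W$", nmp)) gp <- gp + l2 * params[[nmp]]
          mstate[[nmp]] <- b1 * mstate[[nmp]] + (1 - b1) * gp
          vstate[[nmp]] <- b2 * vstate[[nmp]] + (1 - b2) * gp^2
          mh <- mstate[[nmp]] / (1 - b1^tstep)
          vh <- vstate[[nmp]] / (1 - b2^tstep)
          params[[nmp]] <- params[[nmp]] - lr * mh / (sqrt(vh) + eps)
        }
        model <- set_params(model, params)
        tr_loss <- tr_loss + sx$loss; nb <- nb + 1
      }
      # validation
      pv <- predict(model, xva)
      lv <- -mean(log(pmax(pv[cbind(seq_along(y_va), y_va)], 1e-12)))
      if (!is.finite(lv))
        stop("training diverged (non-finite loss) at epoch ", ep)
      pred <- max.col(pv)
      bacc <- mean(c(mean(pred[y_va == 1] == 1), mean(pred[y_va == 2] == 2)),
                   na.rm = TRUE)
      hist[[ep]] <- tibble::tibble(epoch = ep, train_loss = tr_loss / nb,
                                   val_loss = lv, val_bacc = bacc)
      epochs_run <- ep
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f  val_bacc %.3f",
                        ep, tr_loss / nb, lv, bacc))
      if (lv < best$loss) {
        best <- list(loss = lv, params = params, epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
        if (early_stop && wait >= patience) break
      }
    }
  })
  model <- set_params(model, best$params)
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 best_epoch = best$epoch, epochs_run = epochs_run,
                 val_loss = best$loss, class_weights_used = cw),
            class = "histocnn_fit")
}

#' @export
print.histocnn_fit <- function(x, ...) {
  cat(sprintf("<histocnn_fit %d epochs (best %d, val loss %.4f)>\n",
              x$epochs_run, x$best_epoch, x$val_loss))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.histocnn_fit <- function(x, ...) {
  tibble::tibble(epochs_run = x$epochs_run, best_epoch = x$best_epoch,
                 val_loss = x$val_loss,
                 val_bacc = x$history$val_bacc[x$best_epoch])
}

#' @exportS3Method generics::tidy
tidy.histocnn_fit <- function(x, ...) x$history

# trapezoidal ROC-AUC over the positive-class score (rank/Mann-Whitney
# formulation; ties contribute half)
auc_trapezoid <- function(score, positive) {
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification metrics on a set of tiles
#'
#' Computes the confusion matrix at the argmax decision, precision,
#' recall, F1, balanced accuracy (`(recall + specificity) / 2`), and the
#' trapezoidal ROC-AUC of the positive-class probability.
#'
#' @param model a `histocnn` or `histocnn_fit`.
#' @param tiles non-empty list of tiles (both classes needed for AUC;
#'   with one class the AUC is `NA` and flagged).
#' @return a `cnn_metrics` list: `balanced_accuracy`, `auc`, `f1`,
#'   `precision`, `recall`, `confusion` (TP, FP, FN, TN), `n`,
#'   `single_class`.
#' @export
evaluate_cnn <- function(model, tiles) {
  if (inherits(model, "histocnn_fit")) model <- model$model
  if (!length(tiles)) stop("tiles must be non-empty")
  y <- tile_labels(tiles) == "positive"
  p <- predict(model, tiles)[, "positive"]
  pred <- p >= 0.5
  conf <- c(TP = sum(pred & y), FP = sum(pred & !y),
            FN = sum(!pred & y), TN = sum(!pred & !y))
  metrics_from_confusion(conf, auc = auc_trapezoid(p, y), n = length(y),
                         single_class = !any(y) || all(y))
}

#' Metrics from a confusion-matrix count vector
#'
#' @param conf named vector with `TP`, `FP`, `FN`, `TN`.
#' @param auc optional AUC to attach.
#' @param n number of observations.
#' @param single_class flag that only one class was present.
#' @return a `cnn_metrics` object.
#' @export
metrics_from_confusion <- function(conf, auc = NA_real_, n = sum(conf),
                                   single_class = FALSE) {
  TP <- conf[["TP"]]; FP <- conf[["FP"]]; FN <- conf[["FN"]]; TN <- conf[["TN"]]
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  specificity <- if (TN + FP > 0) TN / (TN + FP) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(balanced_accuracy = mean(c(recall, specificity), na.rm = TRUE),
                 auc = auc, f1 = f1, precision = precision, recall = recall,
                 confusion = conf, n = n, single_class = single_class),
            class = "cnn_metrics")
}

#' @export
print.cnn_metrics <- function(x, ...) {
  cat(sprintf(paste0("<cnn_metrics n=%d  bacc %.3f  auc %s  f1 %.3f  ",
                     "precision %.3f  recall %.3f>\n"),
              x$n, x$balanced_accuracy,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc)),
              x$f1, x$precision, x$recall))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cnn_metrics <- function(x, ...) {
  tibble::tibble(balanced_accuracy = x$balanced_accuracy, auc = x$auc,
                 f1 = x$f1, precision = x$precision, recall = x$recall,
                 n = x$n)
}
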