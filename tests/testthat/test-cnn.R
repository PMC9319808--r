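test_that("layer output sizes match the architecture table", {
  m <- build_model(256, seed = 1)
  x <- array(runif(256 * 256 * 3), c(256, 256, 3, 1))
  fw <- histobias:::nn_forward(m, x, taps = c("conv1", "pool1", "res2_2",
                                              "stage3"))
  expect_identical(dim(fw$taps$conv1)[1:3], c(128L, 128L, 32L))
  expect_identical(dim(fw$taps$pool1)[1:3], c(64L, 64L, 32L))
  expect_identical(dim(fw$taps$res2_2)[1:3], c(64L, 64L, 32L))
  expect_identical(dim(fw$taps$res3_3)[1:3], c(32L, 32L, 64L))
  expect_equal(rowSums(fw$probs), 1, tolerance = 1e-6)
})

test_that("the body is fully convolutional: parameters do not depend on input size", {
  p96 <- histobias:::flatten_params(build_model(96, seed = 2))
  p256 <- histobias:::flatten_params(build_model(256, seed = 2))
  expect_identical(lapply(p96, dim), lapply(p256, dim))
  expect_error(build_model(100), "divisible")
})

test_that("activations have the documented shapes and are deterministic", {
  m <- build_model(96, seed = 4)
  tiles <- lapply(1:3, function(s)
    generate_tile("positive", "A", 1, "nuclei_dense", seed = s))
  a <- activations(m, "fc16", tiles)
  expect_identical(dim(a), c(3L, 16L))
  a2 <- activations(m, "fc16", tiles[c(1, 1)])
  expect_equal(a2[1, ], a2[2, ])
  s3 <- activations(m, "stage3", tiles)
  expect_identical(dim(s3), c(12L, 12L, 64L, 3L))
  expect_error(activations(m, "nope", tiles), "unknown layer")
})

test_that("class gradients match central finite differences", {
  m <- tiny_model()
  set.seed(8)
  x <- array(runif(32 * 32 * 3 * 1), c(32, 32, 3, 1))
  fw <- histobias:::nn_forward(m, x, keep_cache = TRUE)
  dl <- matrix(c(0, 1), 1)
  bw <- histobias:::nn_backward(m, fw$caches, dl, need_param_grads = FALSE,
                                need_input_grad = TRUE)
  f <- function(xx) histobias:::nn_forward(m, xx)$logits[1, 2]
  for (rep in 1:5) {
    i <- sample(length(x), 1)
    eps <- 1e-6
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (f(xp) - f(xm)) / (2 * eps)
    expect_lt(abs(num - bw$dx[i]) / max(1e-6, abs(num)), 1e-3)
  }
})

test_that("class gradients are batch independent and one-hot at the logits", {
  m <- tiny_model()
  tiles <- lapply(1:2, function(s)
    list(pixels = array(as.integer(round(runif(32 * 32 * 3, 0, 255))),
                        c(32, 32, 3)), label = "positive"))
  g2 <- class_gradient(m, "fc16", "positive", tiles)
  g1a <- class_gradient(m, "fc16", "positive", tiles[1])
  g1b <- class_gradient(m, "fc16", "positive", tiles[2])
  expect_equal(g2, rbind(g1a, g1b), tolerance = 1e-5)
  expect_equal(class_gradient(m, "logits", "positive", tiles[1]),
               matrix(c(0, 1), 1))
})

test_that("augmentation transforms behave as specified", {
  px <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 2)$pixels
  # cutout forced at a known position is exactly 127
  cut <- cutout_rect(px, 10, 20, 16)
  expect_true(all(cut[10:25, 20:35, ] == 127L))
  out <- abs(cut - px); out[10:25, 20:35, ] <- 0L
  expect_identical(sum(out), 0L)
  # everything disabled is the identity
  expect_identical(augment(px, flip = FALSE, rotate = FALSE, hsv = FALSE,
                           cutout = FALSE), px)
  # flip is an involution
  expect_identical(flip_h(flip_h(px)), px)
  # rotation preserves shape and range
  rot <- rotate_tile(px, 123.4)
  expect_identical(dim(rot), dim(px))
  expect_true(all(rot >= 0 & rot <= 255))
})

test_that("training learns a linearly separable marker signal perfectly", {
  tiles <- toy_marker_tiles(n_each = 16, size = 32)
  data <- list(train = tiles, val = tiles[c(1:4, 17:20)])
  m <- build_model(32, widths = c(8, 16), fc_units = 8, seed = 1)
  fit <- train_cnn(m, data, epochs = 60, patience = 60, batch_size = 16,
                   augment_train = FALSE, seed = 3)
  metr <- evaluate_cnn(fit, tiles)
  expect_equal(metr$balanced_accuracy, 1.0)
})

test_that("early stopping waits exactly `patience` epochs without improvement", {
  tiles <- toy_marker_tiles(n_each = 4, size = 32)
  data <- list(train = tiles, val = tiles)
  m <- build_model(32, widths = c(4, 8), fc_units = 6, seed = 1)
  # lr = 0: the validation loss never improves after the first epoch
  fit <- train_cnn(m, data, epochs = 30, lr = 0, patience = 3,
                   augment_train = FALSE, seed = 1)
  expect_identical(fit$epochs_run, 4L)
  expect_identical(fit$best_epoch, 1L)
  # with early stopping disabled the loop runs all epochs
  fit2 <- train_cnn(m, data, epochs = 5, lr = 0, early_stop = FALSE,
                    augment_train = FALSE, seed = 1)
  expect_identical(fit2$epochs_run, 5L)
})

test_that("class weights are inverse to class frequency", {
  tiles <- toy_marker_tiles(n_each = 12, size = 32)
  # 2:1 imbalance: drop half the positives
  imb <- tiles[c(1:6, 13:24)]
  data <- list(train = imb, val = imb)
  m <- build_model(32, widths = c(4, 8), fc_units = 6, seed = 1)
  fit <- train_cnn(m, data, epochs = 1, augment_train = FALSE, seed = 1)
  cw <- fit$class_weights_used   # order: negative, positive
  expect_equal(cw[["positive"]] / cw[["negative"]], 2, tolerance = 1e-6)
  fit0 <- train_cnn(m, data, epochs = 1, class_weights = FALSE,
                    augment_train = FALSE, seed = 1)
  expect_equal(unname(fit0$class_weights_used), c(1, 1))
})

test_that("metrics match their definitions and the reported operating points", {
  m <- metrics_from_confusion(c(TP = 2, FP = 0, FN = 1, TN = 3))
  expect_equal(m$precision, 1.0)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-4)
  expect_equal(m$balanced_accuracy, (2 / 3 + 1) / 2, tolerance = 1e-4)
  # F1 at the two operating points the study reports
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(round(f1(0.80, 2 / 3), 3), 0.727)
  expect_equal(round(f1(0.75, 1.00), 3), 0.857)
  expect_equal(metrics_from_confusion(c(TP = 3, FP = 1, FN = 1, TN = 3))$f1,
               f1(0.75, 0.75))
})

test_that("trapezoidal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  y <- rep(c(TRUE, FALSE), c(30, 40))
  score <- rnorm(70) + y * 0.8
  ours <- histobias:::auc_trapezoid(score, y)
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
  # single-class input is flagged
  tiles <- toy_marker_tiles(n_each = 2, size = 32)[1:2]
  mm <- build_model(32, widths = c(4, 8), fc_units = 6, seed = 1)
  metr <- evaluate_cnn(mm, tiles)
  expect_true(metr$single_class)
  expect_true(is.na(metr$auc))
})

test_that("training reports divergence with the epoch index", {
  tiles <- toy_marker_tiles(n_each = 4, size = 32)
  data <- list(train = tiles, val = tiles)
  m <- build_model(32, widths = c(4, 8), fc_units = 6, seed = 1)
  expect_error(train_cnn(m, data, epochs = 3, lr = 1e30,
                         augment_train = FALSE, seed = 1),
               "diverged|epoch")
})
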