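#' Grad-CAM, guided backpropagation and Guided Grad-CAM
#'
#' Grad-CAM weights each feature map of the deepest spatial layer by the
#' global average of the class-logit gradient over that map, sums the
#' weighted maps and rectifies; the result is a coarse class-localization
#' map. Guided backpropagation computes the pixel gradient of the class
#' logit with a gating rule at every activation site (backward signal
#' zeroed where the incoming gradient or the forward pre-activation is
#' negative; here applied at Swish sites using the pre-activation sign).
#' Guided Grad-CAM is the pointwise product of the bilinearly upsampled
#' coarse map with the guided-backprop image.
#'
#' @name saliency
NULL

#' Grad-CAM feature-map weights
#'
#' Global average pooling of the class gradient per feature map:
#' `alpha_k = mean_ij dY/dA_ijk`.
#'
#' @param feature_maps `u x v x K` activation array (unused except for
#'   shape checking; may be `NULL`).
#' @param gradients `u x v x K` gradient array of the class logit with
#'   respect to the feature maps.
#' @return numeric vector of K weights.
#' @export
gradcam_weights <- function(feature_maps, gradients) {
  if (!is.null(feature_maps) && !identical(dim(feature_maps), dim(gradients)))
    stop("feature map and gradient shapes differ")
  apply(gradients, 3, mean)
}

#' Grad-CAM coarse map
#'
#' `ReLU(sum_k alpha_k A_k)`, elementwise over the spatial grid.
#'
#' @param feature_maps `u x v x K` activation array.
#' @param weights K per-map weights.
#' @return non-negative `u x v` matrix.
#' @export
gradcam_map <- function(feature_maps, weights) {
  if (dim(feature_maps)[3] != length(weights))
    stop("need one weight per feature map")
  d <- dim(feature_maps)
  m <- matrix(feature_maps, d[1] * d[2]) %*% weights
  matrix(pmax(m, 0), d[1], d[2])
}

#' Guided backpropagation image
#'
#' Gradient of the class logit with respect to the input pixels with the
#' guided gating rule applied at every Swish site. With `gates = FALSE`
#' this reduces to the plain input gradient.
#'
#' @param model a `histocnn` or `histocnn_fit`.
#' @param tile a tile or pixel array.
#' @param class_k `"positive"` or `"negative"` (or column index).
#' @param gates apply the guided gating rule.
#' @param target `"margin"` differentiates the class margin
#'   (logit_k - logit_other), the quantity that drives a 2-class softmax
#'   prediction; `"logit"` the raw class logit.
#' @return signed `H x W x 3` gradient array.
#' @export
guided_backprop <- function(model, tile, class_k, gates = TRUE,
                            target = c("margin", "logit")) {
  target <- match.arg(target)
  if (inherits(model, "histocnn_fit")) model <- model$model
  x <- tiles_to_batch(list(tile))
  k <- if (is.character(class_k)) match(class_k, model$classes) else class_k
  fw <- nn_forward(model, x, keep_cache = TRUE)
  dl <- matrix(0, 1, 2); dl[, k] <- 1
  if (target == "margin") dl[, 3 - k] <- -1
  bw <- nn_backward(model, fw$caches, dl, guided = gates,
                    need_param_grads = FALSE, need_input_grad = TRUE)
  array(bw$dx, dim(bw$dx)[1:3])
}

#' Guided Grad-CAM map
#'
#' Pointwise product of the bilinearly upsampled coarse map with the
#' guided-backprop image (per channel).
#'
#' @param coarse `u x v` Grad-CAM map.
#' @param gbp `H x W x 3` guided-backprop image.
#' @return list with `rgb` (signed `H x W x 3` product) and `magnitude`
#'   (non-negative `H x W`, upsampled coarse times the l2 channel
#'   magnitude of `gbp`).
#' @export
guided_gradcam <- function(coarse, gbp) {
  d <- dim(gbp)
  up <- resize_bilinear(as.numeric(coarse), nrow(coarse), ncol(coarse), 1L,
                        d[1], d[2])
  up <- array(up, d[1:2])
  rgb <- gbp
  for (c in 1:3) rgb[, , c] <- gbp[, , c] * up
  mag <- up * sqrt(gbp[, , 1]^2 + gbp[, , 2]^2 + gbp[, , 3]^2)
  list(rgb = rgb, magnitude = mag, upsampled = up)
}

#' Full saliency heatmap for one tile and class
#'
#' @inheritParams guided_backprop
#' @param layer spatial layer for Grad-CAM (default the deepest,
#'   `"stage3"`).
#' @return a `saliency_heatmap`: list with `coarse` (non-negative
#'   Grad-CAM map at the layer's spatial size), `gbp` (signed pixel
#'   gradients), `guided` (non-negative `H x W` magnitude map),
#'   `guided_rgb`, `class_k`.
#' @export
compute_heatmap <- function(model, tile, class_k, layer = "stage3",
                            target = c("margin", "logit")) {
  target <- match.arg(target)
  if (inherits(model, "histocnn_fit")) model <- model$model
  A <- activations(model, layer, list(tile))
  A <- array(A, dim(A)[1:3])
  G <- class_gradient(model, layer, class_k, list(tile), target = target)
  G <- array(G, dim(G)[1:3])
  w <- gradcam_weights(A, G)
  coarse <- gradcam_map(A, w)
  gbp <- guided_backprop(model, tile, class_k, target = target)
  gg <- guided_gradcam(coarse, gbp)
  structure(list(coarse = coarse, gbp = gbp, guided = gg$magnitude,
                 guided_rgb = gg$rgb, class_k = class_k, layer = layer),
            class = "saliency_heatmap")
}

# simple blue-red colormap for overlay rendering
heat_colors <- function(v) {
  v <- clip01(v)
  cbind(r = clip01(1.5 * v - 0.25), g = clip01(1 - abs(2 * v - 1)),
        b = clip01(1.25 - 1.5 * v))
}

#' Render a saliency triptych to PNG files
#'
#' Writes (a) the tile, (b) the tile with the upsampled coarse map
#' superimposed as a colormap, and (c) the guided image (signed
#' gradients on grey).
#'
#' @param tile a tile or pixel array.
#' @param heatmap a `saliency_heatmap`.
#' @param prefix output path prefix; files `<prefix>_tile.png`,
#'   `<prefix>_gradcam.png`, `<prefix>_guided.png` are written.
#' @return invisibly, the three paths.
#' @export
render_heatmap <- function(tile, heatmap, prefix) {
  px <- if (is.list(tile)) tile$pixels else tile
  d <- dim(px)
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  p1 <- paste0(prefix, "_tile.png")
  png::writePNG(px / 255, p1)
  # overlay
  up <- resize_bilinear(as.numeric(heatmap$coarse), nrow(heatmap$coarse),
                        ncol(heatmap$coarse), 1L, d[1], d[2])
  mx <- max(up)
  up <- if (mx > 0) up / mx else up
  hc <- heat_colors(as.vector(up))
  overlay <- array(0, d)
  alpha <- 0.45
  for (c in 1:3)
    overlay[, , c] <- (1 - alpha) * px[, , c] / 255 +
      alpha * array(hc[, c], d[1:2])
  p2 <- paste0(prefix, "_gradcam.png")
  png::writePNG(clip01(overlay), p2)
  # guided image: signed gradients centered on grey
  g <- heatmap$guided_rgb
  s <- stats::quantile(abs(g), 0.99)
  if (s == 0) s <- 1
  p3 <- paste0(prefix, "_guided.png")
  png::writePNG(clip01(0.5 + g / (2 * s)), p3)
  invisible(c(p1, p2, p3))
}
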