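#' Compact residual CNN for tile classification
#'
#' Architecture: a 7x7/32 stride-2 stem, 3x3/2 max pool, two residual
#' blocks of two 3x3x32 convolutions, three residual blocks of two 3x3x64
#' convolutions (the first downsampling with stride 2 via a 1x1 projection
#' shortcut), then global max pooling, a 16-unit fully connected layer and
#' a 2-class softmax. All activations are Swish. With 256x256 input the
#' stage outputs are 128, 64 and 32 pixels; the body is fully
#' convolutional so the parameter count is invariant to input size.
#'
#' @name cnn
NULL

swish <- function(x) swish_fwd(x)

# activation backward; `guided` applies the guided-backprop gating rule:
# the backward signal is zeroed where the incoming gradient is negative or
# the forward pre-activation is negative
act_bwd <- function(dout, z, act, guided = FALSE) {
  if (act == "none") return(dout)
  swish_bwd(dout, z, guided)
}

new_conv <- function(name, kh, kw, cin, cout, stride, pad, act = "swish") {
  list(type = "conv", name = name, kh = kh, kw = kw, cin = cin, cout = cout,
       stride = stride, pad = pad, act = act,
       W = array(rnorm(kh * kw * cin * cout, 0, sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

new_dense <- function(name, nin, nout, act = "none") {
  list(type = "dense", name = name, nin = nin, nout = nout, act = act,
       W = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

new_resblock <- function(name, cin, cout, stride) {
  list(type = "resblock", name = name, stride = stride,
       conv1 = new_conv(paste0(name, ".1"), 3, 3, cin, cout, stride, 1, "none"),
       conv2 = new_conv(paste0(name, ".2"), 3, 3, cout, cout, 1, 1, "none"),
       proj = if (stride != 1 || cin != cout)
         new_conv(paste0(name, ".p"), 1, 1, cin, cout, stride, 0, "none"))
}

#' Build the residual tile-classification CNN
#'
#' @param input_size tile side in pixels; must be divisible by 8.
#' @param widths channel widths of the two residual stages.
#' @param fc_units units of the fully connected embedding layer.
#' @param seed RNG seed for weight initialization (He-scaled Gaussian).
#' @return a `histocnn` model object. Named layers addressable by
#'   [activations()] / [class_gradient()]: `conv1`, `pool1`, `res2_1`,
#'   `res2_2`, `res3_1`..`res3_3` (alias `stage3`), `gpool`, `fc16`
#'   (alias `fc`), `logits`.
#' @export
build_model <- function(input_size = 96, widths = c(32, 64), fc_units = 16,
                        seed = 1) {
  if (input_size %% 8 != 0) stop("input size must be divisible by 8")
  w2 <- widths[1]; w3 <- widths[2]
  with_seed(derive_seed(seed, 77L), {
    layers <- list(
      new_conv("conv1", 7, 7, 3, w2, 2, 3, "swish"),
      list(type = "maxpool", name = "pool1", k = 3, stride = 2, pad = 1),
      new_resblock("res2_1", w2, w2, 1),
      new_resblock("res2_2", w2, w2, 1),
      new_resblock("res3_1", w2, w3, 2),
      new_resblock("res3_2", w3, w3, 1),
      new_resblock("res3_3", w3, w3, 1),
      list(type = "gmaxpool", name = "gpool"),
      new_dense("fc16", w3, fc_units, "swish"),
      new_dense("logits", fc_units, 2, "none"))
  })
  structure(list(layers = layers, input_size = input_size, widths = widths,
                 fc_units = fc_units, classes = c("negative", "positive")),
            class = "histocnn")
}

#' @export
print.histocnn <- function(x, ...) {
  np <- sum(vapply(flatten_params(x), length, numeric(1)))
  cat(sprintf("<histocnn %dpx widths %s fc%d, %d parameters>\n",
              x$input_size, paste(x$widths, collapse = "/"), x$fc_units, np))
  invisible(x)
}

resolve_layer <- function(name) {
  switch(name, "stage3" = "res3_3", "fc" = "fc16", "FC-16" = "fc16", name)
}

conv_fwd_op <- function(op, x, single = FALSE) {
  d <- dim(x)
  kfun <- if (single) conv2d_fwd_f else conv2d_fwd
  z <- kfun(x, matrix(op$W, op$kh * op$kw * op$cin, op$cout), op$b,
            d[1], d[2], d[3], d[4], op$kh, op$kw, op$stride, op$pad)
  a <- if (op$act == "swish") swish(z) else z
  list(out = a, cache = list(x = x, z = z))
}

conv_bwd_op <- function(op, cache, dout, guided, need_w, need_dx = TRUE,
                        single = FALSE) {
  dz <- act_bwd(dout, cache$z, op$act, guided)
  d <- dim(cache$x)
  kfun <- if (single) conv2d_bwd_f else conv2d_bwd
  r <- kfun(cache$x, matrix(op$W, op$kh * op$kw * op$cin, op$cout), dz,
            d[1], d[2], d[3], d[4], op$kh, op$kw, op$stride, op$pad,
            need_dx, need_w)
  grads <- if (need_w) list(W = array(r$dw, dim(op$W)), b = r$db)
  list(dx = r$dx, grads = grads)
}

# forward pass; returns probabilities plus optional tapped activations
# and the caches needed for a backward pass
nn_forward <- function(model, x, keep_cache = FALSE, taps = character(),
                       single = FALSE) {
  taps <- vapply(taps, resolve_layer, character(1))
  caches <- vector("list", length(model$layers))
  tapped <- list()
  for (i in seq_along(model$layers)) {
    op <- model$layers[[i]]
    if (op$type == "conv") {
      r <- conv_fwd_op(op, x, single); x <- r$out; caches[[i]] <- r$cache
    } else if (op$type == "maxpool") {
      d <- dim(x)
      r <- maxpool_fwd(x, d[1], d[2], d[3], d[4], op$k, op$stride, op$pad)
      caches[[i]] <- list(argmax = r$argmax, dim_in = d, dim_out = dim(r$out))
      x <- r$out
    } else if (op$type == "resblock") {
      r1 <- conv_fwd_op(op$conv1, x, single)
      a1 <- swish(r1$out)
      r2 <- conv_fwd_op(op$conv2, a1, single)
      sc <- if (!is.null(op$proj)) conv_fwd_op(op$proj, x, single)
      zadd <- r2$out + if (is.null(sc)) x else sc$out
      out <- swish(zadd)
      caches[[i]] <- list(c1 = r1$cache, c2 = r2$cache,
                          cs = if (!is.null(sc)) sc$cache,
                          z1 = r1$out, zadd = zadd)
      x <- out
    } else if (op$type == "gmaxpool") {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2])            # (H*W) x (C*N)
      am <- max.col(t(m), ties.method = "first")
      vals <- m[cbind(am, seq_len(ncol(m)))]
      caches[[i]] <- list(argmax = am, dim_in = d)
      x <- t(matrix(vals, d[3]))             # N x C
    } else if (op$type == "dense") {
      z <- x %*% op$W + matrix(op$b, nrow(x), length(op$b), byrow = TRUE)
      a <- if (op$act == "swish") swish(z) else z
      caches[[i]] <- list(x = x, z = z)
      x <- a
    }
    if (op$name %in% taps) tapped[[op$name]] <- x
  }
  logits <- x
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  list(probs = p, logits = logits, caches = if (keep_cache) caches,
       taps = tapped)
}

# backward pass from dlogits. stop_at: return gradient w.r.t. that
# layer's *output* instead of descending further. guided: apply
# guided-backprop gating at every Swish site.
nn_backward <- function(model, caches, dlogits, stop_at = NULL,
                        guided = FALSE, need_param_grads = TRUE,
                        need_input_grad = FALSE, single = FALSE) {
  stop_at <- if (!is.null(stop_at)) resolve_layer(stop_at)
  grads <- vector("list", length(model$layers))
  names(grads) <- vapply(model$layers, function(l) l$name, character(1))
  g <- dlogits
  for (i in rev(seq_along(model$layers))) {
    op <- model$layers[[i]]
    if (!is.null(stop_at) && op$name == stop_at)
      return(list(dx = g, grads = grads))
    cache <- caches[[i]]
    if (op$type == "dense") {
      dz <- act_bwd(g, cache$z, op$act, guided)
      if (need_param_grads)
        grads[[i]] <- list(W = crossprod(cache$x, dz), b = colSums(dz))
      g <- dz %*% t(op$W)
    } else if (op$type == "gmaxpool") {
      d <- cache$dim_in
      dx <- numeric(prod(d))
      # g is N x C; column j of the (H*W) x (C*N) view is (c, n)
      gt <- as.numeric(t(g))                 # c fastest
      plane <- d[1] * d[2]
      idx <- cache$argmax + plane * (seq_along(cache$argmax) - 1)
      dx[idx] <- gt
      dim(dx) <- d
      g <- dx
    } else if (op$type == "maxpool") {
      d <- cache$dim_in; do_ <- cache$dim_out
      g <- maxpool_bwd(g, cache$argmax, d[1], d[2], d[3], d[4], do_[1], do_[2])
    } else if (op$type == "resblock") {
      dzadd <- act_bwd(g, cache$zadd, "swish", guided)
      r2 <- conv_bwd_op(op$conv2, cache$c2, dzadd, guided, need_param_grads,
                        single = single)
      da1 <- act_bwd(r2$dx, cache$z1, "swish", guided)
      r1 <- conv_bwd_op(op$conv1, cache$c1, da1, guided, need_param_grads,
                        single = single)
      if (!is.null(op$proj)) {
        rs <- conv_bwd_op(op$proj, cache$cs, dzadd, guided, need_param_grads,
                          single = single)
        dsc <- rs$dx
      } else dsc <- dzadd
      g <- r1$dx + dsc
      if (need_param_grads)
        grads[[i]] <- list(conv1 = r1$grads, conv2 = r2$grads,
                           proj = if (!is.null(op$proj)) rs$grads)
    } else if (op$type == "conv") {
      r <- conv_bwd_op(op, cache, g, guided, need_param_grads,
                       need_dx = i > 1 || need_input_grad, single = single)
      grads[[i]] <- r$grads
      g <- r$dx
    }
  }
  list(dx = g, grads = grads)
}

#' Class probabilities for a batch of tiles
#'
#' @param object a `histocnn` model.
#' @param tiles list of tiles or a 4-D `(H, W, 3, N)` batch in `[0, 1]`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return `N x 2` matrix of class probabilities (columns
#'   `negative`, `positive`), rows summing to 1.
#' @export
predict.histocnn <- function(object, tiles, batch_size = 64, ...) {
  x <- if (is.array(tiles) && length(dim(tiles)) == 4) tiles
    else tiles_to_batch(tiles)
  n <- dim(x)[4]
  out <- matrix(0, n, 2, dimnames = list(NULL, object$classes))
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    out[s:e, ] <- nn_forward(object, x[, , , s:e, drop = FALSE])$probs
  }
  out
}

#' Activations of a named layer
#'
#' Runs the network up to `layer` and returns its post-activation output:
#' an `N x d` matrix for vector layers (`gpool`, `fc16`, `logits`) or an
#' `(u, v, C, N)` array for spatial layers.
#'
#' @param model a `histocnn`.
#' @param layer layer name (see [build_model()]); `"fc16"` is the 16-d
#'   embedding used for concept extraction.
#' @param tiles tiles or 4-D batch in `[0, 1]`.
#' @param batch_size forward batch size.
#' @return activation matrix or array.
#' @export
activations <- function(model, layer, tiles, batch_size = 64) {
  layer <- resolve_layer(layer)
  nm <- vapply(model$layers, function(l) l$name, character(1))
  if (!layer %in% nm) stop("unknown layer name: ", layer)
  x <- if (is.array(tiles) && length(dim(tiles)) == 4) tiles
    else tiles_to_batch(tiles)
  n <- dim(x)[4]
  pieces <- list()
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    t <- nn_forward(model, x[, , , s:e, drop = FALSE], taps = layer)$taps[[layer]]
    pieces[[length(pieces) + 1]] <- t
  }
  if (is.matrix(pieces[[1]])) do.call(rbind, pieces)
  else {
    d <- dim(pieces[[1]])
    out <- array(0, c(d[1:3], n)); at <- 1
    for (p in pieces) { k <- dim(p)[4]; out[, , , at:(at + k - 1)] <- p; at <- at + k }
    out
  }
}

#' Gradient of a class logit with respect to a layer's activations
#'
#' Backpropagates the pre-softmax logit of `class_k` down to the named
#' layer's output. For the fully connected embedding layer this is the
#' gradient row used by TCAV directional derivatives; for the deepest
#' spatial layer it is the Grad-CAM gradient.
#'
#' @inheritParams activations
#' @param class_k `"positive"`, `"negative"`, or a column index (1/2).
#' @param guided apply the guided-backprop gating rule at Swish sites.
#' @param target `"logit"` differentiates the raw class-k logit;
#'   `"margin"` differentiates the softmax margin
#'   (logit_k - logit_other), the direction that maximizes the class-k
#'   prediction in a 2-class softmax (used by TCAV).
#' @return `N x d` matrix or `(u, v, C, N)` array matching the layer's
#'   activation shape.
#' @export
class_gradient <- function(model, layer, class_k, tiles, batch_size = 64,
                           guided = FALSE, target = c("logit", "margin")) {
  target <- match.arg(target)
  layer <- resolve_layer(layer)
  nm <- vapply(model$layers, function(l) l$name, character(1))
  li <- match(layer, nm)
  if (is.na(li)) stop("unknown layer name: ", layer)
  k <- if (is.character(class_k)) match(class_k, model$classes) else class_k
  if (is.na(k)) stop("unknown class: ", class_k)
  x <- if (is.array(tiles) && length(dim(tiles)) == 4) tiles
    else tiles_to_batch(tiles)
  n <- dim(x)[4]
  if (layer == "logits") {              # gradient of the logit w.r.t. itself
    g <- matrix(0, n, 2); g[, k] <- 1
    if (target == "margin") g[, 3 - k] <- -1
    return(g)
  }
  pieces <- list()
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    fw <- nn_forward(model, x[, , , s:e, drop = FALSE], keep_cache = TRUE)
    dl <- matrix(0, e - s + 1, 2); dl[, k] <- 1
    if (target == "margin") dl[, 3 - k] <- -1
    bw <- nn_backward(model, fw$caches, dl, stop_at = layer, guided = guided,
                      need_param_grads = FALSE)
    pieces[[length(pieces) + 1]] <- bw$dx
  }
  if (is.matrix(pieces[[1]])) do.call(rbind, pieces)
  else {
    d <- dim(pieces[[1]])
    out <- array(0, c(d[1:3], n)); at <- 1
    for (p in pieces) { kk <- dim(p)[4]; out[, , , at:(at + kk - 1)] <- p; at <- at + kk }
    out
  }
}

# ---- parameter plumbing (flatten to a named list for the optimizer) ----

flatten_params <- function(model) {
  out <- list()
  for (i in seq_along(model$layers)) {
    op <- model$layers[[i]]
    if (op$type %in% c("conv", "dense")) {
      out[[paste0(op$name, ".W")]] <- op$W
      out[[paste0(op$name, ".b")]] <- op$b
    } else if (op$type == "resblock") {
      for (part in c("conv1", "conv2", "proj")) {
        if (is.null(op[[part]])) next
        out[[paste0(op$name, ".", part, ".W")]] <- op[[part]]$W
        out[[paste0(op$name, ".", part, ".b")]] <- op[[part]]$b
      }
    }
  }
  out
}

flatten_grads <- function(model, grads) {
  out <- list()
  for (i in seq_along(model$layers)) {
    op <- model$layers[[i]]; g <- grads[[i]]
    if (op$type %in% c("conv", "dense")) {
      out[[paste0(op$name, ".W")]] <- g$W
      out[[paste0(op$name, ".b")]] <- g$b
    } else if (op$type == "resblock") {
      for (part in c("conv1", "conv2", "proj")) {
        if (is.null(op[[part]])) next
        out[[paste0(op$name, ".", part, ".W")]] <- g[[part]]$W
        out[[paste0(op$name, ".", part, ".b")]] <- g[[part]]$b
      }
    }
  }
  out
}

set_params <- function(model, flat) {
  for (i in seq_along(model$layers)) {
    op <- model$layers[[i]]
    if (op$type %in% c("conv", "dense")) {
      model$layers[[i]]$W <- flat[[paste0(op$name, ".W")]]
      model$layers[[i]]$b <- flat[[paste0(op$name, ".b")]]
    } else if (op$type == "resblock") {
      for (part in c("conv1", "conv2", "proj")) {
        if (is.null(op[[part]])) next
        model$layers[[i]][[part]]$W <- flat[[paste0(op$name, ".", part, ".W")]]
        model$layers[[i]][[part]]$b <- flat[[paste0(op$name, ".", part, ".b")]]
      }
    }
  }
  model
}
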