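#' Testing with concept activation vectors
#'
#' A concept activation vector (CAV) is the unit normal of a linear
#' classifier separating concept-patch activations from random
#' counterexample activations, oriented toward the concept side. The
#' TCAV score of a concept for class k is the fraction of class-k inputs
#' whose class-logit gradient has a positive dot product with the CAV.
#' Significance is assessed against random-vs-random null CAVs over
#' repeated runs with a two-sided Welch t-test.
#'
#' @name tcav
NULL

#' Sample random counterexample patches
#'
#' Draws `n` segments uniformly without replacement from a pooled set of
#' SLIC segments (prepared identically to concept patches). Each call
#' with a distinct seed gives a fresh draw.
#'
#' @param pool a `patch_pool` (or anything indexable of length
#'   `n_total`).
#' @param n number of segments to draw.
#' @param seed RNG seed for this draw.
#' @return integer vector of patch indices into the pool.
#' @export
sample_random_counterexamples <- function(pool, n, seed) {
  n_total <- if (inherits(pool, "patch_pool")) length(pool$patches)
    else length(pool)
  if (n_total < n) stop("too few segments in the pool (", n_total, " < ", n, ")")
  with_seed(seed, sample.int(n_total, n))
}

#' Train a concept activation vector
#'
#' Fits a linear max-margin classifier (hinge loss, L2 penalty; libsvm
#' with linear kernel, C = 1) on concept vs random embeddings and returns
#' the unit normal of the decision boundary oriented so that
#' concept-side scores are positive.
#'
#' @param concept_emb,random_emb embedding matrices (rows = patches).
#' @param seed RNG seed (libsvm shrinking is deterministic here, but the
#'   seed also covers any tie-breaking).
#' @param cost SVM regularization parameter C.
#' @return a `cav`: list with unit vector `v`, `train_accuracy`, `layer`.
#' @export
train_cav <- function(concept_emb, random_emb, seed = 1, cost = 1) {
  if (!nrow(concept_emb) || !nrow(random_emb))
    stop("both embedding sets must be non-empty")
  x <- rbind(concept_emb, random_emb)
  y <- factor(rep(c("concept", "random"), c(nrow(concept_emb),
                                            nrow(random_emb))))
  if (identical(dim(concept_emb), dim(random_emb)) &&
      all(concept_emb == random_emb))
    stop("degenerate embeddings: concept and random sets are identical")
  # condition by a single global factor: with raw activations of large
  # scale, C = 1 degenerates into a hard margin and single contaminated
  # counterexamples can rotate the boundary; a scalar factor restores a
  # calibrated soft margin without reweighting the embedding geometry
  # (per-dimension standardization would)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) s <- 1
  fit <- with_seed(seed, suppressWarnings(
    e1071::svm(x / s, y, kernel = "linear", cost = cost, scale = FALSE)))
  w <- drop(crossprod(fit$coefs, fit$SV)) / s
  if (sqrt(sum(w^2)) < 1e-12)
    stop("degenerate CAV: zero-norm separating direction")
  # orient toward the concept side
  if (mean(concept_emb %*% w) < mean(random_emb %*% w)) w <- -w
  v <- w / sqrt(sum(w^2))
  acc <- mean(predict(fit, x / s) == y)
  structure(list(v = v, train_accuracy = acc, layer = "fc16"), class = "cav")
}

#' Concept sensitivity of one input
#'
#' The directional derivative: dot product of a class-logit gradient row
#' with the CAV. Only its sign is consumed downstream.
#'
#' @param gradient_row numeric vector (a row of [class_gradient()]).
#' @param cav a `cav` or a plain numeric vector.
#' @return signed scalar.
#' @export
cav_sensitivity <- function(gradient_row, cav) {
  v <- if (inherits(cav, "cav")) cav$v else cav
  if (length(gradient_row) != length(v))
    stop("gradient and CAV dimensions differ")
  sum(gradient_row * v)
}

#' TCAV score from a list of sensitivities
#'
#' Fraction of inputs with strictly positive sensitivity; zeros count as
#' non-positive.
#'
#' @param sensitivities numeric vector (non-empty).
#' @return fraction in `[0, 1]`.
#' @export
tcav_score <- function(sensitivities) {
  if (!length(sensitivities)) stop("empty sensitivity list")
  mean(sensitivities > 0)
}

# Welch t-test that tolerates (near-)constant inputs
safe_welch_p <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
}

#' Run TCAV over repeated CAV trainings
#'
#' Per run: a fresh set of random counterexamples is drawn and a CAV is
#' trained per concept; the TCAV score of every (concept, class) pair is
#' computed over the class-k evaluation tiles; a null score comes from a
#' random-vs-random CAV on the same tiles. Scores are summarized as mean
#' and sample standard deviation over runs, and each concept is tested
#' against the null scores with a two-sided Welch t-test
#' (significant iff p < `alpha`). No multiple-testing correction is
#' applied across concept-class pairs.
#'
#' @param model a `histocnn` or `histocnn_fit`.
#' @param concepts an `ace_concepts`.
#' @param eval_tiles evaluation tiles (typically the test split); scores
#'   for class k use the class-k tiles, capped at `eval_cap`.
#' @param classes classes to score (default both).
#' @param runs number of repeated runs (>= 2 for p-values; 100 reproduces
#'   the full protocol, 20 is the reduced configuration).
#' @param alpha significance level (default 0.01).
#' @param n_random random counterexamples per run (default 40).
#' @param eval_cap cap on evaluation tiles per class.
#' @param seed master seed; per-run seeds derive from it.
#' @return a `tcav_result` tibble: one row per (concept, class) with
#'   `mean`, `std`, `p_value`, `significant`, `runs`; per-run score
#'   matrices in `attr(, "scores")`, null scores in `attr(, "null")`.
#' @export
run_tcav <- function(model, concepts, eval_tiles,
                     classes = c("positive", "negative"), runs = 20,
                     alpha = 0.01, n_random = 40, eval_cap = 100, seed = 1) {
  if (inherits(model, "histocnn_fit")) model <- model$model
  if (!length(concepts$concepts)) stop("no concepts to score")
  if (runs < 1) stop("runs must be >= 1")
  pool <- concepts$pool
  emb <- concepts$embeddings
  # gradient rows per class over capped evaluation tiles (run-independent)
  grads <- list()
  for (k in classes) {
    tk <- eval_tiles[tile_labels(eval_tiles) == k]
    if (!length(tk)) stop("no evaluation tiles of class ", k)
    if (length(tk) > eval_cap) {
      idx <- with_seed(derive_seed(seed, 13L, match(k, classes)),
                       sample(length(tk), eval_cap))
      tk <- tk[idx]
    }
    grads[[k]] <- class_gradient(model, "fc16", k, tk, target = "margin")
  }
  nc <- length(concepts$concepts)
  scores <- array(NA_real_, c(runs, nc, length(classes)),
                  dimnames = list(NULL, NULL, classes))
  null_scores <- matrix(NA_real_, runs, length(classes),
                        dimnames = list(NULL, classes))
  cav_acc <- matrix(NA_real_, runs, nc)
  for (r in seq_len(runs)) {
    rs <- derive_seed(seed, 17L, r)
    rnd_idx <- sample_random_counterexamples(pool, n_random, rs)
    rnd_emb <- emb[rnd_idx, , drop = FALSE]
    # second, disjoint random draw for the null CAV
    rest <- setdiff(seq_len(nrow(emb)), rnd_idx)
    rnd2_idx <- rest[with_seed(derive_seed(rs, 2L),
                               sample.int(length(rest), n_random))]
    for (ci in seq_len(nc)) {
      co <- concepts$concepts[[ci]]
      cav <- train_cav(emb[co$patch_idx, , drop = FALSE], rnd_emb,
                       seed = derive_seed(rs, ci))
      cav_acc[r, ci] <- cav$train_accuracy
      for (k in classes)
        scores[r, ci, k] <- tcav_score(grads[[k]] %*% cav$v)
    }
    null_cav <- tryCatch(
      train_cav(emb[rnd2_idx, , drop = FALSE], rnd_emb,
                seed = derive_seed(rs, 999L)),
      error = function(e) NULL)
    for (k in classes)
      null_scores[r, k] <- if (is.null(null_cav)) 0.5
        else tcav_score(grads[[k]] %*% null_cav$v)
  }
  rows <- list()
  for (ci in seq_len(nc)) {
    for (k in classes) {
      sc <- scores[, ci, k]
      p <- safe_welch_p(sc, null_scores[, k])
      rows[[length(rows) + 1]] <- tibble::tibble(
        concept_id = concepts$concepts[[ci]]$id, class = k,
        mean = mean(sc), std = stats::sd(sc),
        p_value = p, significant = !is.na(p) && p < alpha, runs = runs)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scores") <- scores
  attr(out, "null") <- null_scores
  attr(out, "cav_accuracy") <- cav_acc
  attr(out, "alpha") <- alpha
  class(out) <- c("tcav_result", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.tcav_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.tcav_result <- function(x, ...) {
  tibble::tibble(n_concepts = length(unique(x$concept_id)),
                 n_significant = sum(x$significant),
                 runs = x$runs[1], alpha = attr(x, "alpha"))
}

#' Bar chart of TCAV scores
#'
#' Grouped bars of mean TCAVQ per (concept, class) with standard
#' deviation whiskers; significant concepts are marked with an asterisk.
#'
#' @param object a `tcav_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tcav_result <- function(object, ...) {
  df <- tidy(object)
  df$concept <- factor(paste("concept", df$concept_id))
  df$star <- ifelse(df$significant, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concept, y = .data$mean,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$std),
                   ymax = pmin(1, .data$mean + .data$std)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25,
      color = "black") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$star,
                   y = pmin(1, .data$mean + .data$std) + 0.03),
      position = ggplot2::position_dodge(width = 0.8), size = 6) +
    ggplot2::scale_y_continuous(limits = c(0, 1.1),
                                breaks = seq(0, 1, 0.25)) +
    ggplot2::labs(y = "mean TCAVQ", x = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Write the TCAV bar chart to a PNG
#'
#' @param results a `tcav_result`.
#' @param path output PNG path.
#' @param width,height,dpi figure geometry.
#' @return invisibly, `path`.
#' @export
plot_scores <- function(results, path, width = 7, height = 4, dpi = 120) {
  p <- autoplot.tcav_result(results)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = dpi)
  invisible(path)
}
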