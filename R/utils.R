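#' @useDynLib histobias, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats plogis rnorm runif rpois kmeans t.test chisq.test predict
#' @importFrom grDevices rgb2hsv hsv col2rgb
#' @importFrom rlang %||% .data
#' @import tibble
NULL

# Deterministic 31-bit seed derivation: mixes a master seed with integer
# stream ids so every randomized stage gets an independent, reproducible seed.
derive_seed <- function(seed, ...) {
  ids <- c(seed, ...)
  h <- 0
  # two mixing rounds per id; all intermediates stay below 2^53 so the
  # arithmetic is exact in doubles
  for (v in ids) {
    h <- (h * 8191 + as.numeric(v) %% 2147483647 + 999331) %% 2147483629
    h <- (h * 127 + 20261) %% 2147483629
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Stack tiles into a normalized image batch
#'
#' Converts a list of tiles (or raw pixel arrays) into the 4-D array
#' `(H, W, 3, N)` of values in `[0, 1]` that the network consumes.
#'
#' @param tiles list of tile objects (see [generate_tile()]) or of
#'   `H x W x 3` pixel arrays with values in 0--255.
#' @return numeric array of dimension `(H, W, 3, N)`.
#' @export
tiles_to_batch <- function(tiles) {
  px <- lapply(tiles, function(t) if (is.list(t)) t$pixels else t)
  d <- dim(px[[1]])
  out <- array(0, c(d[1], d[2], d[3], length(px)))
  for (i in seq_along(px)) out[, , , i] <- px[[i]]
  out / 255
}

tile_labels <- function(tiles) vapply(tiles, function(t) t$label, character(1))

# fraction of pixels with all channels >= 240 (the near-white rule)
near_white_fraction <- function(pixels) {
  mean(pixels[, , 1] >= 240 & pixels[, , 2] >= 240 & pixels[, , 3] >= 240)
}
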