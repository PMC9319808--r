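#' Synthetic histology-like tile generation with plantable biases
#'
#' The generator emulates the statistical structure of H&E-stained skin
#' biopsy tiles used for binary cancerous/non-cancerous patch
#' classification: a pinkish stroma texture, dark elliptical nuclei whose
#' density and size separate the two classes, an optional wavy collagen
#' band (standing for reticular dermis), an optional near-white background
#' region, and two acquisition "sources" that differ by a global
#' brightness/contrast regime. Tiles are grouped into virtual slides so
#' datasets can be split slide-disjointly.
#'
#' @name synthgen
NULL

.valid_strata <- c("nuclei_dense", "nuclei_sparse", "collagen", "background")

# reference stroma color (eosin pink); also the fixed reference means used
# by the default source-B affine shift
.stroma_base <- c(214, 168, 194)
.nucleus_base <- c(72, 52, 118)

#' Tile generator parameters
#'
#' Defaults define the study conditions: nucleus density and size are the
#' class-separating signal (a positive tile has roughly twice the nuclei
#' of a negative tile and larger nuclei), with multiplicative per-slide
#' variation so that slides differ in overall cellularity and stain tone.
#'
#' @param density_dense,density_sparse expected nucleus count per 96x96
#'   tile for the dense (positive-class) and sparse (negative-class)
#'   strata; counts scale with tile area.
#' @param radius_positive,radius_negative mean nucleus radius in pixels at
#'   96 px tile size; radii scale linearly with tile size.
#' @param slide_sd standard deviation (log scale) of the per-slide
#'   cellularity multiplier.
#' @param texture_amplitude amplitude (0--255) of the low-frequency stroma
#'   texture noise.
#' @return list of generator parameters.
#' @export
tile_params <- function(density_dense = 26, density_sparse = 18,
                        radius_positive = 3.1, radius_negative = 2.7,
                        slide_sd = 0.35, texture_amplitude = 12) {
  list(density_dense = density_dense, density_sparse = density_sparse,
       radius_positive = radius_positive, radius_negative = radius_negative,
       slide_sd = slide_sd, texture_amplitude = texture_amplitude)
}

# slide-level deterministic appearance: cellularity multiplier and a small
# per-channel stain tone offset, both functions of slide_id alone
slide_effects <- function(slide_id, params) {
  u <- with_seed(derive_seed(987654L, slide_id), runif(4))
  list(cellularity = exp(params$slide_sd * stats::qnorm(u[1])),
       tone = round((u[2:4] - 0.5) * 16))
}

# low-frequency smooth noise field in [-1, 1]
smooth_noise <- function(h, w, grid = 10) {
  g <- matrix(runif(grid * grid, -1, 1), grid, grid)
  m <- resize_bilinear(as.numeric(g), grid, grid, 1L, as.integer(h), as.integer(w))
  array(m, c(h, w))
}

# draw soft-edged ellipses; returns list(img = updated, mask = logical)
draw_nuclei <- function(img, n, r_mean, color) {
  h <- dim(img)[1]; w <- dim(img)[2]
  mask <- matrix(FALSE, h, w)
  if (n <= 0) return(list(img = img, mask = mask))
  for (i in seq_len(n)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    ry <- r_mean * runif(1, 0.75, 1.25)
    rx <- ry * runif(1, 0.6, 1.0)
    th <- runif(1, 0, pi)
    col_i <- clip255(color + round(runif(3, -14, 14)))
    # work only inside the ellipse's bounding window
    r <- ceiling(max(rx, ry) * 1.3) + 1
    hr <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
    wr <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
    xs <- matrix(rep(wr, each = length(hr)), length(hr))
    ys <- matrix(rep(hr, length(wr)), length(hr))
    dx <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    dy <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    d2 <- (dx / rx)^2 + (dy / ry)^2
    alpha <- clip01(1.4 - d2)          # soft edge
    mask[hr, wr] <- mask[hr, wr] | d2 <= 1
    for (c in 1:3)
      img[hr, wr, c] <- img[hr, wr, c] * (1 - alpha) + col_i[c] * alpha
  }
  list(img = img, mask = mask)
}

# wavy pale fiber band standing for reticular-dermis collagen
draw_collagen <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  band_h <- round(h * runif(1, 0.25, 0.4))
  top <- round(runif(1, 0, h - band_h))
  ys <- matrix(rep(seq_len(h), w), h, w)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  freq <- runif(1, 0.25, 0.45)
  phase <- runif(1, 0, 2 * pi)
  wob <- runif(1, 2, 5)
  fiber <- sin(freq * ys + phase + wob * sin(0.08 * xs))
  region <- ys > top & ys <= top + band_h
  strands <- region & fiber > 0.15
  col <- c(236, 214, 226)
  for (c in 1:3)
    img[, , c] <- ifelse(strands, 0.35 * img[, , c] + 0.65 * col[c], img[, , c])
  list(img = img, mask = region)
}

# near-white background blob, capped well under the 10% white budget
draw_background <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  # ellipse hugging a random corner, ~6-8% of tile area
  corner <- sample(4, 1)
  cy <- if (corner %in% c(1, 2)) 1 else h
  cx <- if (corner %in% c(1, 3)) 1 else w
  r <- sqrt(0.07 * h * w / pi) * runif(1, 0.9, 1.1)
  d2 <- ((xs - cx) / (1.6 * r))^2 + ((ys - cy) / r)^2
  inside <- d2 <= 1
  for (c in 1:3)
    img[, , c] <- ifelse(inside, 248 + 4 * runif(h * w), img[, , c])
  list(img = img, mask = inside)
}

render_tile_once <- function(label, source, slide_id, strata, seed,
                             tile_size, params, shift) {
  with_seed(seed, {
    h <- tile_size; w <- tile_size
    eff <- slide_effects(slide_id, params)
    img <- array(0, c(h, w, 3))
    base <- clip255(.stroma_base + eff$tone)
    amp <- params$texture_amplitude
    for (c in 1:3) img[, , c] <- base[c] + amp * smooth_noise(h, w) +
      rnorm(h * w, 0, 3)
    masks <- list()
    if ("collagen" %in% strata) {
      cg <- draw_collagen(img); img <- cg$img; masks$collagen <- cg$mask
    }
    if ("background" %in% strata) {
      bg <- draw_background(img); img <- bg$img; masks$background <- bg$mask
    }
    area_scale <- (tile_size / 96)^2
    lambda <- if ("nuclei_dense" %in% strata) params$density_dense
      else if ("nuclei_sparse" %in% strata) params$density_sparse else 8
    n_nuc <- rpois(1, lambda * area_scale * eff$cellularity)
    r_mean <- (if (label == "positive") params$radius_positive
               else params$radius_negative) * tile_size / 96
    nc <- draw_nuclei(img, n_nuc, r_mean, .nucleus_base)
    img <- nc$img; masks$nuclei <- nc$mask
    img <- clip255(round(img))
    if (source == "B") img <- shift_pixels(img, shift)
    storage.mode(img) <- "integer"
    list(pixels = img, masks = masks, n_nuclei = n_nuc)
  })
}

#' Generate one synthetic histology-like tile
#'
#' Deterministic given `seed`: calling twice with identical arguments
#' yields byte-identical pixels. Positive-class tiles have denser, larger
#' nuclei than negative-class tiles under the default [tile_params()];
#' source "B" tiles carry a global brightness/contrast shift relative to
#' source "A". Tiles whose near-white fraction would exceed 10% are
#' re-rendered (fresh sub-seed) and an all-background tile is rejected.
#'
#' @param label `"positive"` or `"negative"`.
#' @param source acquisition regime, `"A"` or `"B"`.
#' @param slide_id integer virtual-slide id; slide-level cellularity and
#'   stain tone are deterministic functions of it.
#' @param strata character vector of tissue-texture tags; subset of
#'   `nuclei_dense`, `nuclei_sparse`, `collagen`, `background`.
#' @param seed integer RNG seed for this tile.
#' @param tile_size tile side in pixels (default 96; use 256 for
#'   full-fidelity runs).
#' @param params generator parameters, see [tile_params()].
#' @param shift source-B appearance shift, see [source_shift()].
#' @return a `histo_tile`: list with integer `pixels` (`H x W x 3`,
#'   0--255), `label`, `source`, `slide_id`, `has_marker`, `strata`, and
#'   ground-truth `masks` (nuclei, collagen, background).
#' @export
generate_tile <- function(label = c("positive", "negative"),
                          source = c("A", "B"), slide_id = 1L,
                          strata = "nuclei_dense", seed,
                          tile_size = 96, params = tile_params(),
                          shift = source_shift()) {
  label <- match.arg(label); source <- match.arg(source)
  if (missing(seed)) stop("`seed` is required for reproducible tiles")
  if (length(strata) == 0) stop("`strata` must be non-empty")
  bad <- setdiff(strata, .valid_strata)
  if (length(bad))
    stop("unknown stratum tag(s): ", paste(bad, collapse = ", "))
  if (identical(sort(strata), "background"))
    stop("all-background tile rejected: near-white fraction would exceed 0.10")
  for (attempt in 0:19) {
    r <- render_tile_once(label, source, slide_id, strata,
                          derive_seed(seed, attempt), tile_size, params, shift)
    if (near_white_fraction(r$pixels) <= 0.10) {
      tile <- list(pixels = r$pixels, label = label, source = source,
                   slide_id = as.integer(slide_id), has_marker = FALSE,
                   strata = strata, masks = r$masks, seed = as.integer(seed))
      class(tile) <- "histo_tile"
      return(tile)
    }
  }
  stop("could not render a tile with near-white fraction <= 0.10")
}

#' @export
print.histo_tile <- function(x, ...) {
  cat(sprintf("<histo_tile %dx%d %s source %s slide %d%s strata: %s>\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$label, x$source,
              x$slide_id, if (x$has_marker) " [marker]" else "",
              paste(x$strata, collapse = ",")))
  invisible(x)
}

#' Default marker geometry for a tile size
#'
#' A small red square in the upper-left corner: side `round(size/12)`,
#' offset `round(size/24)` from the top-left, color RGB (255, 0, 0).
#'
#' @param tile_size tile side in pixels.
#' @param size,offset,color override side length, top-left offset
#'   (row, col), and RGB color.
#' @return list with `size`, `offset`, `color`.
#' @export
marker_spec <- function(tile_size = 96, size = NULL, offset = NULL,
                        color = c(255L, 0L, 0L)) {
  list(size = size %||% round(tile_size / 12),
       offset = offset %||% rep(round(tile_size / 24), 2),
       color = as.integer(color))
}

#' Plant the class-correlated marker on a tile
#'
#' Sets the marker rectangle to exactly the marker color and leaves every
#' other pixel untouched. With `size = 0` the tile is returned unchanged
#' (and `has_marker` stays `FALSE`).
#'
#' @param tile a `histo_tile` (must be positive class).
#' @param marker marker geometry, see [marker_spec()].
#' @return the tile with the marker drawn and `has_marker = TRUE`.
#' @export
inject_marker <- function(tile, marker = marker_spec(dim(tile$pixels)[1])) {
  if (tile$label != "positive")
    stop("the class-correlated marker is planted on positive tiles only")
  if (marker$size == 0) return(tile)
  h <- dim(tile$pixels)[1]; w <- dim(tile$pixels)[2]
  rows <- marker$offset[1] + seq_len(marker$size)   # 0-based offset, 1-based idx
  cols <- marker$offset[2] + seq_len(marker$size)
  if (max(rows) > h || max(cols) > w || min(rows) < 1 || min(cols) < 1)
    stop("marker rectangle lies outside the tile")
  for (c in 1:3) tile$pixels[rows, cols, c] <- marker$color[c]
  tile$has_marker <- TRUE
  tile$marker_rows <- range(rows)
  tile$marker_cols <- range(cols)
  tile
}

# logical mask of the marker region for a tile (all FALSE when no marker)
marker_region_mask <- function(tile) {
  h <- dim(tile$pixels)[1]; w <- dim(tile$pixels)[2]
  m <- matrix(FALSE, h, w)
  if (isTRUE(tile$has_marker)) {
    m[tile$marker_rows[1]:tile$marker_rows[2],
      tile$marker_cols[1]:tile$marker_cols[2]] <- TRUE
  }
  m
}

#' Source-B appearance shift
#'
#' Per-channel affine map `p' = gain * p + offset`, applied uniformly to
#' every pixel. The default emulates a second scanner/stain regime whose
#' images are 12% brighter with 30% less per-channel variation: values are
#' contracted toward fixed reference channel means and then brightened.
#'
#' @param gain,offset numeric length-3 per-channel gain and offset;
#'   defaults derive from brightness factor 1.12 and contraction 0.7
#'   around the generator's reference stroma color.
#' @return list with `gain` and `offset`.
#' @export
source_shift <- function(gain = NULL, offset = NULL) {
  if (is.null(gain)) gain <- rep(0.7 * 1.12, 3)
  if (is.null(offset)) offset <- 1.12 * 0.3 * .stroma_base
  list(gain = gain, offset = offset)
}

shift_pixels <- function(pixels, shift) {
  out <- pixels
  for (c in 1:3)
    out[, , c] <- clip255(round(shift$gain[c] * pixels[, , c] + shift$offset[c]))
  storage.mode(out) <- "integer"
  out
}

#' Apply a source appearance shift to a tile
#'
#' @param tile a `histo_tile` or an `H x W x 3` pixel array.
#' @param shift shift parameters, see [source_shift()]. The identity is
#'   `source_shift(gain = rep(1, 3), offset = rep(0, 3))`.
#' @return object of the same type with shifted, clipped pixels.
#' @export
apply_source_shift <- function(tile, shift = source_shift()) {
  if (is.list(tile)) {
    tile$pixels <- shift_pixels(tile$pixels, shift)
    tile
  } else {
    shift_pixels(tile, shift)
  }
}
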