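#' Bias configuration for dataset construction
#'
#' @param kind one of `"none"`, `"class_ratio"`, `"measurement"`,
#'   `"sampling"`, `"class_correlated"`.
#' @param ratio_reduction for `class_ratio`: probability of rejecting a
#'   positive tile from the training pool (default 0.5, which yields an
#'   approximately 2:1 negative:positive training ratio).
#' @param excluded_stratum for `sampling`: texture tag excluded from
#'   negative-class training tiles (default `"collagen"`, standing for
#'   reticular dermis).
#' @param marker for `class_correlated`: marker geometry
#'   (see [marker_spec()]); defaults to the tile-size default.
#' @param shift for `measurement`: source-B appearance shift
#'   (see [source_shift()]).
#' @return a `bias_config` list.
#' @export
bias_config <- function(kind = c("none", "class_ratio", "measurement",
                                 "sampling", "class_correlated"),
                        ratio_reduction = 0.5,
                        excluded_stratum = "collagen",
                        marker = NULL, shift = source_shift()) {
  kind <- match.arg(kind)
  if (ratio_reduction < 0 || ratio_reduction >= 1)
    stop("ratio_reduction must lie in [0, 1)")
  if (!excluded_stratum %in% c("collagen", "background"))
    stop("excluded_stratum must be an optional stratum (collagen or background)")
  structure(list(kind = kind, ratio_reduction = ratio_reduction,
                 excluded_stratum = excluded_stratum, marker = marker,
                 shift = shift),
            class = "bias_config")
}

# sample the strata tag set for one tile
sample_strata <- function(label, exclude = NULL) {
  s <- if (label == "positive") "nuclei_dense" else "nuclei_sparse"
  p_collagen <- if (label == "positive") 0.10 else 0.50
  if (runif(1) < p_collagen) s <- c(s, "collagen")
  if (runif(1) < 0.15) s <- c(s, "background")
  setdiff(s, exclude)
}

split_slides <- function(n_slides) {
  n_train <- round(n_slides * 2 / 3)
  n_val <- max(1L, round(n_slides / 6))
  n_test <- n_slides - n_train - n_val
  if (n_test < 1) { n_train <- n_train - 1L; n_test <- n_test + 1L }
  rep(c("train", "val", "test"), c(n_train, n_val, n_test))
}

#' Build a slide-grouped synthetic dataset with a planted bias
#'
#' Generates `n_slides * tiles_per_slide` tiles, partitions slides
#' (not tiles) into train/validation/test at approximately
#' 66.67/16.67/16.67 percent, and applies the configured bias:
#'
#' * `none` - labels are balanced and independent of source and marker.
#' * `class_ratio` - positive tiles are admitted to the training pool with
#'   probability `1 - ratio_reduction`; validation/test untouched.
#' * `measurement` - label is perfectly confounded with source in every
#'   split (positive slides from source A, negative from source B), with
#'   no appearance normalization.
#' * `sampling` - negative-class training tiles never contain the excluded
#'   stratum; validation/test retain it.
#' * `class_correlated` - the red corner marker is planted on every
#'   positive tile in all splits.
#'
#' @param bias a [bias_config()].
#' @param n_slides number of virtual slides (>= 6 so all splits are
#'   non-empty).
#' @param tiles_per_slide tiles sampled per slide.
#' @param seed master seed; the whole dataset is a deterministic function
#'   of `(bias, n_slides, tiles_per_slide, seed, tile_size)`.
#' @param tile_size tile side in pixels.
#' @param params generator parameters, see [tile_params()].
#' @return a `tile_dataset`: list with `train`, `val`, `test` (lists of
#'   tiles), and `manifest`, a tibble with one row per tile
#'   (`path, label, source, slide_id, split, has_marker, strata`).
#' @export
build_dataset <- function(bias = bias_config("none"), n_slides = 30,
                          tiles_per_slide = 40, seed = 1, tile_size = 96,
                          params = tile_params()) {
  stopifnot(inherits(bias, "bias_config"))
  if (n_slides < 6) stop("need n_slides >= 6 so all splits are non-empty")
  kind <- bias$kind
  with_seed(derive_seed(seed, 1L), {
    split <- split_slides(n_slides)[sample(n_slides)]
    # slide-level class (measurement only) and source assignment
    slide_label <- slide_source <- character(n_slides)
    for (sp in unique(split)) {
      idx <- which(split == sp)
      lab <- rep(c("positive", "negative"), length.out = length(idx))
      slide_label[idx] <- sample(lab)
    }
    if (kind == "measurement") {
      slide_source <- ifelse(slide_label == "positive", "A", "B")
    } else {
      for (sp in unique(split)) {
        idx <- which(split == sp)
        slide_source[idx] <- sample(rep(c("A", "B"), length.out = length(idx)))
      }
    }
  })
  tiles <- list(); rows <- list(); n <- 0
  for (s in seq_len(n_slides)) {
    for (t in seq_len(tiles_per_slide)) {
      tseed <- derive_seed(seed, s, t)
      info <- with_seed(derive_seed(tseed, 2L), {
        label <- if (kind == "measurement") slide_label[s]
          else sample(c("positive", "negative"), 1)
        exclude <- if (kind == "sampling" && split[s] == "train" &&
                       label == "negative") bias$excluded_stratum
        keep <- !(kind == "class_ratio" && split[s] == "train" &&
                    label == "positive" && runif(1) < bias$ratio_reduction)
        list(label = label, strata = sample_strata(label, exclude), keep = keep)
      })
      if (!info$keep) next
      tile <- generate_tile(info$label, slide_source[s], s, info$strata,
                            seed = tseed, tile_size = tile_size,
                            params = params, shift = bias$shift)
      if (kind == "class_correlated" && info$label == "positive")
        tile <- inject_marker(tile, bias$marker %||% marker_spec(tile_size))
      n <- n + 1
      tile$split <- split[s]
      tiles[[n]] <- tile
      rows[[n]] <- tibble::tibble(
        path = sprintf("tiles/s%03d_t%03d.png", s, t),
        label = info$label, source = slide_source[s], slide_id = s,
        split = split[s], has_marker = tile$has_marker,
        strata = paste(sort(tile$strata), collapse = ";"))
    }
  }
  manifest <- dplyr::bind_rows(rows)
  ds <- list(train = tiles[manifest$split == "train"],
             val = tiles[manifest$split == "val"],
             test = tiles[manifest$split == "test"],
             manifest = manifest, bias = bias, seed = seed,
             tile_size = tile_size)
  class(ds) <- "tile_dataset"
  ds
}

#' @export
print.tile_dataset <- function(x, ...) {
  cat(sprintf("<tile_dataset bias=%s %d/%d/%d tiles (train/val/test), %d px>\n",
              x$bias$kind, length(x$train), length(x$val), length(x$test),
              x$tile_size))
  invisible(x)
}

#' Write a dataset to disk as PNG tiles plus a CSV manifest
#'
#' @param ds a `tile_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest with paths relative to `dir`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  for (sp in c("train", "val", "test")) {
    rows <- which(ds$manifest$split == sp)
    tiles <- ds[[sp]]
    for (j in seq_along(rows))
      png::writePNG(tiles[[j]]$pixels / 255,
                    file.path(dir, ds$manifest$path[rows[j]]))
  }
  utils::write.csv(ds$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(ds$manifest)
}
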