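#' Automated concept extraction (superpixels + activation clustering)
#'
#' Concepts are proposed by multi-resolution SLIC-zero superpixel
#' segmentation of evaluation tiles, rendered each on a grey-127 canvas at
#' their original location and scale (no resize or crop -- patch size is
#' treated as informative), embedded at the network's fully connected
#' layer, clustered with k-means, and filtered.
#'
#' @name ace
NULL

#' SLIC segment counts for a tile size
#'
#' The three segmentation resolutions use 15/50/80 segments at 256 px and
#' scale with `(tile_size/256)^2` (rounded up, minimum 4) so that segment
#' area is preserved at smaller tile sizes.
#'
#' @param tile_size tile side in pixels.
#' @return integer vector of three segment counts (coarse, mid, fine).
#' @export
slic_levels <- function(tile_size) {
  pmax(4L, as.integer(ceiling(c(15, 50, 80) * (tile_size / 256)^2)))
}

#' Segment a tile into superpixels
#'
#' SLIC-zero (adaptive compactness) segmentation. Masks partition the
#' tile; segments smaller than `min_pixels` are merged by the
#' connectivity pass or dropped.
#'
#' @param tile a `histo_tile` or `H x W x 3` pixel array (0--255).
#' @param n_segments requested number of segments (>= 2); the realized
#'   count is approximate.
#' @param min_pixels minimum segment size; default 0.5% of the tile area.
#' @return list of logical `H x W` masks. For a constant (degenerate)
#'   image a single full mask is returned with attribute
#'   `degenerate = TRUE`.
#' @export
segment_tile <- function(tile, n_segments, min_pixels = NULL) {
  if (n_segments < 2) stop("n_segments must be >= 2")
  px <- if (is.list(tile)) tile$pixels else tile
  h <- dim(px)[1]; w <- dim(px)[2]
  min_pixels <- min_pixels %||% max(1L, round(0.005 * h * w))
  if (length(unique(as.vector(px))) == 1L) {
    m <- list(matrix(TRUE, h, w))
    attr(m, "degenerate") <- TRUE
    return(m)
  }
  lab <- slic_cpp(as.numeric(px) / 255, h, w, as.integer(n_segments),
                  10L, as.integer(max(4, (h * w / n_segments) / 4)))
  ids <- sort(unique(as.vector(lab)))
  masks <- lapply(ids, function(i) lab == i)
  masks[vapply(masks, sum, numeric(1)) >= min_pixels]
}

#' Render a segment as a concept-patch canvas
#'
#' Keeps the segment's pixels at their original location and scale and
#' fills everything off-mask with greyscale value 127 (the same fill the
#' network saw during cutout augmentation, so grey regions are
#' class-neutral).
#'
#' @param tile a `histo_tile` or pixel array.
#' @param mask logical `H x W` segment mask (non-empty).
#' @return integer `H x W x 3` canvas array.
#' @export
make_patch <- function(tile, mask) {
  px <- if (is.list(tile)) tile$pixels else tile
  if (!any(mask)) stop("mask must be non-empty")
  canvas <- array(127L, dim(px))
  for (c in 1:3) {
    ch <- canvas[, , c]; src <- px[, , c]
    ch[mask] <- src[mask]
    canvas[, , c] <- ch
  }
  canvas
}

#' Propose concept patches from a set of tiles
#'
#' Pools SLIC segments from all three resolutions over all tiles.
#' Canvases are not materialized here (only masks and provenance);
#' [embed_patches()] builds them on the fly.
#'
#' @param tiles list of tiles.
#' @param levels segment counts per resolution; default
#'   [slic_levels()] for the tile size.
#' @return a `patch_pool`: list with `patches` (list of
#'   `list(tile, level, mask)`) and `tiles` (the source tiles).
#' @export
propose_patches <- function(tiles, levels = NULL) {
  ts <- dim(tiles[[1]]$pixels)[1]
  levels <- levels %||% slic_levels(ts)
  patches <- list()
  for (i in seq_along(tiles)) {
    for (li in seq_along(levels)) {
      masks <- segment_tile(tiles[[i]], levels[li])
      for (m in masks)
        patches[[length(patches) + 1]] <-
          list(tile = i, level = c("coarse", "mid", "fine")[li], mask = m)
    }
  }
  structure(list(patches = patches, tiles = tiles), class = "patch_pool")
}

#' @export
print.patch_pool <- function(x, ...) {
  cat(sprintf("<patch_pool %d segments from %d tiles>\n",
              length(x$patches), length(x$tiles)))
  invisible(x)
}

#' Embed concept patches at a network layer
#'
#' Renders each patch canvas (grey-127 off-mask), scales to `[0, 1]` and
#' runs the network up to `layer`. The fully connected layer is the
#' default: after global pooling its embedding is insensitive to the
#' patch's location in the canvas, which convolutional feature maps are
#' not.
#'
#' @param pool a `patch_pool`, or a list of canvases.
#' @param model a `histocnn` or `histocnn_fit`.
#' @param layer layer name (default `"fc16"`).
#' @param batch_size forward batch size.
#' @return numeric matrix, one embedding row per patch.
#' @export
embed_patches <- function(pool, model, layer = "fc16", batch_size = 64) {
  if (inherits(model, "histocnn_fit")) model <- model$model
  canvases <- if (inherits(pool, "patch_pool")) NULL else pool
  n <- if (is.null(canvases)) length(pool$patches) else length(canvases)
  rows <- list()
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    batch <- lapply(s:e, function(i) {
      if (is.null(canvases))
        make_patch(pool$tiles[[pool$patches[[i]]$tile]], pool$patches[[i]]$mask)
      else canvases[[i]]
    })
    rows[[length(rows) + 1]] <-
      activations(model, layer, tiles_to_batch(batch), batch_size = batch_size)
  }
  do.call(rbind, rows)
}

# k-means++ seeding
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  ci <- sample.int(n, 1)
  centers[1, ] <- x[ci, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    pr <- d2 / sum(d2)
    ci <- if (all(d2 == 0)) sample.int(n, 1) else sample.int(n, 1, prob = pr)
    centers[j, ] <- x[ci, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster patch embeddings with k-means
#'
#' k-means with k-means++ initialization under a fixed seed.
#'
#' @param embeddings numeric matrix (patches x features).
#' @param k number of clusters (>= 1; must not exceed the number of
#'   rows).
#' @param seed RNG seed.
#' @return list with `labels` (integer vector) and `centers`
#'   (`k x d` matrix).
#' @export
cluster_concepts <- function(embeddings, k, seed = 1) {
  if (k > nrow(embeddings)) stop("k exceeds the number of embeddings")
  if (k == 1) {
    return(list(labels = rep(1L, nrow(embeddings)),
                centers = matrix(colMeans(embeddings), 1)))
  }
  with_seed(derive_seed(seed, 5L), {
    init <- kmeanspp_centers(embeddings, k)
    km <- suppressWarnings(stats::kmeans(embeddings, centers = init,
                                         iter.max = 100))
    list(labels = km$cluster, centers = km$centers)
  })
}

#' Select and filter concepts from clusters
#'
#' Keeps, per surviving cluster, the `n` members closest (l2) to the
#' cluster center, ties broken by patch index. Clusters with fewer than
#' `min_members` members in total, or drawing from fewer than `min_tiles`
#' distinct source tiles, are discarded.
#'
#' @param clusters result of [cluster_concepts()].
#' @param embeddings the embedding matrix that was clustered.
#' @param pool the `patch_pool` the embeddings came from.
#' @param n maximum patches per concept (default 40).
#' @param min_members,min_tiles filtering thresholds.
#' @return an `ace_concepts` object: list of concepts (each with `id`,
#'   `patch_idx` ordered by distance, `center`, `n_members_total`,
#'   `source_tiles`), plus the pool and embeddings. Empty (with a
#'   warning) if every cluster is filtered out.
#' @export
select_concepts <- function(clusters, embeddings, pool, n = 40,
                            min_members = 20, min_tiles = 5) {
  concepts <- list()
  for (cid in seq_len(nrow(clusters$centers))) {
    members <- which(clusters$labels == cid)
    if (length(members) < min_members) next
    tiles_of <- vapply(members, function(i) pool$patches[[i]]$tile, numeric(1))
    if (length(unique(tiles_of)) < min_tiles) next
    ctr <- clusters$centers[cid, ]
    d <- sqrt(rowSums((embeddings[members, , drop = FALSE] -
                         matrix(ctr, length(members), length(ctr),
                                byrow = TRUE))^2))
    ord <- order(d, members)
    keep <- members[ord][seq_len(min(n, length(members)))]
    concepts[[length(concepts) + 1]] <-
      list(id = length(concepts) + 1, cluster = cid, patch_idx = keep,
           distances = sort(d)[seq_along(keep)], center = ctr,
           n_members_total = length(members),
           source_tiles = unique(tiles_of), target_layer = "fc16")
  }
  if (!length(concepts)) warning("all clusters were filtered out")
  structure(list(concepts = concepts, pool = pool, embeddings = embeddings),
            class = "ace_concepts")
}

#' @export
print.ace_concepts <- function(x, ...) {
  cat(sprintf("<ace_concepts %d concepts from %d segments>\n",
              length(x$concepts), nrow(x$embeddings)))
  for (co in x$concepts)
    cat(sprintf("  concept %d: %d/%d patches, %d source tiles\n", co$id,
                length(co$patch_idx), co$n_members_total,
                length(co$source_tiles)))
  invisible(x)
}

#' Run the full concept-extraction pipeline
#'
#' Multi-resolution SLIC proposal, FC-layer embedding, k-means
#' clustering, selection and filtering.
#'
#' @param model a `histocnn` or `histocnn_fit`.
#' @param tiles discovery tiles (typically the evaluation split).
#' @param k number of concept clusters (set per experiment; duplicate
#'   concepts suggest decreasing `k`, mixed concepts increasing it).
#' @param seed RNG seed.
#' @param layer embedding layer.
#' @param n,min_members,min_tiles see [select_concepts()].
#' @param max_tiles cap on the number of discovery tiles.
#' @return an `ace_concepts` object.
#' @export
ace_extract <- function(model, tiles, k = 5, seed = 1, layer = "fc16",
                        n = 40, min_members = 20, min_tiles = 5,
                        max_tiles = 60) {
  if (length(tiles) > max_tiles) {
    idx <- with_seed(derive_seed(seed, 11L), sample(length(tiles), max_tiles))
    tiles <- tiles[idx]
  }
  pool <- propose_patches(tiles)
  emb <- embed_patches(pool, model, layer = layer)
  cl <- cluster_concepts(emb, k, seed = seed)
  select_concepts(cl, emb, pool, n = n, min_members = min_members,
                  min_tiles = min_tiles)
}

#' Concept gallery contact sheet
#'
#' Writes one PNG per concept: its top patches (cropped to the mask
#' bounding box for display) arranged on a grid, plus a JSON index.
#'
#' @param concepts an `ace_concepts`.
#' @param dir output directory.
#' @param max_show patches shown per sheet.
#' @return invisibly, the paths written.
#' @export
write_concept_gallery <- function(concepts, dir, max_show = 20) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  index <- list()
  for (co in concepts$concepts) {
    shown <- co$patch_idx[seq_len(min(max_show, length(co$patch_idx)))]
    crops <- lapply(shown, function(i) {
      p <- concepts$pool$patches[[i]]
      canvas <- make_patch(concepts$pool$tiles[[p$tile]], p$mask)
      rr <- range(which(rowSums(p$mask) > 0))
      cc <- range(which(colSums(p$mask) > 0))
      canvas[rr[1]:rr[2], cc[1]:cc[2], , drop = FALSE]
    })
    side <- max(vapply(crops, function(x) max(dim(x)[1:2]), numeric(1)))
    ncol_g <- ceiling(sqrt(length(crops)))
    nrow_g <- ceiling(length(crops) / ncol_g)
    sheet <- array(127L, c(nrow_g * (side + 2), ncol_g * (side + 2), 3))
    for (i in seq_along(crops)) {
      r0 <- ((i - 1) %/% ncol_g) * (side + 2) + 1
      c0 <- ((i - 1) %% ncol_g) * (side + 2) + 1
      d <- dim(crops[[i]])
      sheet[r0:(r0 + d[1] - 1), c0:(c0 + d[2] - 1), ] <- crops[[i]]
    }
    path <- file.path(dir, sprintf("concept_%02d.png", co$id))
    png::writePNG(sheet / 255, path)
    paths <- c(paths, path)
    index[[length(index) + 1]] <-
      list(id = co$id, n_patches = length(co$patch_idx),
           n_members_total = co$n_members_total,
           source_tiles = co$source_tiles)
  }
  jsonlite::write_json(index, file.path(dir, "concepts.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
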