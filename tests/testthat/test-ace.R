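test_that("SLIC partitions the tile and meets the requested count approximately", {
  tile <- generate_tile("negative", "A", 1, c("nuclei_sparse", "collagen"),
                        seed = 2)
  for (n_req in c(4, 8, 12)) {
    masks <- segment_tile(tile, n_req, min_pixels = 1)
    # every pixel belongs to exactly one mask
    counts <- Reduce(`+`, lapply(masks, function(m) m + 0))
    expect_true(all(counts == 1))
    expect_gte(length(masks), ceiling(n_req * 0.6))
    expect_lte(length(masks), floor(n_req * 1.4))
  }
  expect_error(segment_tile(tile, 1), ">= 2")
})

test_that("a constant image degenerates to a single flagged segment", {
  flat <- array(100L, c(48, 48, 3))
  masks <- segment_tile(flat, 10)
  expect_length(masks, 1)
  expect_true(all(masks[[1]]))
  expect_true(isTRUE(attr(masks, "degenerate")))
})

test_that("SLIC isolates a salient disc", {
  # dark disc on a light background: at least one segment covers >= 50%
  # of the disc (checked against the constructed disc mask)
  img <- array(220L, c(96, 96, 3))
  xs <- matrix(rep(1:96, each = 96), 96)
  ys <- matrix(rep(1:96, 96), 96)
  disc <- (xs - 40)^2 + (ys - 56)^2 <= 14^2
  for (c in 1:3) { ch <- img[, , c]; ch[disc] <- 60L; img[, , c] <- ch }
  masks <- segment_tile(img, 15, min_pixels = 1)
  best <- max(vapply(masks, function(m) sum(m & disc) / sum(disc), numeric(1)))
  expect_gte(best, 0.5)
})

test_that("patch canvases keep segment pixels in place on grey 127", {
  tile <- generate_tile("positive", "A", 2, "nuclei_dense", seed = 9)
  full <- matrix(TRUE, 96, 96)
  expect_identical(make_patch(tile, full), tile$pixels)
  masks <- segment_tile(tile, 8)
  m <- masks[[1]]
  canvas <- make_patch(tile, m)
  for (c in 1:3) {
    expect_true(all(canvas[, , c][!m] == 127L))
    expect_identical(canvas[, , c][m], tile$pixels[, , c][m])
  }
  expect_error(make_patch(tile, matrix(FALSE, 96, 96)), "non-empty")
})

test_that("patch embeddings have one row per patch and duplicate in, duplicate out", {
  m <- build_model(96, seed = 5)
  tile <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 3)
  masks <- segment_tile(tile, 8)
  canvases <- lapply(masks[c(1, 2, 1)], function(mm) make_patch(tile, mm))
  emb <- embed_patches(canvases, m)
  expect_identical(dim(emb), c(3L, 16L))
  expect_equal(emb[1, ], emb[3, ], tolerance = 1e-10)
})

test_that("FC-layer embeddings are location invariant where conv maps are not", {
  # the same texture patch placed at two canvas locations: after global
  # pooling the FC embedding barely moves, while flattened conv features
  # change with position
  m <- build_model(96, seed = 6)
  tile <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 12)
  patch <- tile$pixels[25:48, 25:48, ]
  c1 <- array(127L, c(96, 96, 3)); c1[1:24, 1:24, ] <- patch
  c2 <- array(127L, c(96, 96, 3)); c2[61:84, 61:84, ] <- patch
  cos <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  fc <- activations(m, "fc16", list(c1, c2))
  conv <- activations(m, "stage3", list(c1, c2))
  cos_fc <- cos(fc[1, ], fc[2, ])
  cos_conv <- cos(as.numeric(conv[, , , 1]), as.numeric(conv[, , , 2]))
  expect_gt(cos_fc, cos_conv)
})

test_that("k-means recovers well-separated blobs and is deterministic", {
  set.seed(4)
  blob <- rbind(matrix(rnorm(60 * 16, mean = 0), ncol = 16),
                matrix(rnorm(60 * 16, mean = 10), ncol = 16))
  truth <- rep(1:2, each = 60)
  cl <- cluster_concepts(blob, 2, seed = 7)
  # brute-force nearest-center oracle
  d1 <- rowSums((blob - matrix(cl$centers[1, ], 120, 16, byrow = TRUE))^2)
  d2 <- rowSums((blob - matrix(cl$centers[2, ], 120, 16, byrow = TRUE))^2)
  expect_identical(cl$labels, ifelse(d1 <= d2, 1L, 2L))
  agree <- max(mean((cl$labels == 1) == (truth == 1)),
               mean((cl$labels == 2) == (truth == 1)))
  expect_gte(agree, 0.95)
  cl2 <- cluster_concepts(blob, 2, seed = 7)
  expect_identical(cl$labels, cl2$labels)
  one <- cluster_concepts(blob, 1)
  expect_equal(as.numeric(one$centers), colMeans(blob))
  expect_error(cluster_concepts(blob[1:3, ], 5), "exceeds")
})

test_that("concept selection keeps the n nearest members and filters clusters", {
  set.seed(8)
  emb <- matrix(rnorm(100 * 4), 100, 4)
  pool <- structure(list(
    patches = lapply(1:100, function(i)
      list(tile = ((i - 1) %% 10) + 1, level = "mid",
           mask = matrix(TRUE, 2, 2))),
    tiles = vector("list", 10)), class = "patch_pool")
  cl <- list(labels = rep(1L, 100), centers = matrix(colMeans(emb), 1))
  sel <- select_concepts(cl, emb, pool, n = 40, min_members = 20,
                         min_tiles = 5)
  co <- sel$concepts[[1]]
  expect_length(co$patch_idx, 40)
  expect_identical(co$n_members_total, 100L)
  # brute-force: exactly the 40 smallest distances, ties by index
  d <- sqrt(rowSums((emb - matrix(co$center, 100, 4, byrow = TRUE))^2))
  expect_identical(co$patch_idx, order(d, seq_len(100))[1:40])
  expect_true(all(diff(co$distances) >= 0))
  # small clusters are discarded
  cl2 <- list(labels = rep(c(1L, 2L), c(12, 88)),
              centers = rbind(colMeans(emb[1:12, ]), colMeans(emb[13:100, ])))
  sel2 <- select_concepts(cl2, emb, pool, min_members = 20, min_tiles = 5)
  expect_length(sel2$concepts, 1)
  # clusters from too few distinct tiles are discarded
  pool1 <- pool
  for (i in 1:100) pool1$patches[[i]]$tile <- 1
  expect_warning(sel3 <- select_concepts(cl, emb, pool1, min_tiles = 5))
  expect_length(sel3$concepts, 0)
})

test_that("multi-resolution proposal pools all three SLIC levels", {
  expect_identical(slic_levels(256), c(15L, 50L, 80L))
  expect_identical(slic_levels(96), c(4L, 8L, 12L))
  tiles <- list(generate_tile("positive", "A", 1, "nuclei_dense", seed = 1))
  pool <- propose_patches(tiles)
  lv <- vapply(pool$patches, function(p) p$level, character(1))
  expect_setequal(unique(lv), c("coarse", "mid", "fine"))
})
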