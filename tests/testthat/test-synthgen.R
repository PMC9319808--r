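test_that("tile generation is deterministic and validates its inputs", {
  t1 <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 7)
  t2 <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 7)
  expect_identical(t1$pixels, t2$pixels)
  t3 <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 8)
  expect_false(identical(t1$pixels, t3$pixels))
  expect_error(generate_tile("positive", "A", 1, "mystery", seed = 1),
               "unknown stratum")
  expect_error(generate_tile("negative", "A", 1, "background", seed = 1),
               "near-white")
  expect_error(generate_tile("positive", "A", 1, character(0), seed = 1))
})

test_that("rendered tiles respect the near-white budget", {
  for (s in 1:12) {
    tile <- generate_tile(sample(c("positive", "negative"), 1), "A",
                          s %% 5 + 1,
                          c("nuclei_sparse", "collagen", "background"),
                          seed = s)
    expect_lte(histobias:::near_white_fraction(tile$pixels), 0.10)
  }
})

test_that("positive tiles have more and larger nuclei than negative tiles", {
  # count blobs with an independent connected-components oracle applied
  # to the generator's own nucleus masks
  n_pos <- n_neg <- area_pos <- area_neg <- numeric(0)
  for (s in 1:100) {
    tp <- generate_tile("positive", "A", s %% 9 + 1, "nuclei_dense", seed = s)
    tn <- generate_tile("negative", "A", s %% 9 + 1, "nuclei_sparse",
                        seed = s + 1000)
    cp <- count_components(tp$masks$nuclei)
    cn <- count_components(tn$masks$nuclei)
    n_pos <- c(n_pos, cp); n_neg <- c(n_neg, cn)
    if (cp > 0) area_pos <- c(area_pos, sum(tp$masks$nuclei) / cp)
    if (cn > 0) area_neg <- c(area_neg, sum(tn$masks$nuclei) / cn)
  }
  expect_gt(mean(n_pos), mean(n_neg))
  expect_gt(mean(area_pos), mean(area_neg))
})

test_that("source-B tiles are brighter than source-A tiles", {
  br <- function(src) mean(vapply(1:10, function(s)
    mean(generate_tile("negative", src, s, "nuclei_sparse",
                       seed = s)$pixels), numeric(1)))
  expect_gt(br("B"), br("A"))
})

test_that("marker injection is exact, local and validated", {
  tile <- generate_tile("positive", "A", 1, "nuclei_dense", seed = 3)
  mk <- marker_spec(96, size = 8, offset = c(4, 4))
  out <- inject_marker(tile, mk)
  expect_true(out$has_marker)
  expect_true(all(out$pixels[5:12, 5:12, 1] == 255))
  expect_true(all(out$pixels[5:12, 5:12, 2] == 0))
  expect_true(all(out$pixels[5:12, 5:12, 3] == 0))
  # locality: everything outside the marker rectangle is unchanged
  diff <- abs(out$pixels - tile$pixels)
  diff[5:12, 5:12, ] <- 0L
  expect_equal(sum(diff), 0)
  # size-0 marker leaves the tile unchanged
  out0 <- inject_marker(tile, marker_spec(96, size = 0))
  expect_identical(out0$pixels, tile$pixels)
  expect_false(out0$has_marker)
  expect_error(inject_marker(tile, marker_spec(96, size = 200)), "outside")
  tneg <- generate_tile("negative", "A", 1, "nuclei_sparse", seed = 4)
  expect_error(inject_marker(tneg), "positive")
})

test_that("source shift is a per-channel affine map", {
  tile <- generate_tile("negative", "A", 1, "nuclei_sparse", seed = 5)
  idshift <- source_shift(gain = rep(1, 3), offset = rep(0, 3))
  expect_identical(apply_source_shift(tile, idshift)$pixels, tile$pixels)
  plus20 <- apply_source_shift(tile, source_shift(gain = rep(1, 3),
                                                  offset = rep(20, 3)))
  expect_identical(plus20$pixels,
                   {p <- tile$pixels + 20L; p[p > 255L] <- 255L; p})
  expect_gt(mean(plus20$pixels), mean(tile$pixels))
})

test_that("datasets are slide-disjoint and deterministic", {
  for (kind in c("none", "class_ratio", "measurement", "sampling",
                 "class_correlated")) {
    ds <- build_dataset(bias_config(kind), n_slides = 8, tiles_per_slide = 4,
                        seed = 21)
    m <- ds$manifest
    splits <- split(m$slide_id, m$split)
    expect_length(Reduce(intersect, lapply(splits, unique)), 0)
  }
  d1 <- build_dataset(bias_config("none"), 8, 4, seed = 33)
  d2 <- build_dataset(bias_config("none"), 8, 4, seed = 33)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$train[[1]]$pixels, d2$train[[1]]$pixels)
  expect_error(build_dataset(bias_config("none"), n_slides = 4), ">= 6")
})

test_that("class-ratio rejection yields roughly 2:1 training imbalance", {
  # 30 slides x 30 tiles: 20 training slides = 600 candidate train tiles
  ds <- build_dataset(bias_config("class_ratio"), n_slides = 30,
                      tiles_per_slide = 30, seed = 41, tile_size = 96)
  tr <- ds$manifest[ds$manifest$split == "train", ]
  ratio <- sum(tr$label == "negative") / sum(tr$label == "positive")
  expect_gte(ratio, 1.7); expect_lte(ratio, 2.3)
  # validation/test untouched
  te <- ds$manifest[ds$manifest$split != "train", ]
  expect_lt(abs(mean(te$label == "positive") - 0.5), 0.15)
})

test_that("bias kinds satisfy their defining posts", {
  dcc <- mini_dataset("class_correlated")
  m <- dcc$manifest
  expect_true(all(m$has_marker[m$label == "positive"]))
  expect_false(any(m$has_marker[m$label == "negative"]))

  dsamp <- mini_dataset("sampling")
  m <- dsamp$manifest
  has_col <- grepl("collagen", m$strata)
  expect_identical(sum(has_col[m$split == "train" & m$label == "negative"]), 0L)
  expect_gt(sum(has_col[m$split == "test" & m$label == "negative"]), 0)

  dms <- mini_dataset("measurement")
  m <- dms$manifest
  expect_true(all(m$source[m$label == "positive"] == "A"))
  expect_true(all(m$source[m$label == "negative"] == "B"))
})

test_that("without bias, label is independent of source (chi-square)", {
  ok <- 0
  for (s in 1:20) {
    ds <- build_dataset(bias_config("none"), n_slides = 8,
                        tiles_per_slide = 8, seed = 100 + s)
    m <- ds$manifest
    p <- suppressWarnings(chisq.test(table(m$label, m$source))$p.value)
    if (p > 0.01) ok <- ok + 1
    expect_false(any(m$has_marker))
  }
  expect_gte(ok, 19)
})

test_that("datasets round-trip to PNG tiles plus CSV manifest", {
  ds <- build_dataset(bias_config("none"), 6, 2, seed = 9, tile_size = 48)
  dir <- tempfile("tiles")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_identical(nrow(mf), nrow(ds$manifest))
  row1 <- which(ds$manifest$split == "train")[1]
  px <- png::readPNG(file.path(dir, ds$manifest$path[row1]))
  expect_identical(round(px * 255), round(ds$train[[1]]$pixels + 0))
})
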