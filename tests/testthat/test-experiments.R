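# helper: hand-built tcav_result-shaped tibbles for the decision checks
fake_tcav <- function(pos_means, neg_means, sig) {
  n <- length(pos_means)
  df <- tibble::tibble(
    concept_id = rep(seq_len(n), each = 2),
    class = rep(c("positive", "negative"), n),
    mean = as.numeric(rbind(pos_means, neg_means)),
    std = 0.05,
    p_value = rep(ifelse(sig, 1e-4, 0.5), each = 2),
    significant = rep(sig, each = 2),
    runs = 20)
  class(df) <- c("tcav_result", class(df))
  df
}

test_that("concept dominance counts significant concepts per class", {
  # one cancerous vs four non-cancerous concepts: dominance (0.2, 0.8)
  res <- fake_tcav(pos_means = c(0.91, 0.1, 0.2, 0.05, 0.15),
                   neg_means = c(0.2, 1, 1, 1, 1),
                   sig = rep(TRUE, 5))
  d <- concept_dominance(res)
  expect_equal(unname(d$fractions["positive"]), 0.2)
  expect_equal(unname(d$fractions["negative"]), 0.8)
  expect_true(d$shift_flag)
  expect_lte(sum(d$fractions), 1)

  # four cancerous vs one non-cancerous: no shift
  res2 <- fake_tcav(pos_means = c(1, 1, 1, 1, 0.2),
                    neg_means = c(0, 0.1, 0, 0.05, 1),
                    sig = rep(TRUE, 5))
  d2 <- concept_dominance(res2)
  expect_equal(unname(d2$fractions["positive"]), 0.8)
  expect_false(d2$shift_flag)

  # all tied at 0.5: nothing countable
  res3 <- fake_tcav(pos_means = rep(0.5, 3), neg_means = rep(0.5, 3),
                    sig = rep(TRUE, 3))
  d3 <- concept_dominance(res3)
  expect_true(d3$undefined)

  # no significant concepts at all
  res4 <- fake_tcav(pos_means = c(1, 0), neg_means = c(0, 1),
                    sig = c(FALSE, FALSE))
  expect_true(concept_dominance(res4)$undefined)
})

# hand-built ace_concepts with known provenance
fake_concepts <- function(tiles, patch_tiles, masks) {
  pool <- structure(list(
    patches = lapply(seq_along(patch_tiles), function(i)
      list(tile = patch_tiles[i], level = "mid", mask = masks[[i]])),
    tiles = tiles), class = "patch_pool")
  structure(list(concepts = list(list(id = 1,
                                      patch_idx = seq_along(patch_tiles),
                                      center = rep(0, 4),
                                      n_members_total = length(patch_tiles),
                                      source_tiles = unique(patch_tiles))),
                 pool = pool,
                 embeddings = matrix(0, length(patch_tiles), 4)),
            class = "ace_concepts")
}

test_that("marker overlap and source purity read the generator ground truth", {
  tm <- inject_marker(generate_tile("positive", "A", 1, "nuclei_dense",
                                    seed = 1))
  tn <- generate_tile("negative", "B", 2, "nuclei_sparse", seed = 2)
  corner <- matrix(FALSE, 96, 96); corner[1:16, 1:16] <- TRUE
  far <- matrix(FALSE, 96, 96); far[60:96, 60:96] <- TRUE

  # every patch hits the marker region
  con <- fake_concepts(list(tm, tn), rep(1L, 4), rep(list(corner), 4))
  expect_equal(marker_overlap_check(con)$overlap, 1.0)
  # patches from a tile without a marker never hit
  con0 <- fake_concepts(list(tm, tn), rep(2L, 4), rep(list(corner), 4))
  expect_equal(marker_overlap_check(con0)$overlap, 0.0)
  # masks that avoid the corner never hit either
  con1 <- fake_concepts(list(tm, tn), rep(1L, 4), rep(list(far), 4))
  expect_equal(marker_overlap_check(con1)$overlap, 0.0)

  # purity: all from one source vs an even split
  conA <- fake_concepts(list(tm, tn), rep(1L, 40), rep(list(far), 40))
  expect_equal(source_purity_check(conA)$purity, 1.0)
  conAB <- fake_concepts(list(tm, tn), rep(c(1L, 2L), 20), rep(list(far), 40))
  expect_equal(source_purity_check(conAB)$purity, 0.5)
})

test_that("the excluded-location dataset-bias design is rejected", {
  expect_error(run_experiment("dataset_bias"), "location")
  expect_error(run_experiment("unheard_of"))
})

test_that("summaries carry one row per experiment with metric pairs", {
  mk <- function(name, bacc_b, auc_b, bacc_u = NA, auc_u = NA, flags = FALSE) {
    structure(list(
      experiment = name,
      metrics_biased = metrics_from_confusion(c(TP = 5, FP = 0, FN = 0,
                                                TN = 5), auc = auc_b),
      metrics_unbiased = if (!is.na(bacc_u))
        metrics_from_confusion(c(TP = 4, FP = 1, FN = 1, TN = 4),
                               auc = auc_u),
      bias_flags = c(dominance_shift = flags, marker_overlap = flags,
                     source_purity = flags)),
      class = "experiment_report")
  }
  reports <- list(mk("feature_vis", 1, 0.99),
                  mk("class_ratio", 0.7, 0.625, 0.75, 0.875, TRUE),
                  mk("measurement", 1, 1),
                  mk("sampling", 0.875, 1, 0.9, 1),
                  mk("class_correlated", 1, 1))
  tab <- summarize_experiments(reports)
  expect_identical(nrow(tab), 5L)
  expect_equal(tab$auc_biased[tab$experiment == "class_ratio"], 0.625)
  expect_equal(tab$auc_unbiased[tab$experiment == "class_ratio"], 0.875)
  expect_false(any(unlist(tab[tab$experiment == "measurement",
                              c("dominance_shift", "marker_overlap",
                                "source_purity")])))
})

test_that("run_experiment orchestrates a study end to end", {
  p <- scale_preset("mini")
  p$tcav_runs <- 5
  rep <- run_experiment("class_correlated", scale = p, seed = 5, epochs = 3,
                        out_dir = tempfile("xp"))
  expect_s3_class(rep, "experiment_report")
  expect_s3_class(rep$metrics_biased, "cnn_metrics")
  expect_null(rep$metrics_unbiased)
  expect_named(rep$bias_flags,
               c("dominance_shift", "marker_overlap", "source_purity"))
  expect_true(all(rep$overlap$overlap >= 0 & rep$overlap$overlap <= 1))
  tab <- summarize_experiments(list(rep))
  expect_identical(nrow(tab), 1L)
})
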