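#' Study orchestration: biased/unbiased model pairs and bias flags
#'
#' Five study configurations are supported: `feature_vis` (unbiased
#' control with two appearance sources and HSV augmentation),
#' `class_ratio`, `measurement`, `sampling`, and `class_correlated`.
#' Each run builds the configured dataset(s), trains the CNN, applies
#' concept extraction + TCAV (and saliency where artifacts are
#' requested), and converts the explanations into operational bias
#' flags: a concept-dominance shift toward the absence-defined negative
#' class, a concept whose patches overlap the planted marker, and a
#' concept whose patches all come from one acquisition source.
#'
#' @name experiments
NULL

#' Problem-size presets
#'
#' `desk` is the default working scale (96 px tiles, 30 slides x 40
#' tiles, up to 40 epochs, 20 TCAV runs). `paper` restores the
#' full-fidelity configuration (256 px, up to 100 epochs, 100 runs).
#' `mini` is a reduced preset for quick verification runs (96 px, 12
#' slides x 12 tiles, 12 epochs).
#'
#' @param scale `"desk"`, `"paper"`, or `"mini"`.
#' @return list of sizes: `tile_size`, `n_slides`, `tiles_per_slide`,
#'   `epochs`, `patience`, `tcav_runs`, `eval_cap`, `max_tiles`, `k`.
#' @export
scale_preset <- function(scale = c("desk", "paper", "mini")) {
  scale <- match.arg(scale)
  switch(scale,
    desk = list(tile_size = 96, n_slides = 30, tiles_per_slide = 40,
                epochs = 40, patience = 10, tcav_runs = 20, eval_cap = 100,
                max_tiles = 60, k = 5),
    paper = list(tile_size = 256, n_slides = 30, tiles_per_slide = 40,
                 epochs = 100, patience = 50, tcav_runs = 100,
                 eval_cap = 100, max_tiles = 60, k = 5),
    mini = list(tile_size = 96, n_slides = 12, tiles_per_slide = 12,
                epochs = 12, patience = 6, tcav_runs = 20, eval_cap = 60,
                max_tiles = 24, k = 5))
}

.experiment_names <- c("feature_vis", "class_ratio", "measurement",
                       "sampling", "class_correlated")

#' Concept dominance per class
#'
#' For each class, the share of significant concepts whose mean TCAVQ
#' for that class exceeds 0.5. The dominance-shift flag is raised when
#' the absence-defined (negative) class holds the majority of
#' significant concepts -- the signature of class-ratio and sampling
#' biases.
#'
#' @param tcav_results a `tcav_result`.
#' @return list with `fractions` (named per class), `counts`,
#'   `shift_flag`, `undefined` (no concept countable).
#' @export
concept_dominance <- function(tcav_results) {
  df <- tidy(tcav_results)
  sig_ids <- unique(df$concept_id[df$significant])
  if (!length(sig_ids))
    return(list(fractions = c(positive = NA_real_, negative = NA_real_),
                counts = c(positive = 0L, negative = 0L),
                shift_flag = FALSE, undefined = TRUE))
  counts <- c(positive = 0L, negative = 0L)
  for (id in sig_ids) {
    sub <- df[df$concept_id == id & df$significant & df$mean > 0.5, ]
    if (!nrow(sub)) next
    top <- sub$class[which.max(sub$mean)]
    counts[top] <- counts[top] + 1L
  }
  total <- length(sig_ids)
  fr <- counts / total
  list(fractions = fr, counts = counts,
       shift_flag = isTRUE(fr[["negative"]] > 0.5),
       undefined = sum(counts) == 0L)
}

#' Overlap of concept patches with the planted marker
#'
#' Fraction of each concept's patches whose mask intersects the marker
#' region of its source tile (generator ground truth).
#'
#' @param concepts an `ace_concepts`.
#' @return tibble with `concept_id` and `overlap`.
#' @export
marker_overlap_check <- function(concepts) {
  rows <- lapply(concepts$concepts, function(co) {
    hits <- vapply(co$patch_idx, function(i) {
      p <- concepts$pool$patches[[i]]
      tile <- concepts$pool$tiles[[p$tile]]
      any(p$mask & marker_region_mask(tile))
    }, logical(1))
    tibble::tibble(concept_id = co$id, overlap = mean(hits))
  })
  dplyr::bind_rows(rows)
}

#' Source purity of concepts
#'
#' For each concept, the maximum over sources of the fraction of its
#' patches originating from that source. Purity 1.0 of a significant
#' concept is the measurement-bias signature.
#'
#' @param concepts an `ace_concepts`.
#' @return tibble with `concept_id`, `purity`, `top_source`.
#' @export
source_purity_check <- function(concepts) {
  rows <- lapply(concepts$concepts, function(co) {
    src <- vapply(co$patch_idx, function(i)
      concepts$pool$tiles[[concepts$pool$patches[[i]]$tile]]$source,
      character(1))
    tb <- table(src)
    tibble::tibble(concept_id = co$id, purity = max(tb) / sum(tb),
                   top_source = names(tb)[which.max(tb)])
  })
  dplyr::bind_rows(rows)
}

# fraction of a concept's patches overlapping the excluded stratum mask
stratum_overlap_check <- function(concepts, stratum = "collagen") {
  rows <- lapply(concepts$concepts, function(co) {
    fr <- vapply(co$patch_idx, function(i) {
      p <- concepts$pool$patches[[i]]
      m <- concepts$pool$tiles[[p$tile]]$masks[[stratum]]
      if (is.null(m)) 0 else sum(p$mask & m) / sum(p$mask)
    }, numeric(1))
    tibble::tibble(concept_id = co$id, mean_overlap = mean(fr),
                   frac_hit = mean(fr > 0.5))
  })
  dplyr::bind_rows(rows)
}

run_explanations <- function(fit, ds, preset, seed) {
  concepts <- ace_extract(fit, ds$test, k = preset$k, seed = seed,
                          max_tiles = preset$max_tiles)
  tcav <- if (length(concepts$concepts))
    run_tcav(fit, concepts, ds$test, runs = preset$tcav_runs,
             eval_cap = preset$eval_cap, seed = seed)
  list(concepts = concepts, tcav = tcav)
}

#' Run one study configuration end to end
#'
#' Builds the biased dataset (and, for `feature_vis`, `class_ratio` and
#' `sampling`, the unbiased counterpart), trains the CNN with the
#' configuration's protocol -- `class_ratio` runs a fixed epoch budget
#' with early stopping and class weights disabled, all others use early
#' stopping and class weights -- then extracts concepts, scores them
#' with TCAV, and computes the bias flags.
#'
#' @param name experiment name, one of `feature_vis`, `class_ratio`,
#'   `measurement`, `sampling`, `class_correlated`.
#' @param scale size preset name or a [scale_preset()]-shaped list.
#' @param seed master seed; dataset, training, concept and TCAV seeds
#'   derive from it.
#' @param out_dir optional directory; when given, concept galleries, the
#'   TCAV bar chart, saliency triptychs of a few test tiles, and the
#'   report JSON are written there.
#' @param epochs optional override of the preset's epoch budget.
#' @return an `experiment_report`: list with `experiment`,
#'   `metrics_biased`, `metrics_unbiased` (NULL where no counterpart is
#'   defined), `tcav`, `tcav_unbiased`, `concepts`, `dominance`,
#'   `bias_flags` (named logical vector), `overlap`, `purity`, `fits`.
#' @export
run_experiment <- function(name, scale = "desk", seed = 1, out_dir = NULL,
                           epochs = NULL) {
  if (identical(name, "dataset_bias"))
    stop("the location-dependent dataset-bias design is not supported: ",
         "concept patches are location-free, so this study excludes it ",
         "by design")
  name <- match.arg(name, .experiment_names)
  preset <- if (is.character(scale)) scale_preset(scale) else scale
  if (!is.null(epochs)) preset$epochs <- epochs
  kind <- switch(name, feature_vis = "none", class_ratio = "class_ratio",
                 measurement = "measurement", sampling = "sampling",
                 class_correlated = "class_correlated")
  ratio_protocol <- name == "class_ratio"
  hsv <- name == "feature_vis"
  train_one <- function(bias_kind, sd_offset) {
    ds <- build_dataset(bias_config(bias_kind), preset$n_slides,
                        preset$tiles_per_slide, seed = derive_seed(seed, sd_offset),
                        tile_size = preset$tile_size)
    model <- build_model(preset$tile_size, seed = derive_seed(seed, sd_offset, 2L))
    fit <- train_cnn(model, ds, epochs = preset$epochs,
                     patience = preset$patience,
                     early_stop = !ratio_protocol,
                     class_weights = !ratio_protocol, hsv_aug = hsv,
                     seed = derive_seed(seed, sd_offset, 3L))
    list(ds = ds, fit = fit, metrics = evaluate_cnn(fit, ds$test))
  }
  biased <- train_one(kind, 1L)
  unbiased <- if (name %in% c("class_ratio", "sampling"))
    train_one("none", 4L)
  expl <- run_explanations(biased$fit, biased$ds, preset,
                           derive_seed(seed, 7L))
  expl_un <- if (!is.null(unbiased))
    run_explanations(unbiased$fit, unbiased$ds, preset,
                     derive_seed(seed, 8L))
  dominance <- if (!is.null(expl$tcav)) concept_dominance(expl$tcav)
  overlap <- marker_overlap_check(expl$concepts)
  purity <- source_purity_check(expl$concepts)
  sig_ids <- if (!is.null(expl$tcav)) {
    df <- tidy(expl$tcav)
    unique(df$concept_id[df$significant])
  } else integer(0)
  pos_sig <- if (!is.null(expl$tcav)) {
    df <- tidy(expl$tcav)
    unique(df$concept_id[df$significant & df$class == "positive" &
                           df$mean > 0.5])
  } else integer(0)
  flags <- c(
    dominance_shift = isTRUE(dominance$shift_flag),
    marker_overlap = any(overlap$overlap[overlap$concept_id %in% pos_sig]
                         >= 0.9),
    source_purity = any(purity$purity[purity$concept_id %in% sig_ids] == 1 &
                          length(sig_ids) > 0))
  report <- structure(list(
    experiment = name,
    metrics_biased = biased$metrics,
    metrics_unbiased = if (!is.null(unbiased)) unbiased$metrics,
    tcav = expl$tcav, tcav_unbiased = if (!is.null(expl_un)) expl_un$tcav,
    concepts = expl$concepts,
    concepts_unbiased = if (!is.null(expl_un)) expl_un$concepts,
    dominance = dominance, overlap = overlap, purity = purity,
    bias_flags = flags, seed = seed,
    fits = list(biased = biased$fit,
                unbiased = if (!is.null(unbiased)) unbiased$fit),
    datasets = list(biased = biased$ds,
                    unbiased = if (!is.null(unbiased)) unbiased$ds)),
    class = "experiment_report")
  if (!is.null(out_dir)) write_report_artifacts(report, out_dir)
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report %s>\n", x$experiment))
  cat("  biased:   "); print(x$metrics_biased)
  if (!is.null(x$metrics_unbiased)) {
    cat("  unbiased: "); print(x$metrics_unbiased)
  }
  fired <- names(x$bias_flags)[x$bias_flags]
  cat("  flags fired:", if (length(fired)) paste(fired, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

write_report_artifacts <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_concept_gallery(report$concepts, file.path(out_dir, "concepts"))
  if (!is.null(report$tcav))
    plot_scores(report$tcav, file.path(out_dir, "tcav_scores.png"))
  ds <- report$datasets$biased
  fit <- report$fits$biased
  show <- ds$test[seq_len(min(3, length(ds$test)))]
  for (i in seq_along(show)) {
    hm <- compute_heatmap(fit, show[[i]], "positive")
    render_heatmap(show[[i]], hm,
                   file.path(out_dir, sprintf("saliency_tile%02d", i)))
  }
  js <- list(experiment = report$experiment,
             metrics_biased = glance(report$metrics_biased),
             metrics_unbiased = if (!is.null(report$metrics_unbiased))
               glance(report$metrics_unbiased),
             bias_flags = as.list(report$bias_flags),
             tcav = if (!is.null(report$tcav)) tidy(report$tcav))
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Summarize a set of experiment reports
#'
#' One row per experiment: metrics for the biased and (where defined)
#' unbiased model and which bias flags fired.
#'
#' @param reports list of `experiment_report` objects.
#' @return tibble.
#' @export
summarize_experiments <- function(reports) {
  rows <- lapply(reports, function(r) {
    tibble::tibble(
      experiment = r$experiment,
      bacc_biased = r$metrics_biased$balanced_accuracy,
      auc_biased = r$metrics_biased$auc,
      bacc_unbiased = if (!is.null(r$metrics_unbiased))
        r$metrics_unbiased$balanced_accuracy else NA_real_,
      auc_unbiased = if (!is.null(r$metrics_unbiased))
        r$metrics_unbiased$auc else NA_real_,
      dominance_shift = r$bias_flags[["dominance_shift"]],
      marker_overlap = r$bias_flags[["marker_overlap"]],
      source_purity = r$bias_flags[["source_purity"]])
  })
  dplyr::bind_rows(rows)
}
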