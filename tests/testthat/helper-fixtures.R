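# Shared fixtures, built once per test run and memoised. Trained models
# are expensive, so several test files reuse the same fits.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

# reduced study scale used throughout the suite
mini <- scale_preset("mini")

mini_dataset <- function(kind, seed = 11) {
  memo(paste0("ds_", kind, "_", seed),
       build_dataset(bias_config(kind), n_slides = mini$n_slides,
                     tiles_per_slide = mini$tiles_per_slide, seed = seed,
                     tile_size = mini$tile_size))
}

# measurement-confound model: the global appearance shift saturates fast
measurement_fit <- function() {
  memo("fit_measurement", {
    ds <- mini_dataset("measurement")
    m <- build_model(mini$tile_size, seed = 1)
    train_cnn(m, ds, epochs = 8, patience = 6, seed = 2)
  })
}

# class-correlated (marker) model: the corner marker needs a longer budget
marker_fit <- function() {
  memo("fit_marker", {
    ds <- mini_dataset("class_correlated")
    m <- build_model(mini$tile_size, seed = 1)
    train_cnn(m, ds, epochs = 40, patience = 10, seed = 2)
  })
}

marker_concepts <- function() {
  memo("concepts_marker", {
    ds <- mini_dataset("class_correlated")
    ace_extract(marker_fit(), ds$test, k = mini$k, seed = 3,
                max_tiles = mini$max_tiles)
  })
}

marker_tcav <- function() {
  memo("tcav_marker", {
    ds <- mini_dataset("class_correlated")
    run_tcav(marker_fit(), marker_concepts(), ds$test,
             runs = mini$tcav_runs, eval_cap = mini$eval_cap, seed = 4)
  })
}

measurement_concepts <- function() {
  memo("concepts_measurement", {
    ds <- mini_dataset("measurement")
    ace_extract(measurement_fit(), ds$test, k = mini$k, seed = 3,
                max_tiles = mini$max_tiles)
  })
}

measurement_tcav <- function() {
  memo("tcav_measurement", {
    ds <- mini_dataset("measurement")
    run_tcav(measurement_fit(), measurement_concepts(), ds$test,
             runs = mini$tcav_runs, eval_cap = mini$eval_cap, seed = 4)
  })
}

# a small model for gradient checks (same ops, reduced widths)
tiny_model <- function(seed = 3) build_model(32, widths = c(4, 8),
                                             fc_units = 6, seed = seed)

# independent connected-components labeling (4-neighborhood flood fill),
# used as the blob-counting oracle against the generator's nucleus masks
count_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  n <- 0
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1
    stack <- start
    while (length(stack)) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[p]) next
      seen[p] <- TRUE
      r <- (p - 1) %% h + 1; c <- (p - 1) %/% h + 1
      for (d in list(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))) {
        if (d[1] >= 1 && d[1] <= h && d[2] >= 1 && d[2] <= w) {
          q <- d[1] + (d[2] - 1) * h
          if (mask[q] && !seen[q]) stack <- c(stack, q)
        }
      }
    }
  }
  n
}

# flat-grey toy tiles where a red corner square is the only signal
toy_marker_tiles <- function(n_each = 16, size = 32, seed = 5) {
  tiles <- list()
  set.seed(seed)
  for (i in seq_len(2 * n_each)) {
    px <- array(as.integer(round(runif(size * size * 3, 120, 135))),
                c(size, size, 3))
    lab <- if (i <= n_each) "positive" else "negative"
    tile <- list(pixels = px, label = lab, source = "A",
                 slide_id = ((i - 1) %% 8) + 1L, has_marker = FALSE,
                 strata = "nuclei_sparse", masks = list())
    class(tile) <- "histo_tile"
    if (lab == "positive") tile <- inject_marker(tile, marker_spec(size))
    tiles[[i]] <- tile
  }
  tiles
}
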