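#' Configuration of an end-to-end run
#'
#' Bundles every knob of the pipeline — simulation size, split
#' probabilities, fold count, autoencoder settings, progression and
#' prediction grids — into one serializable list, so a run is reproducible
#' from its config and seed alone.
#'
#' @param n_patients Synthetic cohort size (ignored when `data_csv` given).
#' @param data_csv Optional path to a longitudinal cohort CSV to load
#'   instead of simulating.
#' @param out_dir Output directory for report files.
#' @param seed Master seed.
#' @param vae A [vae_config()].
#' @param params A [cohort_params()] for simulation.
#' @param probs Split probabilities (train/validation/test).
#' @param k_folds Cross-validation folds; `1` means a single split.
#' @param latent_dims Latent dimensions to train (one model per value).
#' @param cutoffs Progression hit-rate cutoffs in years.
#' @param alpha Progression significance level.
#' @param n_boot Bootstrap replicates for hit-rate intervals.
#' @param k_inputs,horizons,trends Prediction scenario grid.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_patients = 200L, data_csv = NULL,
                       out_dir = tempfile("vfvae_run_"), seed = 1L,
                       vae = vae_config(latent_dim = 8L, epochs = 20L),
                       params = cohort_params(),
                       probs = c(train = 0.8, validation = 0.1, test = 0.1),
                       k_folds = 1L, latent_dims = NULL,
                       cutoffs = c(2, 4, 6, Inf), alpha = 0.05,
                       n_boot = 200L, k_inputs = c(3L, 5L, 7L),
                       horizons = 1:5, trends = c("linear", "quadratic")) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline: simulate/load, QC, split, train, report
#'
#' Simulates (or loads) a cohort, applies the reliability filter, builds
#' patient-level splits or folds, trains one autoencoder per fold and
#' latent dimension, and writes the progression hit-rate report and the
#' prediction records/summary as CSV files in `config$out_dir`, together
#' with the serialized config and a small text log. Identical config and
#' seed reproduce identical report files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, fold fits, and both reports.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  log_line <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), sprintf(...), "\n",
        file = logf, append = TRUE)
  }
  cat("", file = logf)
  jsonlite::write_json(
    config_serializable(config), file.path(config$out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  if (!is.null(config$data_csv)) {
    cohort <- read_vf_csv(config$data_csv)
    log_line("loaded %d fields from %s", nrow(cohort), config$data_csv)
  } else {
    cohort <- simulate_cohort(config$n_patients, config$params,
                              seed = config$seed)$cohort
    log_line("simulated %d fields from %d patients", nrow(cohort),
             config$n_patients)
  }

  n0 <- nrow(cohort)
  cohort <- suppressMessages(qc_filter(cohort))
  log_line("qc: excluded %d of %d fields", attr(cohort, "n_excluded"), n0)
  cohort <- convert_to_right_eye(cohort)

  dims <- config$latent_dims
  if (is.null(dims)) dims <- config$vae$latent_dim
  if (config$k_folds > 1) {
    folds <- make_folds(cohort, config$k_folds, config$probs,
                        seed = config$seed)
    splits <- lapply(seq_len(config$k_folds), function(f) {
      apply_fold(cohort, folds, f)
    })
  } else {
    splits <- list(split_patients(cohort, config$probs, seed = config$seed))
  }

  fold_fits <- purrr::map_dfr(seq_along(splits), function(f) {
    sp <- splits[[f]]
    purrr::map_dfr(dims, function(L) {
      cfg <- config$vae
      cfg$latent_dim <- as.integer(L)
      cfg$mmd_bandwidth <- sqrt(L)
      cfg$seed <- config$seed + f
      fit <- vae_train(sp[sp$split == "train", ],
                       sp[sp$split == "validation", ], cfg)
      log_line("fold %d L = %d: trained, selected epoch %d", f, L,
               fit$selected_epoch)
      tibble::tibble(fold = f, latent_dim = L, fit = list(fit),
                     test = list(sp[sp$split == "test", ]))
    })
  })

  prog <- progression_report(fold_fits, config$cutoffs, config$alpha,
                             config$n_boot, seed = config$seed)
  readr::write_csv(prog, file.path(config$out_dir, "progression_report.csv"))
  log_line("progression report: %d rows", nrow(prog))

  records <- purrr::map_dfr(seq_len(nrow(fold_fits)), function(i) {
    dplyr::mutate(
      evaluate_predictions(fold_fits$test[[i]], fold_fits$fit[[i]],
                           config$k_inputs, config$horizons, config$trends),
      fold = fold_fits$fold[i], latent_dim = fold_fits$latent_dim[i])
  })
  rec_out <- dplyr::select(records, -"predicted_td", -"observed_td")
  readr::write_csv(rec_out, file.path(config$out_dir,
                                      "prediction_records.csv"))
  summary <- summarise_predictions(records)
  readr::write_csv(summary, file.path(config$out_dir,
                                      "prediction_summary.csv"))
  log_line("prediction records: %d; summary rows: %d", nrow(records),
           nrow(summary))

  invisible(list(cohort = cohort, fold_fits = fold_fits,
                 progression = prog, prediction_records = records,
                 prediction_summary = summary))
}

config_serializable <- function(config) {
  out <- unclass(config)
  out$vae <- unclass(out$vae)
  out$params <- unclass(out$params)
  out$cutoffs <- ifelse(is.infinite(out$cutoffs), "Inf", out$cutoffs)
  out
}

#' Decode a lattice of 2-D latent points into a field mosaic
#'
#' For a model with two latent dimensions, decodes a `steps x steps` grid
#' of latent points spanning `grid_range` in both coordinates — a picture
#' of the generative distribution: each panel is the de-noised visual field
#' the decoder associates with that region of latent space.
#'
#' @param fit A `vfvae_fit` with `latent_dim == 2`.
#' @param grid_range Range spanned in each latent coordinate.
#' @param steps Number of lattice points per side.
#' @return A tibble with one row per decoded pixel: `z1`, `z2`, `panel_row`,
#'   `panel_col`, `row`, `col`, `td` (dB; pad cells `NA`).
#' @export
latent_grid <- function(fit, grid_range = c(-2, 2), steps = 5L) {
  if (fit$config$latent_dim != 2) {
    rlang::abort("latent_grid needs a model with 2 latent dimensions; train one with vae_config(latent_dim = 2).")
  }
  vals <- seq(grid_range[1], grid_range[2], length.out = steps)
  pts <- expand.grid(z1 = vals, z2 = vals)
  td <- vf_decode_td(fit, as.matrix(pts))
  mask <- fit$mask
  purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    img <- matrix(NA_real_, 12, 12)
    img[cbind(mask$coords$row, mask$coords$col)] <- td[i, mask$coords$loc]
    tibble::tibble(
      z1 = pts$z1[i], z2 = pts$z2[i],
      panel_row = match(pts$z2[i], vals), panel_col = match(pts$z1[i], vals),
      row = rep(1:12, 12), col = rep(1:12, each = 12),
      td = as.vector(img))
  })
}

#' Plot a decoded latent-space mosaic
#'
#' @param grid Output of [latent_grid()].
#' @return A ggplot: one heatmap panel per latent lattice point, on a fixed
#'   dB colour scale.
#' @export
plot_latent_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(.data$col, .data$row,
                                     fill = .data$td)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "red",
                                  high = "lightyellow", midpoint = -16,
                                  limits = c(-38, 6), na.value = "white") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$z2),
                        cols = ggplot2::vars(.data$z1),
                        labeller = ggplot2::label_both) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "TD (dB)")
}

#' Plot one visual field as a heatmap
#'
#' @param td Numeric 52-vector of TD values (dB).
#' @param mask A [vf_mask()].
#' @return A ggplot heatmap on the fixed `[-38, 6]` dB scale.
#' @export
plot_field <- function(td, mask = vf_mask()) {
  img <- matrix(NA_real_, 12, 12)
  img[cbind(mask$coords$row, mask$coords$col)] <- td[mask$coords$loc]
  d <- tibble::tibble(row = rep(1:12, 12), col = rep(1:12, each = 12),
                      td = as.vector(img))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$td)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(low = "black", mid = "red",
                                  high = "lightyellow", midpoint = -16,
                                  limits = c(-38, 6), na.value = "white") +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "TD (dB)")
}
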