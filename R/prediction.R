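#' Extrapolate latent trajectories from the first k visits
#'
#' Fits an independent OLS regression of each latent dimension on time
#' (intercept + time, plus time^2 for the quadratic trend) using only the
#' first `k` visits, and evaluates the fits at the requested target times.
#'
#' @param z Numeric matrix `n x L` of latent features, rows time-ordered.
#' @param times Visit times in years (length `n`).
#' @param k Number of input visits (>= 3; >= 4 for quadratic).
#' @param target_times Times at which to predict.
#' @param trend `"linear"` or `"quadratic"`.
#' @return Numeric matrix `length(target_times) x L`.
#' @export
predict_latent_trajectory <- function(z, times, k, target_times,
                                      trend = c("linear", "quadratic")) {
  trend <- match.arg(trend)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  min_k <- if (trend == "linear") 3L else 4L
  if (k < min_k) {
    rlang::abort(sprintf("predict_latent_trajectory: k = %d < required %d for %s trend.",
                         k, min_k, trend))
  }
  if (nrow(z) < k) rlang::abort("predict_latent_trajectory: fewer than k visits.")
  t_in <- times[seq_len(k)]
  X <- if (trend == "linear") cbind(1, t_in) else cbind(1, t_in, t_in^2)
  B <- qr.solve(X, z[seq_len(k), , drop = FALSE])
  Xt <- if (trend == "linear") cbind(1, target_times) else
    cbind(1, target_times, target_times^2)
  Xt %*% B
}

#' Two-stage autoencoder prediction of a future visual field
#'
#' Encodes the first `k` visits of one patient's series, extrapolates each
#' latent dimension to the observed time of the target visit
#' (`k + horizon`-th), decodes the predicted latent point, and scores the
#' de-noised field against the held-out observed field by mean absolute
#' error over the 52 informative locations. Decoded predictions are always
#' within the normalization range (sigmoid output).
#'
#' @param data A [vf_cohort] tibble holding one patient's series (or a
#'   cohort; `patient_id` must then be unique), time-ordered.
#' @param fit A `vfvae_fit`.
#' @param k Number of input visits.
#' @param horizon Visits ahead of the k-th to predict (target index
#'   `k + horizon`).
#' @param trend Latent trend, `"linear"` or `"quadratic"`.
#' @return One-row tibble: `patient_id`, `status`, `method`, `trend`,
#'   `k_input`, `horizon`, `target_years`, `mae`, plus list-columns
#'   `predicted_td` and `observed_td` (52-vectors, dB).
#' @export
predict_field_vae <- function(data, fit, k, horizon = 1L,
                              trend = c("linear", "quadratic")) {
  trend <- match.arg(trend)
  s <- one_series(data, k, horizon)
  enc <- vf_encode(s$input, fit)
  z <- as.matrix(enc[, grep("^z_", names(enc)), drop = FALSE])
  z_pred <- predict_latent_trajectory(z, s$input$years, k, s$target_years,
                                      trend)
  pred_td <- as.vector(vf_decode_td(fit, z_pred))
  prediction_record(s, "vae", trend, k, horizon, pred_td)
}

#' Pointwise-regression baseline prediction of a future visual field
#'
#' The established comparator: an independent OLS of TD on time at each of
#' the 52 locations, fitted on the first `k` visits and extrapolated to the
#' target visit's observed time. Predictions are not clamped to the
#' physiologic range unless `clamp = TRUE`.
#'
#' @inheritParams predict_field_vae
#' @param clamp Clamp predictions to `norm`'s range (default `FALSE`).
#' @param norm A [vf_norm()] supplying the clamping range.
#' @return One-row tibble as in [predict_field_vae()], `method =
#'   "pointwise"`.
#' @export
predict_field_pointwise <- function(data, k, horizon = 1L, clamp = FALSE,
                                    norm = vf_norm()) {
  if (k < 2) rlang::abort("predict_field_pointwise: k must be >= 2.")
  s <- one_series(data, k, horizon)
  t_in <- s$input$years
  X <- cbind(1, t_in)
  B <- qr.solve(X, td_matrix(s$input))
  pred_td <- as.vector(c(1, s$target_years) %*% B)
  if (clamp) pred_td <- pmin(pmax(pred_td, norm$td_min), norm$td_max)
  prediction_record(s, "pointwise", "linear", k, horizon, pred_td)
}

one_series <- function(data, k, horizon) {
  if (length(unique(data$patient_id)) != 1) {
    rlang::abort("prediction functions take a single patient's series.")
  }
  data <- data[order(data$years), , drop = FALSE]
  target <- k + horizon
  if (nrow(data) < target) {
    rlang::abort(sprintf("series has %d visits; k + horizon = %d required.",
                         nrow(data), target))
  }
  list(input = data[seq_len(k), , drop = FALSE],
       target_years = data$years[target],
       observed = as.vector(td_matrix(data[target, , drop = FALSE])),
       patient_id = data$patient_id[1], status = data$status[1])
}

prediction_record <- function(s, method, trend, k, horizon, pred_td) {
  tibble::tibble(
    patient_id = s$patient_id, status = s$status, method = method,
    trend = trend, k_input = k, horizon = horizon,
    target_years = s$target_years,
    mae = mean(abs(pred_td - s$observed)),
    predicted_td = list(pred_td), observed_td = list(s$observed)
  )
}

#' Evaluate future-field predictions over a scenario grid
#'
#' Runs the two-stage autoencoder predictor and the pointwise baseline for
#' every patient and every (k, horizon) scenario the patient's series can
#' support: predicting the five visits after the third, fifth, and seventh
#' visit. The quadratic latent trend requires k >= 4, so it skips k = 3.
#' MAE is always computed over exactly the 52 informative locations.
#'
#' @param data A [vf_cohort] tibble (typically the test split).
#' @param fit A `vfvae_fit`.
#' @param k_inputs Input visit counts (default `c(3, 5, 7)`).
#' @param horizons Visits ahead (default `1:5`).
#' @param trends Latent trends to run (default linear and quadratic).
#' @return A records tibble: one row per (patient, scenario, method) with
#'   `mae` in dB; the pointwise baseline appears once per scenario with
#'   `trend = "linear"`.
#' @export
evaluate_predictions <- function(data, fit, k_inputs = c(3L, 5L, 7L),
                                 horizons = 1:5,
                                 trends = c("linear", "quadratic")) {
  per_patient <- split(data[order(data$patient_id, data$years), ],
                       data$patient_id[order(data$patient_id, data$years)])
  purrr::map_dfr(per_patient, function(s) {
    n <- nrow(s)
    purrr::map_dfr(k_inputs, function(k) {
      hs <- horizons[k + horizons <= n]
      purrr::map_dfr(hs, function(h) {
        rec_pw <- predict_field_pointwise(s, k, h)
        rec_vae <- purrr::map_dfr(trends[trends != "quadratic" | k >= 4],
                                  function(tr) {
                                    predict_field_vae(s, fit, k, h, tr)
                                  })
        dplyr::bind_rows(rec_vae, rec_pw)
      })
    })
  })
}

#' Paired one-sided Wilcoxon comparison of prediction errors
#'
#' Signed-rank test of whether the autoencoder's MAE is smaller than the
#' pointwise baseline's on patient-paired errors. Zero differences are
#' dropped (signed-rank convention); the exact null distribution is used
#' for n <= 25 without ties, exact sign-flip enumeration over midranks for
#' tied samples up to n = 14, and otherwise the normal approximation with
#' continuity correction. The significance threshold defaults to the
#' Bonferroni-corrected level 0.05/900 for the full comparison family.
#'
#' @param mae_vae,mae_pw Paired numeric vectors (same patients, same order).
#' @param alpha Family-corrected significance level.
#' @return One-row tibble: `n`, `n_zero` (dropped pairs), `p_value`,
#'   `significant`, `alpha`.
#' @export
compare_wilcoxon <- function(mae_vae, mae_pw, alpha = 0.05 / 900) {
  if (length(mae_vae) != length(mae_pw)) {
    rlang::abort("compare_wilcoxon: vectors must be paired (equal length).")
  }
  d <- mae_vae - mae_pw
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble::tibble(n = 0L, n_zero = n_zero, p_value = 1,
                          significant = FALSE, alpha = alpha))
  }
  ties <- anyDuplicated(abs(d)) > 0
  if (n <= 25 && !ties) {
    p <- stats::wilcox.test(d, alternative = "less", exact = TRUE)$p.value
  } else if (n <= 14) {
    # ties break the standard exact distribution: enumerate sign flips over
    # midranks instead (2^n cases)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    p <- mean(signs %*% r <= w_obs)
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, alternative = "less", exact = FALSE,
                         correct = TRUE)$p.value
    )
  }
  tibble::tibble(n = n, n_zero = n_zero, p_value = p,
                 significant = p < alpha, alpha = alpha)
}

#' Summarise prediction records by scenario
#'
#' Mean/median/quartile MAE per (population, trend, k, horizon, method)
#' cell, with the paired one-sided Wilcoxon p-value comparing the
#' autoencoder to the pointwise baseline within each cell.
#'
#' @param records Output of [evaluate_predictions()].
#' @param populations `"all"`, `"glaucoma"`, or both.
#' @param alpha Bonferroni-corrected level for the Wilcoxon flags.
#' @return A summary tibble with one row per cell and method.
#' @export
summarise_predictions <- function(records,
                                  populations = c("all", "glaucoma"),
                                  alpha = 0.05 / 900) {
  purrr::map_dfr(populations, function(popn) {
    rec <- if (popn == "glaucoma") {
      records[records$status == "glaucoma", ]
    } else {
      records
    }
    # the pointwise baseline is trend-free: pair it with each latent trend
    vae <- rec[rec$method == "vae", ]
    pw <- rec[rec$method == "pointwise", ]
    pw_by_trend <- purrr::map_dfr(unique(vae$trend), function(tr) {
      dplyr::mutate(dplyr::semi_join(
        pw, vae[vae$trend == tr, c("k_input", "horizon")],
        by = c("k_input", "horizon")), trend = tr)
    })
    rec <- dplyr::bind_rows(vae, pw_by_trend)
    cells <- dplyr::group_by(rec, .data$trend, .data$k_input, .data$horizon)
    dplyr::group_modify(cells, function(g, key) {
      vae <- g[g$method == "vae", ]
      pw <- g[g$method == "pointwise", ]
      both <- dplyr::inner_join(
        vae[, c("patient_id", "mae")], pw[, c("patient_id", "mae")],
        by = "patient_id", suffix = c("_vae", "_pw"))
      wt <- if (nrow(both) >= 5) {
        compare_wilcoxon(both$mae_vae, both$mae_pw, alpha)
      } else {
        tibble::tibble(p_value = NA_real_, significant = NA)
      }
      purrr::map_dfr(c("vae", "pointwise"), function(m) {
        mae <- g$mae[g$method == m]
        tibble::tibble(method = m, n = length(mae), mean_mae = mean(mae),
                       median_mae = stats::median(mae),
                       q1_mae = unname(stats::quantile(mae, 0.25)),
                       q3_mae = unname(stats::quantile(mae, 0.75)),
                       p_value = wt$p_value[1],
                       significant = wt$significant[1])
      })
    }) |>
      dplyr::ungroup() |>
      dplyr::mutate(population = popn, .before = 1)
  })
}
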