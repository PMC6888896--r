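#' Global rate-of-progression test on a latent trajectory
#'
#' Fits the stacked zero-sum constrained OLS model to an `n x L` latent
#' series: every feature gets its own intercept, features share a global
#' time slope `beta`, and feature-specific slope deviations are coded
#' sum-to-zero, so `beta` is literally the mean rate of change across
#' features. For `trend = "linear"` the returned p-value is the two-sided t
#' test of `beta = 0` against the pooled residual variance. For
#' `trend = "quadratic"` the model adds a global quadratic term plus
#' sum-to-zero quadratic deviations, and the p-value is the joint F test
#' that both global terms (linear and quadratic) are zero, via nested-model
#' RSS comparison; the reported `global_rate` is still the fitted `beta`.
#'
#' A series with fewer than 3 visits (4 for quadratic) or with no residual
#' degrees of freedom yields `p_value = NA` and `flagged = FALSE` with a
#' warning.
#'
#' @param z Numeric matrix `n x L` of latent features (rows = visits), or a
#'   vector for `L = 1`.
#' @param times Visit times in years from baseline (strictly increasing).
#' @param alpha Significance level (default 0.05, two-sided).
#' @param trend `"linear"` or `"quadratic"`.
#' @return A one-row tibble (`method`, `global_rate`, `p_value`, `flagged`,
#'   `alpha`, `n_visits`).
#' @examples
#' t <- 0:5
#' z <- cbind(1 - 0.3 * t + rnorm(6, 0, .05), 0.5 - 0.2 * t + rnorm(6, 0, .05))
#' global_rate_test(z, t)
#' @export
global_rate_test <- function(z, times, alpha = 0.05,
                             trend = c("linear", "quadratic")) {
  trend <- match.arg(trend)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  n <- nrow(z)
  L <- ncol(z)
  method <- if (trend == "linear") "vae_linear" else "vae_nonlinear"
  min_n <- if (trend == "linear") 3L else 4L
  if (n < min_n || length(times) != n) {
    warning(sprintf("global_rate_test: %d visit(s) < required %d; no test.",
                    n, min_n))
    return(progression_row(method, NA_real_, NA_real_, FALSE, alpha, n))
  }

  y <- as.vector(z)
  tt <- rep(times, L)
  if (L == 1) {
    fit <- if (trend == "linear") stats::lm(y ~ tt) else
      stats::lm(y ~ tt + I(tt^2))
    red <- if (trend == "linear") NULL else stats::lm(y ~ 1)
  } else {
    f <- factor(rep(seq_len(L), each = n))
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    if (trend == "linear") {
      fit <- stats::lm(y ~ f + tt + f:tt)
      red <- NULL
    } else {
      t2 <- tt^2
      fit <- stats::lm(y ~ f + tt + t2 + f:tt + f:t2)
      # null model keeps the sum-to-zero slope deviations but drops the
      # global linear and quadratic terms
      S <- stats::contr.sum(L)[f, , drop = FALSE]
      Xdev <- cbind(S * tt, S * t2)
      red <- stats::lm(y ~ f + Xdev)
    }
  }
  beta <- unname(stats::coef(fit)[["tt"]])
  rdf <- fit$df.residual
  rss <- sum(stats::resid(fit)^2)
  if (rdf <= 0 || rss <= 1e-12 * max(1, sum(y^2))) {
    warning("global_rate_test: zero residual degrees of freedom or perfect fit; p undefined.")
    return(progression_row(method, beta, NA_real_, FALSE, alpha, n))
  }
  if (trend == "linear") {
    se <- sqrt(diag(stats::vcov(fit)))[["tt"]]
    p <- 2 * stats::pt(-abs(beta / se), rdf)
  } else {
    a <- stats::anova(red, fit)
    p <- a$`Pr(>F)`[2]
  }
  progression_row(method, beta, p, is.finite(p) && p < alpha, alpha, n)
}

progression_row <- function(method, rate, p, flagged, alpha, n) {
  tibble::tibble(method = method, global_rate = rate, p_value = p,
                 flagged = flagged, alpha = alpha, n_visits = n)
}

#' Mean-deviation slope comparator test
#'
#' Ordinary least squares of MD on time; progression is a significantly
#' negative slope, so the reported p-value is the one-sided t-test
#' probability of `slope < 0` and a series is flagged when it falls below
#' `alpha`.
#'
#' @param md Numeric vector of per-visit mean deviations (dB).
#' @param times Visit times in years (same length).
#' @param alpha Significance level (default 0.05, one-sided).
#' @return A one-row tibble as in [global_rate_test()], `method = "md"`.
#' @export
md_slope_test <- function(md, times, alpha = 0.05) {
  n <- length(md)
  if (n < 3 || length(times) != n) {
    warning("md_slope_test: fewer than 3 visits; no test.")
    return(progression_row("md", NA_real_, NA_real_, FALSE, alpha, n))
  }
  fit <- stats::lm(md ~ times)
  rdf <- fit$df.residual
  rss <- sum(stats::resid(fit)^2)
  slope <- unname(stats::coef(fit)[["times"]])
  if (rdf <= 0 || rss <= 1e-12 * max(1, sum(md^2))) {
    warning("md_slope_test: perfect fit; p undefined.")
    return(progression_row("md", slope, NA_real_, FALSE, alpha, n))
  }
  se <- sqrt(diag(stats::vcov(fit)))[["times"]]
  p <- stats::pt(slope / se, rdf)  # one-sided: slope < 0
  progression_row("md", slope, p, is.finite(p) && p < alpha, alpha, n)
}

#' Per-patient progression calls on a cohort
#'
#' For each glaucoma-status patient, truncates the series to visits at or
#' before `cutoff_years`, requires the method's minimum number of visits
#' (3, or 4 for the quadratic test), and runs the chosen test: latent
#' global-rate tests encode the truncated fields with `fit`, the MD
#' comparator regresses the unweighted TD mean on time. Patients with too
#' few eligible visits are excluded (reported in the `eligible` column).
#'
#' @param data A [vf_cohort] tibble.
#' @param fit A `vfvae_fit` (may be `NULL` for `method = "md"`).
#' @param method `"vae_linear"`, `"vae_nonlinear"` or `"md"`.
#' @param cutoff_years Include visits with `years <= cutoff_years`
#'   (default `Inf` = all follow-up).
#' @param alpha Significance level.
#' @param statuses Which status labels form the evaluation population
#'   (default glaucoma only, the study's hit-rate population).
#' @return Tibble with one row per patient: `patient_id`, `n_visits`,
#'   `eligible`, `global_rate`, `p_value`, `flagged`.
#' @export
progression_flags <- function(data, fit = NULL,
                              method = c("vae_linear", "vae_nonlinear", "md"),
                              cutoff_years = Inf, alpha = 0.05,
                              statuses = "glaucoma") {
  method <- match.arg(method)
  min_n <- if (method == "vae_nonlinear") 4L else 3L
  pop <- data[data$status %in% statuses & data$years <= cutoff_years, ,
              drop = FALSE]
  empty <- tibble::tibble(patient_id = character(), n_visits = integer(),
                          eligible = logical(), global_rate = numeric(),
                          p_value = numeric(), flagged = logical())
  if (nrow(pop) == 0) return(empty)
  if (method != "md") {
    if (is.null(fit)) rlang::abort("latent methods need a fitted model.")
    enc <- vf_encode(pop, fit)
    zcols <- grep("^z_", names(enc))
  }
  ids <- unique(pop$patient_id)
  purrr::map_dfr(ids, function(id) {
    rows <- which(pop$patient_id == id)
    nv <- length(rows)
    if (nv < min_n) {
      return(tibble::tibble(patient_id = id, n_visits = nv, eligible = FALSE,
                            global_rate = NA_real_, p_value = NA_real_,
                            flagged = NA))
    }
    res <- if (method == "md") {
      md_slope_test(field_md(td_matrix(pop[rows, ])), pop$years[rows], alpha)
    } else {
      suppressWarnings(global_rate_test(
        as.matrix(enc[rows, zcols]), pop$years[rows], alpha,
        trend = if (method == "vae_linear") "linear" else "quadratic"))
    }
    tibble::tibble(patient_id = id, n_visits = nv, eligible = TRUE,
                   global_rate = res$global_rate, p_value = res$p_value,
                   flagged = res$flagged)
  })
}

#' Progression hit rate at a follow-up cutoff
#'
#' Fraction of eligible (>= 3 or 4 visits on or before the cutoff)
#' glaucoma patients flagged as progressing. Because every test is applied
#' at the 0.05 p-value cutoff, specificities are matched at 95% and hit
#' rates are directly comparable across methods.
#'
#' @inheritParams progression_flags
#' @return One-row tibble: `method`, `cutoff_years`, `n_eligible`,
#'   `n_flagged`, `hit_rate`.
#' @export
hit_rate <- function(data, fit = NULL,
                     method = c("vae_linear", "vae_nonlinear", "md"),
                     cutoff_years = Inf, alpha = 0.05,
                     statuses = "glaucoma") {
  method <- match.arg(method)
  flags <- progression_flags(data, fit, method, cutoff_years, alpha, statuses)
  el <- flags[flags$eligible, , drop = FALSE]
  tibble::tibble(method = method, cutoff_years = cutoff_years,
                 n_eligible = nrow(el), n_flagged = sum(el$flagged),
                 hit_rate = if (nrow(el)) mean(el$flagged) else NA_real_)
}

#' Percentile bootstrap interval for a flagged proportion
#'
#' Resamples patients with replacement and returns percentile quantiles of
#' the flagged proportion.
#'
#' @param flags Logical vector of per-patient progression calls.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level Interval level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(flags, n_boot = 1000L, level = 0.95, seed = 1L) {
  stopifnot(length(flags) >= 1)
  flags <- as.logical(flags)
  props <- withr::with_seed(seed, {
    rowMeans(matrix(sample(flags, length(flags) * n_boot, replace = TRUE),
                    n_boot))
  })
  q <- stats::quantile(props, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Fold-averaged progression hit-rate report
#'
#' Computes hit rates with bootstrap confidence intervals for each trained
#' model (latent linear and quadratic tests) and the MD comparator, at each
#' follow-up cutoff, averaged across cross-validation folds.
#'
#' @param fold_fits Tibble with one row per (fold, model): columns `fold`,
#'   `latent_dim`, `fit` (list of `vfvae_fit`) and `test` (list of
#'   [vf_cohort] test-split tibbles).
#' @param cutoffs Follow-up cutoffs in years (default `c(2, 4, 6, Inf)`).
#' @param alpha Significance level.
#' @param n_boot,seed Bootstrap control.
#' @return Tibble: `method`, `latent_dim`, `cutoff_years`, `hit_rate`,
#'   `ci_lo`, `ci_hi`, `n_patients` (averages across folds; the MD rows
#'   carry `latent_dim = NA` since MD ignores the latent space).
#' @export
progression_report <- function(fold_fits, cutoffs = c(2, 4, 6, Inf),
                               alpha = 0.05, n_boot = 1000L, seed = 1L) {
  cells <- purrr::map_dfr(seq_len(nrow(fold_fits)), function(i) {
    fit <- fold_fits$fit[[i]]
    test <- fold_fits$test[[i]]
    purrr::map_dfr(cutoffs, function(cu) {
      purrr::map_dfr(c("vae_linear", "vae_nonlinear", "md"), function(m) {
        fl <- progression_flags(test, fit, m, cu, alpha)
        el <- fl[fl$eligible, , drop = FALSE]
        ci <- if (nrow(el)) bootstrap_ci(el$flagged, n_boot, seed = seed)
              else c(lo = NA_real_, hi = NA_real_)
        tibble::tibble(
          fold = fold_fits$fold[i],
          method = m,
          latent_dim = if (m == "md") NA_integer_ else
            fold_fits$latent_dim[i],
          cutoff_years = cu, hit_rate = mean(el$flagged),
          ci_lo = ci[["lo"]], ci_hi = ci[["hi"]], n_patients = nrow(el))
      })
    })
  })
  cells |>
    dplyr::distinct() |>  # md rows duplicate across latent dims within a fold
    dplyr::group_by(.data$method, .data$latent_dim, .data$cutoff_years) |>
    dplyr::summarise(hit_rate = mean(.data$hit_rate),
                     ci_lo = mean(.data$ci_lo), ci_hi = mean(.data$ci_hi),
                     n_patients = mean(.data$n_patients), .groups = "drop")
}
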