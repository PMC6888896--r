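test_that("latent trajectories extrapolate exactly for exact trends", {
  t <- c(0, 0.5, 1.1, 2.0, 2.8, 3.5)
  targ <- c(4.2, 5.0)
  z_lin <- cbind(1 - 0.5 * t, -2 + 0.25 * t)
  p <- predict_latent_trajectory(z_lin, t, k = 4, targ, trend = "linear")
  expect_equal(p, cbind(1 - 0.5 * targ, -2 + 0.25 * targ),
               tolerance = 1e-10)
  z_quad <- cbind(1 + 2 * t - 0.3 * t^2)
  pq <- predict_latent_trajectory(z_quad, t, k = 4, targ, trend = "quadratic")
  expect_equal(as.vector(pq), 1 + 2 * targ - 0.3 * targ^2, tolerance = 1e-9)

  # normal-equations oracle per dimension, noisy case
  withr::with_seed(21, z <- matrix(rnorm(6 * 3), 6, 3))
  p <- predict_latent_trajectory(z, t, k = 5, targ, trend = "linear")
  X <- cbind(1, t[1:5])
  B <- solve(t(X) %*% X, t(X) %*% z[1:5, ])
  expect_equal(p, cbind(1, targ) %*% B, tolerance = 1e-9)

  expect_error(predict_latent_trajectory(z, t, k = 3, targ,
                                         trend = "quadratic"), "required 4")
  expect_error(predict_latent_trajectory(z[1:2, ], t[1:2], k = 3, targ),
               "fewer than k")
})

test_that("pointwise regression predicts exactly and matches its oracle", {
  rate <- seq(-2, 0, length.out = 52)
  base <- seq(-10, 0, length.out = 52)
  s <- toy_series(rate = rate, base = base, times = c(0, 1, 2, 3, 4.5))
  rec <- predict_field_pointwise(s, k = 3, horizon = 2)
  expect_equal(rec$predicted_td[[1]], base + 4.5 * rate, tolerance = 1e-9)
  expect_equal(rec$mae, 0, tolerance = 1e-9)

  # two equal values at a location give a constant prediction there
  s2 <- toy_series(rate = rep(0, 52), base = base, times = c(0, 1, 2, 3))
  rec2 <- predict_field_pointwise(s2, k = 2, horizon = 2)
  expect_equal(rec2$predicted_td[[1]], base, tolerance = 1e-9)

  # per-location normal-equations oracle on a noisy series
  s3 <- toy_series(rate = rate, base = base, times = c(0, 1, 2, 3, 4),
                   noise_sd = 1.5, seed = 4)
  rec3 <- predict_field_pointwise(s3, k = 4, horizon = 1)
  X <- cbind(1, s3$years[1:4])
  B <- solve(t(X) %*% X, t(X) %*% td_matrix(s3)[1:4, ])
  expect_equal(rec3$predicted_td[[1]],
               as.vector(c(1, s3$years[5]) %*% B), tolerance = 1e-9)
})

test_that("two-stage predictions stay in range and score 52 locations", {
  fit <- small_fit()
  s <- toy_series(rate = rep(-1.5, 52), base = rep(-2, 52),
                  times = seq(0, 5, by = 0.625), noise_sd = 1, seed = 3)
  rec <- predict_field_vae(s, fit, k = 3, horizon = 5)
  pred <- rec$predicted_td[[1]]
  expect_length(pred, 52)
  expect_true(all(pred >= fit$norm$td_min & pred <= fit$norm$td_max))
  expect_true(is.finite(rec$mae))
  # the MAE is the mean of exactly the 52 per-location absolute errors
  expect_equal(rec$mae, mean(abs(pred - rec$observed_td[[1]])),
               tolerance = 1e-12)
  expect_equal(rec$observed_td[[1]], as.vector(td_matrix(s)[8, ]),
               tolerance = 1e-12)
})

test_that("predictions use only the first k visits", {
  fit <- small_fit()
  s <- toy_series(rate = rep(-1, 52), base = rep(-1, 52),
                  times = seq(0, 5, by = 0.5), noise_sd = 1, seed = 6)
  k <- 4
  h <- 2
  corrupt <- s
  # corrupt every visit after k except the target
  bad <- setdiff((k + 1):nrow(s), k + h)
  corrupt[bad, td_cols()] <- as.list(rep(-35, 52))
  for (f in list(
    function(d) predict_field_vae(d, fit, k, h),
    function(d) predict_field_pointwise(d, k, h)
  )) {
    expect_equal(f(corrupt)$predicted_td[[1]], f(s)$predicted_td[[1]],
                 tolerance = 1e-12)
    expect_equal(f(corrupt)$mae, f(s)$mae, tolerance = 1e-12)
  }
})

test_that("the scenario grid respects each series' length", {
  fit <- small_fit()
  s <- toy_series(times = seq(0, 5.25, by = 0.75), noise_sd = 0.5,
                  rate = rep(-0.8, 52), seed = 9)  # exactly 8 visits
  rec <- evaluate_predictions(s, fit)
  vae_lin <- rec[rec$method == "vae" & rec$trend == "linear", ]
  # 8 visits: (k=3, h<=5), (k=5, h<=3), (k=7, h=1)
  expect_identical(nrow(vae_lin), 9L)
  expect_setequal(paste(vae_lin$k_input, vae_lin$horizon),
                  c(paste(3, 1:5), paste(5, 1:3), paste(7, 1)))
  # quadratic latent fits require k >= 4
  vae_quad <- rec[rec$method == "vae" & rec$trend == "quadratic", ]
  expect_false(any(vae_quad$k_input == 3))
  expect_identical(nrow(vae_quad), 4L)
  # one pointwise baseline per scenario
  expect_identical(nrow(rec[rec$method == "pointwise", ]), 9L)
})

test_that("the one-sided Wilcoxon comparison matches exact enumeration", {
  # all six differences negative: exact tail is 1/2^6
  v <- c(1.0, 1.1, 0.9, 1.2, 0.8, 1.05)
  r <- compare_wilcoxon(v, v + 0.5)
  expect_equal(r$p_value, 1 / 64, tolerance = 1e-12)
  expect_equal(r$alpha, 0.05 / 900, tolerance = 1e-15)
  expect_false(r$significant)

  # identical vectors carry no evidence
  r0 <- compare_wilcoxon(v, v)
  expect_identical(r0$p_value, 1)
  expect_identical(r0$n_zero, 6L)

  # exhaustive sign-flip enumeration oracle for n <= 10 without ties
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    mean(w_all <= w_obs)
  }
  withr::with_seed(30, {
    for (i in 1:10) {
      n <- sample(5:10, 1)
      d <- round(rnorm(n), 3)
      while (anyDuplicated(abs(d)) || any(d == 0)) d <- round(rnorm(n), 3)
      r <- compare_wilcoxon(d, rep(0, n))
      expect_equal(r$p_value, enum_p(d), tolerance = 1e-12)
    }
  })
  expect_error(compare_wilcoxon(1:3, 1:4), "paired")
})

test_that("prediction summaries pair the baseline with each latent trend", {
  fit <- small_fit()
  cohort <- small_sim()$cohort
  keep <- names(which(table(cohort$patient_id) >= 6))
  rec <- evaluate_predictions(cohort[cohort$patient_id %in% keep, ], fit,
                              k_inputs = c(3L, 5L), horizons = 1L)
  s <- summarise_predictions(rec, populations = c("all", "glaucoma"))
  expect_setequal(unique(s$method), c("vae", "pointwise"))
  expect_true(all(c("mean_mae", "median_mae", "q1_mae", "q3_mae",
                    "p_value") %in% names(s)))
  # quadratic cells exist only for k >= 4 and carry a paired baseline row
  quad <- s[s$trend == "quadratic", ]
  expect_true(all(quad$k_input >= 4))
  expect_true(all(c("vae", "pointwise") %in% quad$method))
  # glaucoma population is a subset of all
  expect_lte(max(s$n[s$population == "glaucoma"]),
             max(s$n[s$population == "all"]))
})
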