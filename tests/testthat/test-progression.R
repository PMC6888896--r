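test_that("the stacked zero-sum fit reduces to plain OLS when L = 1", {
  t <- c(0, 0.5, 1.2, 2.0, 3.1)
  withr::with_seed(8, y <- 1 - 0.4 * t + rnorm(5, 0, 0.3))
  r <- global_rate_test(y, t)
  s <- summary(lm(y ~ t))
  expect_equal(r$global_rate, unname(coef(s)[2, 1]), tolerance = 1e-12)
  expect_equal(r$p_value, unname(coef(s)[2, 4]), tolerance = 1e-12)
  expect_identical(r$flagged, r$p_value < 0.05)
})

test_that("on a shared time grid the global rate is the mean per-feature slope", {
  withr::with_seed(9, {
    for (i in 1:10) {
      n <- sample(4:9, 1)
      L <- sample(2:8, 1)
      t <- sort(runif(n, 0, 6))
      z <- matrix(rnorm(n * L), n, L)
      r <- global_rate_test(z, t)
      slopes <- apply(z, 2, function(y) unname(coef(lm(y ~ t))[2]))
      expect_lt(abs(r$global_rate - mean(slopes)), 1e-9)
    }
  })
})

test_that("degenerate perfect fits report the rate but no p-value", {
  t <- 0:4
  z <- matrix(rep(1 + 2 * t, 3), ncol = 3)
  expect_warning(r <- global_rate_test(z, t), "perfect fit|degrees")
  expect_equal(r$global_rate, 2, tolerance = 1e-9)
  expect_true(is.na(r$p_value))
  expect_false(r$flagged)
  expect_warning(r2 <- global_rate_test(matrix(rnorm(4), 2), 0:1), "visit")
  expect_false(r2$flagged)
})

test_that("the quadratic model recovers exact coefficients and its F oracle", {
  t <- c(0, 0.6, 1.1, 2.3, 3.2, 4.1)
  z <- matrix(rep(1 + 2 * t + 3 * t^2, 4), ncol = 4)
  expect_warning(r <- global_rate_test(z, t, trend = "quadratic"))
  expect_equal(r$global_rate, 2, tolerance = 1e-8)

  # nested-RSS oracle built from first principles (explicit design matrices)
  withr::with_seed(10, {
    n <- 7
    L <- 3
    tt <- sort(runif(n, 0, 5))
    z <- matrix(0.5 - 0.3 * tt + 0.05 * tt^2 + rnorm(n * L, 0, 0.4), n, L)
  })
  r <- global_rate_test(z, tt, trend = "quadratic")
  y <- as.vector(z)
  f <- rep(seq_len(L), each = n)
  tl <- rep(tt, L)
  Fm <- stats::model.matrix(~ 0 + factor(f))
  S <- stats::contr.sum(L)[f, , drop = FALSE]
  Xfull <- cbind(Fm, tl, tl^2, S * tl, S * tl^2)
  Xred <- cbind(Fm, S * tl, S * tl^2)
  rss <- function(X) sum(qr.resid(qr(X), y)^2)
  df1 <- length(y) - ncol(Xfull)
  Fstat <- ((rss(Xred) - rss(Xfull)) / 2) / (rss(Xfull) / df1)
  p_oracle <- pf(Fstat, 2, df1, lower.tail = FALSE)
  expect_equal(r$p_value, p_oracle, tolerance = 1e-9)
})

test_that("null latent series keep the advertised type-I error and p uniformity", {
  tt <- seq(0, 5, length.out = 8)
  n_sim <- 800
  withr::with_seed(14, {
    res <- vapply(seq_len(n_sim), function(i) {
      z <- matrix(rnorm(8 * 8), 8, 8)
      c(global_rate_test(z, tt)$p_value,
        global_rate_test(z, tt, trend = "quadratic")$p_value)
    }, numeric(2))
  })
  tol <- 3 * sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(mean(res[1, ] < 0.05) - 0.05), tol)
  expect_lt(abs(mean(res[2, ] < 0.05) - 0.05), tol)
  # p-values are uniform under the null
  expect_gt(suppressWarnings(ks.test(res[1, ], "punif")$p.value), 0.01)
  expect_gt(suppressWarnings(ks.test(res[2, ], "punif")$p.value), 0.01)
})

test_that("the MD comparator is one-sided for deterioration", {
  t <- seq(0, 4.5, by = 0.5)
  withr::with_seed(15, md <- -1 - 1 * t + rnorm(10, 0, 0.15))
  r <- md_slope_test(md, t)
  expect_true(r$flagged)
  expect_lt(r$global_rate, 0)
  # an equally strong improvement is never called progression
  r_up <- md_slope_test(-md, t)
  expect_false(r_up$flagged)
  expect_gt(r_up$p_value, 0.95)
  # closed-form t oracle
  fit <- lm(md ~ t)
  t_stat <- coef(summary(fit))[2, 3]
  expect_equal(r$p_value, pt(t_stat, 8), tolerance = 1e-12)
})

test_that("follow-up cutoffs truncate the visit set as stated", {
  s <- toy_series(times = c(0, 1, 3, 5), noise_sd = 0.3)
  fl4 <- progression_flags(s, method = "md", cutoff_years = 4)
  expect_identical(fl4$n_visits, 3L)   # visits at 0, 1, 3 only
  fl2 <- progression_flags(s, method = "md", cutoff_years = 2)
  expect_identical(fl2$n_visits, 2L)
  expect_false(fl2$eligible)           # too few visits before the cutoff
  flInf <- progression_flags(s, method = "md", cutoff_years = Inf)
  expect_identical(flInf$n_visits, 4L)
  # visit sets are nested across growing cutoffs
  expect_lte(fl2$n_visits, fl4$n_visits)
  expect_lte(fl4$n_visits, flInf$n_visits)
})

test_that("hit rate is 1 for uniformly strong deterioration and ~5% under the null", {
  strong <- dplyr::bind_rows(lapply(1:12, function(i) {
    toy_series(rate = rep(-2, 52), times = seq(0, 4, by = 0.5),
               noise_sd = 0.05, id = sprintf("S%05d", i), seed = i)
  }))
  hr <- hit_rate(strong, method = "md")
  expect_identical(hr$hit_rate, 1)
  expect_identical(hr$n_eligible, 12L)

  nc <- null_cohort(300, n_visits = 8, followup_years = 5, seed = 33)
  hr0 <- hit_rate(nc, method = "md")
  expect_lt(abs(hr0$hit_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 300))
})

test_that("bootstrap intervals behave like percentile bootstraps", {
  expect_identical(bootstrap_ci(rep(TRUE, 40), seed = 1),
                   c(lo = 1, hi = 1))
  expect_identical(bootstrap_ci(rep(FALSE, 40), seed = 1),
                   c(lo = 0, hi = 0))
  flags <- c(rep(TRUE, 30), rep(FALSE, 70))
  expect_identical(bootstrap_ci(flags, seed = 5), bootstrap_ci(flags, seed = 5))
  ci <- bootstrap_ci(flags, seed = 5)
  expect_lt(ci[["lo"]], 0.3)
  expect_gt(ci[["hi"]], 0.3)

  # coverage: ~95% of intervals over Bernoulli(0.3) samples cover 0.3
  withr::with_seed(6, {
    cover <- vapply(1:150, function(i) {
      fl <- runif(200) < 0.3
      ci <- bootstrap_ci(fl, n_boot = 400, seed = i)
      ci[["lo"]] <= 0.3 && 0.3 <= ci[["hi"]]
    }, logical(1))
  })
  expect_gt(mean(cover), 0.88)
})

test_that("the fold-averaged report covers every method and cutoff", {
  fit <- small_fit()
  test_split <- split_patients(small_sim()$cohort, seed = 42)
  test_split <- test_split[test_split$split == "test", ]
  fold_fits <- tibble::tibble(fold = 1L, latent_dim = 2L,
                              fit = list(fit), test = list(test_split))
  rep <- progression_report(fold_fits, cutoffs = c(2, Inf), n_boot = 50)
  expect_setequal(rep$method, c("vae_linear", "vae_nonlinear", "md"))
  expect_setequal(unique(rep$cutoff_years), c(2, Inf))
  expect_identical(nrow(rep), 6L)
  expect_true(all(rep$ci_lo <= rep$hit_rate + 1e-12 &
                    rep$hit_rate <= rep$ci_hi + 1e-12, na.rm = TRUE))
  # MD rows do not depend on the latent space
  expect_true(all(is.na(rep$latent_dim[rep$method == "md"])))
})
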