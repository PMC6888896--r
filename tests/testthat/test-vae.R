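test_that("MMD matches a brute-force double sum and its basic identities", {
  # explicit double-sum oracle on 3-point 1-D samples
  x <- c(-0.4, 0.1, 1.3)
  y <- c(0.2, 0.9, -1.1)
  sigma <- 0.8
  k <- function(a, b) exp(-(a - b)^2 / (2 * sigma^2))
  brute <- function(u, v) {
    s <- 0
    for (a in u) for (b in v) s <- s + k(a, b)
    s / (length(u) * length(v))
  }
  oracle <- brute(x, x) + brute(y, y) - 2 * brute(x, y)
  expect_lt(abs(mmd(x, y, sigma) - oracle), 1e-12)

  # symmetry, nonnegativity, zero at equality
  withr::with_seed(4, {
    for (i in 1:20) {
      a <- matrix(rnorm(12), 4)
      b <- matrix(rnorm(15), 5)
      expect_equal(mmd(a, b, 1.3), mmd(b, a, 1.3), tolerance = 1e-12)
      expect_gte(mmd(a, b, 1.3), 0)
      expect_lt(abs(mmd(a, a, 1.3)), 1e-12)
    }
  })
  expect_error(mmd(matrix(0, 0, 2), matrix(0, 3, 2)), "empty")
  expect_error(mmd(matrix(0, 2, 2), matrix(0, 2, 3)), "column")
})

test_that("analytic gradients agree with finite differences", {
  cfg <- vae_config(latent_dim = 3, channels = c(2, 3), mmd_weight = 5,
                    batch_size = 4)
  gm <- vfvae:::vae_geoms(cfg$channels)
  withr::with_seed(42, {
    par <- vfvae:::vae_init_params(cfg)
    # perturb away from 0 so no ReLU preactivation sits exactly on its kink
    par <- lapply(par, function(p) p + stats::rnorm(length(p), 0, 0.05))
    X <- matrix(runif(4 * 144), 4)
    prior <- matrix(rnorm(4 * 3), 4)
  })
  res <- vfvae:::vae_batch(par, X, prior, cfg, gm, grads = TRUE)
  total_at <- function(par) {
    vfvae:::vae_batch(par, X, prior, cfg, gm, grads = FALSE)$total
  }
  withr::with_seed(7, {
    for (nm in names(par)) {
      for (i in sample(length(par[[nm]]), min(4, length(par[[nm]])))) {
        eps <- 1e-6
        up <- par; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- par; dn[[nm]][i] <- dn[[nm]][i] - eps
        fd <- (total_at(up) - total_at(dn)) / (2 * eps)
        expect_equal(res$grads[[nm]][i], fd, tolerance = 1e-3)
      }
    }
  })
})

test_that("the network honours the 12 -> 6 -> 3 -> L -> 3 -> 6 -> 12 contract", {
  gm <- vfvae:::vae_geoms(c(4, 6))
  expect_identical(gm$enc1$Hout, 6L)
  expect_identical(gm$enc2$Hout, 3L)
  expect_identical(gm$dec1$H, 6L)   # upsamples 3 -> 6
  expect_identical(gm$dec2$H, 12L)  # upsamples 6 -> 12
  expect_identical(gm$dec3$Hout, 12L)
  for (L in c(1, 5, 15)) {
    cfg <- vae_config(latent_dim = L, channels = c(3, 4))
    fit <- list(params = withr::with_seed(1, vfvae:::vae_init_params(cfg)),
                config = cfg, geoms = vfvae:::vae_geoms(cfg$channels))
    z <- encode_images(fit, matrix(runif(5 * 144), 5))
    expect_identical(dim(z), c(5L, as.integer(L)))
    out <- decode_latent(fit, z)
    expect_identical(dim(out), c(5L, 144L))
    expect_true(all(out > 0 & out < 1))
  }
})

test_that("encoding is deterministic and batch-consistent", {
  fit <- small_fit()
  X <- fields_to_images(small_sim()$cohort[1:6, ])
  z <- encode_images(fit, X)
  expect_identical(encode_images(fit, X), z)
  one_by_one <- do.call(rbind, lapply(1:6, function(i) {
    encode_images(fit, X[i, , drop = FALSE])
  }))
  expect_equal(one_by_one, z, tolerance = 1e-12)
  expect_identical(decode_latent(fit, z), decode_latent(fit, z))
  expect_error(encode_images(fit, X[, 1:10]), "144")
  expect_error(decode_latent(fit, cbind(z, 0)), "columns")
})

test_that("loss components are consistent and the MMD term switches off", {
  fit <- small_fit()
  X <- fields_to_images(small_sim()$cohort[1:30, ])
  prior <- withr::with_seed(2, matrix(rnorm(30 * 2), 30))
  l <- vae_loss(fit, X, prior)
  expect_equal(l$total, l$reconstruction + l$regularization,
               tolerance = 1e-12)
  # recompute both components independently of the loss path
  xhat <- decode_latent(fit, encode_images(fit, X))
  expect_equal(l$reconstruction, mean((xhat - X)^2), tolerance = 1e-6)
  expect_equal(l$regularization,
               fit$config$mmd_weight *
                 mmd(encode_images(fit, X), prior, fit$config$mmd_bandwidth),
               tolerance = 1e-6)
  fit0 <- fit
  fit0$config$mmd_weight <- 0
  l0 <- vae_loss(fit0, X, prior)
  expect_identical(l0$total, l0$reconstruction)
  expect_identical(l0$regularization, 0)
})

test_that("training selects the epoch with minimal validation loss", {
  fit <- small_fit()
  h <- tidy(fit)
  val <- h[h$split == "validation", ]
  expect_identical(fit$selected_epoch, val$epoch[which.min(val$total)])
  expect_identical(nrow(h), 2L * fit$config$epochs)
  # training decreased the loss overall
  tr <- h[h$split == "train", ]
  expect_lt(tail(tr$total, 1), tr$total[1])
  expect_lt(min(val$total), val$total[1])
})

test_that("training is reproducible and aligns the latent space to the prior", {
  sp <- split_patients(small_sim()$cohort, seed = 42)
  cfg <- vae_config(latent_dim = 2, channels = c(4, 8), epochs = 4,
                    lr = 1e-3, seed = 31)
  f1 <- vae_train(sp[sp$split == "train", ], sp[sp$split == "validation", ],
                  cfg)
  f2 <- vae_train(sp[sp$split == "train", ], sp[sp$split == "validation", ],
                  cfg)
  expect_identical(f1$loss_history, f2$loss_history)
  expect_identical(f1$params, f2$params)

  # after real training the encoded validation batch is closer to the prior
  # than at initialization
  fit <- small_fit()
  Xval <- fields_to_images(convert_to_right_eye(
    sp[sp$split == "validation", ]))
  prior <- withr::with_seed(5, matrix(rnorm(500 * 2), 500))
  init <- list(params = withr::with_seed(fit$config$seed,
                                         vfvae:::vae_init_params(fit$config)),
               config = fit$config, geoms = fit$geoms)
  m_init <- mmd(encode_images(init, Xval), prior, fit$config$mmd_bandwidth)
  m_fit <- mmd(encode_images(fit, Xval), prior, fit$config$mmd_bandwidth)
  expect_lt(m_fit, m_init)
})

test_that("the autoencoder can overfit a single repeated field", {
  img <- fields_to_images(convert_to_right_eye(small_sim()$cohort[3, ]))
  X <- img[rep(1, 200), ]
  cfg <- vae_config(latent_dim = 2, channels = c(8, 16), epochs = 250,
                    batch_size = 50, lr = 3e-3, seed = 2)
  fit <- vae_train(X, X[1:20, ], cfg)
  rec <- decode_latent(fit, encode_images(fit, img))
  expect_lt(mean(abs(rec - img)), 0.02)
})

test_that("higher-dimensional latent spaces reconstruct at least as well", {
  sp <- split_patients(small_sim()$cohort, seed = 42)
  sw <- sweep_latent_dims(sp[sp$split == "train", ],
                          sp[sp$split == "validation", ], dims = c(1, 8),
                          config = vae_config(channels = c(8, 16),
                                              epochs = 80, lr = 1e-3,
                                              seed = 12))
  expect_identical(sw$latent_dim, c(1, 8))
  for (i in seq_len(nrow(sw))) {
    z <- encode_images(sw$fit[[i]], matrix(runif(3 * 144), 3))
    expect_identical(ncol(z), as.integer(sw$latent_dim[i]))
  }
  # the richer latent space achieves at least as good a reconstruction
  # once trained to convergence (compare the best validation MSE, which
  # unlike the selected-epoch value is not traded off against the
  # latent-matching term)
  best_recon <- vapply(sw$fit, function(f) {
    h <- f$loss_history
    min(h$reconstruction[h$split == "validation"])
  }, numeric(1))
  expect_lte(best_recon[sw$latent_dim == 8], best_recon[sw$latent_dim == 1])
})

test_that("model checkpoints round-trip through JSON", {
  fit <- small_fit()
  path <- withr::local_tempfile(fileext = ".json")
  write_vae(fit, path)
  back <- read_vae(path)
  X <- fields_to_images(small_sim()$cohort[1:4, ])
  expect_equal(encode_images(back, X), encode_images(fit, X),
               tolerance = 1e-12)
  expect_equal(back$selected_epoch, fit$selected_epoch)
  expect_equal(back$config$mmd_bandwidth, fit$config$mmd_bandwidth)
})

test_that("broom methods and the training-curve plot work", {
  fit <- small_fit()
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$latent_dim, 2L)
  expect_s3_class(autoplot(fit), "ggplot")
})
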