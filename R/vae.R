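#' Configuration of the generalized (MMD-regularized) autoencoder
#'
#' The network follows a fixed shape contract: a 12 x 12 input is taken
#' through two 3 x 3, stride-2 convolutions (12 -> 6 -> 3), reshaped, and
#' mapped by an identity-activation dense layer to `latent_dim` features; the
#' decoder mirrors it (dense, reshape, two stride-2 transposed convolutions
#' 3 -> 6 -> 12, and a final 3 x 3 stride-1 layer with sigmoid activation).
#' All hidden activations are ReLU. Instead of a per-point KL term, training
#' penalizes the maximum mean discrepancy between the batch of encoded
#' features and a standard-normal prior sample, so the encoder is
#' deterministic and only the aggregate latent distribution is regularized.
#'
#' @param latent_dim Number of latent features `L` (the study sweeps 1..15).
#' @param channels Feature channels of the two convolutional layers.
#' @param lr Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param mmd_weight Weight `lambda` of the MMD penalty relative to the
#'   per-pixel mean-squared reconstruction error. The default 10 balances
#'   the two terms: on these images the squared-MMD of a mismatched batch
#'   (~0.1-1) is of the same order as the pixel MSE (~0.05-0.2), so a much
#'   larger weight would let the latent-matching term swamp reconstruction.
#' @param mmd_bandwidth Gaussian-kernel bandwidth `sigma`; default
#'   `sqrt(latent_dim)` (i.e. `sigma^2 = L`), scaling with the latent
#'   dimension so the kernel stays informative as `L` grows.
#' @param seed Integer seed; fixes initialization, shuffling and prior draws.
#' @return A list of class `vae_config`.
#' @export
vae_config <- function(latent_dim = 8L, channels = c(32L, 64L),
                       lr = 1e-4, epochs = 100L, batch_size = 100L,
                       mmd_weight = 10, mmd_bandwidth = NULL,
                       seed = 1L) {
  stopifnot(latent_dim >= 1, length(channels) == 2, all(channels >= 1),
            lr > 0, epochs >= 1, batch_size >= 2, mmd_weight >= 0)
  if (is.null(mmd_bandwidth)) mmd_bandwidth <- sqrt(latent_dim)
  structure(
    list(latent_dim = as.integer(latent_dim), channels = as.integer(channels),
         kernel = 3L, stride = 2L, lr = lr, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), mmd_weight = mmd_weight,
         mmd_bandwidth = mmd_bandwidth, seed = as.integer(seed)),
    class = "vae_config"
  )
}

#' Squared maximum mean discrepancy between two samples
#'
#' Biased (V-statistic) estimator with Gaussian kernel
#' `k(a, b) = exp(-||a - b||^2 / (2 sigma^2))`: the mean kernel value over
#' all x-pairs plus the mean over all y-pairs minus twice the mean over
#' cross-pairs. Always nonnegative and symmetric; zero when the samples are
#' identical.
#'
#' @param x,y Numeric matrices with matching column counts (rows = samples).
#' @param bandwidth Kernel bandwidth `sigma`.
#' @return A nonnegative scalar.
#' @examples
#' mmd(matrix(rnorm(20), 10), matrix(rnorm(20), 10), bandwidth = 1)
#' @export
mmd <- function(x, y, bandwidth = 1) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(dim(y))) y <- matrix(y, ncol = 1)
  if (nrow(x) == 0 || nrow(y) == 0) rlang::abort("mmd: empty sample.")
  if (ncol(x) != ncol(y)) rlang::abort("mmd: column counts differ.")
  mean(gauss_kernel(x, x, bandwidth)) +
    mean(gauss_kernel(y, y, bandwidth)) -
    2 * mean(gauss_kernel(x, y, bandwidth))
}

gauss_kernel <- function(x, y, sigma) {
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

# gradient of mmd(x, y) with respect to x (y treated as fixed prior sample)
mmd_grad_x <- function(x, y, sigma) {
  n <- nrow(x)
  m <- nrow(y)
  kxx <- gauss_kernel(x, x, sigma)
  kxy <- gauss_kernel(x, y, sigma)
  gx <- (2 / (n^2 * sigma^2)) * (kxx %*% x - rowSums(kxx) * x)
  gxy <- (2 / (n * m * sigma^2)) * (kxy %*% y - rowSums(kxy) * x)
  gx - gxy
}

# ---- parameter initialization -------------------------------------------

# decoder channels mirror the encoder (c2 -> c1 across the upsampling
# stages) and narrow to a few feature maps at full 12 x 12 resolution
# before the stride-1 sigmoid output layer
dec_channels <- function(c1) min(c1, max(4L, c1 %/% 4L))

vae_geoms <- function(channels) {
  c1 <- channels[1]
  c3 <- dec_channels(c1)
  list(
    enc1 = conv_geom(12L, 1L),          # 12 -> 6, weights 9 x c1
    enc2 = conv_geom(6L, c1),           # 6 -> 3, weights (9 c1) x c2
    dec1 = conv_geom(6L, c1),           # adjoint: 3 -> 6, weights (9 c1) x c2
    dec2 = conv_geom(12L, c3),          # adjoint: 6 -> 12, weights (9 c3) x c1
    dec3 = conv_geom(12L, c3, s = 1L)   # 12 -> 12, weights (9 c3) x 1
  )
}

vae_init_params <- function(config) {
  c1 <- config$channels[1]
  c2 <- config$channels[2]
  L <- config$latent_dim
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  xavier <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(1 / fan)), nr, nc)
  list(
    Wc1 = he(9, c1, 9), bc1 = rep(0, c1),
    Wc2 = he(9 * c1, c2, 9 * c1), bc2 = rep(0, c2),
    Wf1 = xavier(9 * c2, L, 9 * c2), bf1 = rep(0, L),
    Wf2 = he(L, 9 * c2, L), bf2 = rep(0, 9 * c2),
    Wd1 = he(9 * c1, c2, 9 * c2 / 4), bd1 = rep(0, c1),
    Wd2 = he(9 * dec_channels(c1), c1, 9 * c1 / 4), bd2 = rep(0, dec_channels(c1)),
    Wd3 = xavier(9 * dec_channels(c1), 1, 9 * dec_channels(c1)), bd3 = 0
  )
}

# ---- forward / backward --------------------------------------------------

vae_encode_pass <- function(par, X, gm) {
  N <- nrow(X)
  f1 <- conv_fwd(to_conv_layout(X, 1L), par$Wc1, par$bc1, gm$enc1, N)
  h1 <- relu(f1$Y)
  f2 <- conv_fwd(h1, par$Wc2, par$bc2, gm$enc2, N)
  h2f <- to_flat(relu(f2$Y), N)
  z <- h2f %*% par$Wf1 + rep(par$bf1, each = N)
  list(z = z, f1 = f1, f2 = f2, h2f = h2f, N = N)
}

vae_decode_pass <- function(par, z, gm) {
  N <- nrow(z)
  c2 <- ncol(par$Wd1)
  pre3 <- z %*% par$Wf2 + rep(par$bf2, each = N)
  h3c <- to_conv_layout(relu(pre3), c2)
  d1 <- deconv_fwd(h3c, par$Wd1, par$bd1, gm$dec1, N)
  h4 <- relu(d1$Y)
  d2 <- deconv_fwd(h4, par$Wd2, par$bd2, gm$dec2, N)
  h5 <- relu(d2$Y)
  d3 <- conv_fwd(h5, par$Wd3, par$bd3, gm$dec3, N)
  xhat_c <- sigmoid_mat(d3$Y)
  list(xhat = to_flat(xhat_c, N), xhat_c = xhat_c, pre3 = pre3, h3c = h3c,
       d1 = d1, d2 = d2, d3 = d3, N = N)
}

# loss components and (optionally) parameter gradients for one batch
vae_batch <- function(par, X, prior, config, gm, grads = TRUE) {
  N <- nrow(X)
  enc <- vae_encode_pass(par, X, gm)
  dec <- vae_decode_pass(par, enc$z, gm)
  recon <- mean((dec$xhat - X)^2)
  reg_raw <- mmd(enc$z, prior, config$mmd_bandwidth)
  reg <- config$mmd_weight * reg_raw
  out <- list(total = recon + reg, reconstruction = recon, regularization = reg)
  if (!grads) return(out)

  c2 <- ncol(par$Wd1)
  dxhat_c <- to_conv_layout(2 * (dec$xhat - X) / (N * 144), 1L)
  dpre_d3 <- dxhat_c * dec$xhat_c * (1 - dec$xhat_c)
  b3 <- conv_bwd(dpre_d3, dec$d3$colsmat, par$Wd3, gm$dec3, N)
  dh5 <- b3$dX * (dec$d2$Y > 0)
  b2 <- deconv_bwd(dh5, dec$d2$U, par$Wd2, gm$dec2, N)
  dh4 <- b2$dU * (dec$d1$Y > 0)
  b1 <- deconv_bwd(dh4, dec$d1$U, par$Wd1, gm$dec1, N)
  dh3f <- to_flat(b1$dU, N) * (dec$pre3 > 0)
  dWf2 <- crossprod(enc$z, dh3f)
  dbf2 <- colSums(dh3f)
  dz <- dh3f %*% t(par$Wf2) +
    config$mmd_weight * mmd_grad_x(enc$z, prior, config$mmd_bandwidth)
  dWf1 <- crossprod(enc$h2f, dz)
  dbf1 <- colSums(dz)
  dh2c <- to_conv_layout(dz %*% t(par$Wf1), c2) * (enc$f2$Y > 0)
  e2 <- conv_bwd(dh2c, enc$f2$colsmat, par$Wc2, gm$enc2, N)
  dh1 <- e2$dX * (enc$f1$Y > 0)
  e1 <- conv_bwd(dh1, enc$f1$colsmat, par$Wc1, gm$enc1, N)

  out$grads <- list(
    Wc1 = e1$dW, bc1 = e1$db, Wc2 = e2$dW, bc2 = e2$db,
    Wf1 = dWf1, bf1 = dbf1, Wf2 = dWf2, bf2 = dbf2,
    Wd1 = b1$dW, bd1 = b1$db, Wd2 = b2$dW, bd2 = b2$db,
    Wd3 = b3$dW, bd3 = b3$db
  )
  out
}

#' Loss components of the autoencoder on a batch of images
#'
#' Reconstruction is the mean squared error over all 144 pixels;
#' regularization is `mmd_weight` times the squared MMD between the encoded
#' batch and a standard-normal prior sample of the same size; the total is
#' their sum.
#'
#' @param fit A trained [vae_train()] model (or a list with `params`,
#'   `config`, `geoms`).
#' @param images Numeric matrix `N x 144` of normalized field images.
#' @param prior Optional `M x L` prior sample; drawn fresh from N(0, I) if
#'   omitted.
#' @return A one-row tibble with `total`, `reconstruction`, `regularization`.
#' @export
vae_loss <- function(fit, images, prior = NULL) {
  if (is.null(prior)) {
    prior <- matrix(stats::rnorm(nrow(images) * fit$config$latent_dim),
                    nrow(images))
  }
  out <- vae_batch(fit$params, images, prior, fit$config, fit$geoms,
                   grads = FALSE)
  tibble::tibble(total = out$total, reconstruction = out$reconstruction,
                 regularization = out$regularization)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# ---- training -----------------------------------------------------------

#' Train the generalized autoencoder
#'
#' Runs minibatch Adam for `config$epochs` epochs, recording train and
#' validation loss components each epoch (validation is evaluated batchwise
#' with a fresh prior sample per batch), and returns the parameters from the
#' epoch with minimal validation total loss. Fully reproducible for a fixed
#' `config$seed`.
#'
#' @param train,validation [vf_cohort] tibbles (converted to right-eye
#'   images internally) or `N x 144` image matrices.
#' @param config A [vae_config()].
#' @param mask A [vf_mask()].
#' @param norm A [vf_norm()].
#' @param verbose Print a progress line every 10 epochs.
#' @return An object of class `vfvae_fit`: list with `params`, `config`,
#'   `geoms`, `mask`, `norm`, `loss_history` (tibble: epoch, split, total,
#'   reconstruction, regularization) and `selected_epoch`.
#' @export
vae_train <- function(train, validation, config = vae_config(),
                      mask = vf_mask(), norm = vf_norm(), verbose = FALSE) {
  Xtr <- as_image_matrix(train, mask, norm)
  Xval <- as_image_matrix(validation, mask, norm)
  if (nrow(Xtr) == 0 || nrow(Xval) == 0) {
    rlang::abort("vae_train: empty training or validation set.")
  }
  gm <- vae_geoms(config$channels)
  L <- config$latent_dim

  withr::with_seed(config$seed, {
    par <- vae_init_params(config)
    opt <- adam_init(par)
    hist <- vector("list", 2L * config$epochs)
    best <- list(val = Inf, par = par, epoch = 0L)
    n <- nrow(Xtr)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      tr_acc <- c(total = 0, reconstruction = 0, regularization = 0)
      for (s in starts) {
        bi <- ord[s:min(s + config$batch_size - 1, n)]
        if (length(bi) < 2) next
        Xb <- Xtr[bi, , drop = FALSE]
        prior <- matrix(stats::rnorm(length(bi) * L), length(bi), L)
        res <- vae_batch(par, Xb, prior, config, gm, grads = TRUE)
        if (!is.finite(res$total)) {
          rlang::abort(sprintf(
            "vae_train: non-finite loss at epoch %d (recon %.3g, reg %.3g); try a smaller learning rate.",
            epoch, res$reconstruction, res$regularization))
        }
        step <- adam_step(par, res$grads, opt, config$lr)
        par <- step$par
        opt <- step$state
        w <- length(bi) / n
        tr_acc <- tr_acc + w * c(res$total, res$reconstruction,
                                 res$regularization)
      }
      val <- eval_loss_batched(par, Xval, config, gm)
      hist[[2 * epoch - 1]] <- tibble::tibble(
        epoch = epoch, split = "train", total = tr_acc[[1]],
        reconstruction = tr_acc[[2]], regularization = tr_acc[[3]])
      hist[[2 * epoch]] <- tibble::tibble(
        epoch = epoch, split = "validation", total = val[[1]],
        reconstruction = val[[2]], regularization = val[[3]])
      if (val[[1]] < best$val) {
        best <- list(val = val[[1]], par = par, epoch = epoch)
      }
      if (verbose && epoch %% 10 == 0) {
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch,
                        tr_acc[[1]], val[[1]]))
      }
    }
    par <- align_latent_signs(best$par, Xtr, gm, mask, norm)
    structure(
      list(params = par, config = config, geoms = gm, mask = mask,
           norm = norm, loss_history = dplyr::bind_rows(hist),
           selected_epoch = best$epoch),
      class = "vfvae_fit"
    )
  })
}

# Standardize the sign of every latent axis so it correlates positively
# with field severity (MD) on the training set. The model itself is
# sign-symmetric: negating an encoder output column and the matching
# decoder input row leaves reconstructions and the (sign-invariant) MMD
# term untouched, so axis orientations are unidentified. Fixing them makes
# the global mean rate of change directionally meaningful — without a
# convention, progression can cancel across arbitrarily oriented axes.
align_latent_signs <- function(par, Xtr, gm, mask, norm) {
  z <- vae_encode_pass(par, Xtr, gm)$z
  md <- rowMeans(images_to_td(Xtr, mask, norm))
  for (l in seq_len(ncol(z))) {
    r <- suppressWarnings(stats::cor(z[, l], md))
    if (is.finite(r) && r < 0) {
      par$Wf1[, l] <- -par$Wf1[, l]
      par$bf1[l] <- -par$bf1[l]
      par$Wf2[l, ] <- -par$Wf2[l, ]
    }
  }
  par
}

eval_loss_batched <- function(par, X, config, gm) {
  n <- nrow(X)
  starts <- seq(1, n, by = config$batch_size)
  acc <- c(0, 0, 0)
  used <- 0L
  for (s in starts) {
    bi <- s:min(s + config$batch_size - 1, n)
    if (length(bi) < 2) next
    prior <- matrix(stats::rnorm(length(bi) * config$latent_dim), length(bi))
    r <- vae_batch(par, X[bi, , drop = FALSE], prior, config, gm,
                   grads = FALSE)
    acc <- acc + length(bi) * c(r$total, r$reconstruction, r$regularization)
    used <- used + length(bi)
  }
  acc / used
}

as_image_matrix <- function(x, mask, norm) {
  if (is.matrix(x)) {
    if (ncol(x) != 144) rlang::abort("image matrices must have 144 columns.")
    return(x)
  }
  fields_to_images(convert_to_right_eye(x, mask), mask, norm)
}

#' @export
print.vfvae_fit <- function(x, ...) {
  cat(sprintf(
    "<vfvae_fit> L = %d, channels (%d, %d); best epoch %d of %d (val total %.5f)\n",
    x$config$latent_dim, x$config$channels[1], x$config$channels[2],
    x$selected_epoch, x$config$epochs,
    min(x$loss_history$total[x$loss_history$split == "validation"])))
  invisible(x)
}

# ---- encode / decode -----------------------------------------------------

#' Encode field images to latent features
#'
#' The encoder is deterministic: identical images always map to identical
#' latent rows, and a batch encode equals row-wise single encodes.
#'
#' @param fit A `vfvae_fit`.
#' @param images Numeric matrix `N x 144` (normalized field images).
#' @return Numeric matrix `N x L`.
#' @export
encode_images <- function(fit, images) {
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  if (ncol(images) != 144) rlang::abort("encode_images: images must be N x 144.")
  vae_encode_pass(fit$params, images, fit$geoms)$z
}

#' Decode latent features to field images
#'
#' The decoder is the mean of a Gaussian observation model, so decoded
#' fields are de-noised; the sigmoid output keeps every pixel strictly
#' inside (0, 1).
#'
#' @param fit A `vfvae_fit`.
#' @param z Numeric matrix `N x L` of latent features.
#' @return Numeric matrix `N x 144`.
#' @export
decode_latent <- function(fit, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1)
  if (ncol(z) != fit$config$latent_dim) {
    rlang::abort(sprintf("decode_latent: z must have %d columns.",
                         fit$config$latent_dim))
  }
  vae_decode_pass(fit$params, z, fit$geoms)$xhat
}

#' Encode a cohort's visits into a latent-feature tibble
#'
#' @param data A [vf_cohort] tibble.
#' @param fit A `vfvae_fit`.
#' @return The visit metadata (`patient_id`, `status`, `years`) with latent
#'   columns `z_1..z_L`.
#' @export
vf_encode <- function(data, fit) {
  z <- encode_images(fit, fields_to_images(convert_to_right_eye(data, fit$mask),
                                           fit$mask, fit$norm))
  out <- data[, c("patient_id", "status", "years")]
  colnames(z) <- paste0("z_", seq_len(ncol(z)))
  dplyr::bind_cols(out, tibble::as_tibble(z))
}

#' Decode latent features to total-deviation values in dB
#'
#' @param fit A `vfvae_fit`.
#' @param z Numeric matrix `N x L`.
#' @return Numeric matrix `N x 52` of TD values (always within the
#'   normalization range).
#' @export
vf_decode_td <- function(fit, z) {
  images_to_td(decode_latent(fit, z), fit$mask, fit$norm)
}

# ---- latent-dimension sweep ---------------------------------------------

#' Train one model per latent dimension
#'
#' Re-trains the autoencoder for each requested latent dimension on common
#' data and seed, for latent-dimension selection in the spirit of comparing
#' loss and clinical metrics across L = 1..15.
#'
#' @inheritParams vae_train
#' @param dims Latent dimensions to sweep (default 1..15).
#' @return A tibble with one row per dimension: `latent_dim`,
#'   `selected_epoch`, validation `total`/`reconstruction`/`regularization`
#'   at the selected epoch, and the fitted model in list-column `fit`.
#' @export
sweep_latent_dims <- function(train, validation, dims = 1:15,
                              config = vae_config(), mask = vf_mask(),
                              norm = vf_norm()) {
  stopifnot(length(dims) >= 1)
  purrr::map_dfr(dims, function(L) {
    cfg <- config
    cfg$latent_dim <- as.integer(L)
    cfg$mmd_bandwidth <- sqrt(L)  # keep the sigma^2 = L scaling across the sweep
    fit <- vae_train(train, validation, cfg, mask, norm)
    sel <- fit$loss_history[fit$loss_history$split == "validation" &
                              fit$loss_history$epoch == fit$selected_epoch, ]
    tibble::tibble(latent_dim = L, selected_epoch = fit$selected_epoch,
                   total = sel$total, reconstruction = sel$reconstruction,
                   regularization = sel$regularization, fit = list(fit))
  })
}

# ---- broom-style methods and plots --------------------------------------

#' Tidy the per-epoch loss history of a fitted autoencoder
#'
#' @param x A `vfvae_fit`.
#' @param ... Unused.
#' @return Tibble: `epoch`, `split`, `total`, `reconstruction`,
#'   `regularization`.
#' @method tidy vfvae_fit
#' @export
tidy.vfvae_fit <- function(x, ...) x$loss_history

#' One-row summary of a fitted autoencoder
#'
#' @param x A `vfvae_fit`.
#' @param ... Unused.
#' @return Tibble with `latent_dim`, `epochs`, `selected_epoch` and the
#'   validation loss components at the selected epoch.
#' @method glance vfvae_fit
#' @export
glance.vfvae_fit <- function(x, ...) {
  sel <- x$loss_history[x$loss_history$split == "validation" &
                          x$loss_history$epoch == x$selected_epoch, ]
  tibble::tibble(latent_dim = x$config$latent_dim, epochs = x$config$epochs,
                 selected_epoch = x$selected_epoch, val_total = sel$total,
                 val_reconstruction = sel$reconstruction,
                 val_regularization = sel$regularization)
}

#' Plot training curves of a fitted autoencoder
#'
#' @param object A `vfvae_fit`.
#' @param ... Unused.
#' @return A ggplot of reconstruction/regularization/total loss by epoch
#'   and split.
#' @method autoplot vfvae_fit
#' @export
autoplot.vfvae_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(object$loss_history,
                           c("total", "reconstruction", "regularization"),
                           names_to = "component", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$selected_epoch,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL)
}

# ---- checkpoint I/O ------------------------------------------------------

#' Save / load a fitted autoencoder as portable JSON
#'
#' Stores parameters, configuration, normalization constants and the loss
#' history as plain JSON so checkpoints survive any platform.
#'
#' @param fit A `vfvae_fit`.
#' @param path File path.
#' @return `write_vae()` returns `fit` invisibly; `read_vae()` the restored
#'   fit.
#' @export
write_vae <- function(fit, path) {
  payload <- list(
    config = unclass(fit$config),
    norm = unclass(fit$norm),
    selected_epoch = fit$selected_epoch,
    params = lapply(fit$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.vector(p))
      else list(data = as.vector(p))
    }),
    loss_history = fit$loss_history
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(fit)
}

#' @rdname write_vae
#' @export
read_vae <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- do.call(vae_config, p$config[c("latent_dim", "channels", "lr",
                                           "epochs", "batch_size",
                                           "mmd_weight", "mmd_bandwidth",
                                           "seed")])
  params <- lapply(p$params, function(q) {
    if (length(q$dim) == 2) matrix(q$data, q$dim[1], q$dim[2]) else q$data
  })
  structure(
    list(params = params, config = config, geoms = vae_geoms(config$channels),
         mask = vf_mask(), norm = vf_norm(p$norm$td_min, p$norm$td_max),
         loss_history = tibble::as_tibble(p$loss_history),
         selected_epoch = p$selected_epoch),
    class = "vfvae_fit"
  )
}
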