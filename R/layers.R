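# Convolution primitives for the autoencoder.
#
# Activations are stored as (N * H^2) x channels matrices, rows ordered with
# the batch index fastest inside each pixel block (row = (pix - 1) * N + n,
# pixels column-major over the H x H frame). In this layout reshaping
# between the dense layers and the convolutional stack is a zero-copy `dim`
# change, and a k x k convolution decomposes into k^2 row-gather +
# one-GEMM steps. Transposed convolution is the exact adjoint and reuses
# the same geometry. A kernel offset maps distinct output positions to
# distinct input pixels, so the per-offset scatter-add in the backward pass
# never collides (pad cells all alias one sacrificial zero row).
#
# Weight matrices are (k^2 * c_in) x c_out, rows ordered offset-major
# (offset slowest ... actually offset-major blocks of c_in).

conv_geom <- function(H, c_in, k = 3L, s = 2L, p = 1L) {
  Hout <- (H + 2L * p - k) %/% s + 1L
  P <- Hout * Hout
  # Q[pos, offset]: source pixel (1..H^2) or 0L for padding
  Q <- matrix(0L, P, k * k)
  for (pp in seq_len(P)) {
    orow <- (pp - 1L) %% Hout
    ocol <- (pp - 1L) %/% Hout
    for (kc in seq_len(k)) {
      for (kr in seq_len(k)) {
        ir <- orow * s + kr - p   # 1-based input row
        ic <- ocol * s + kc - p
        if (ir >= 1L && ir <= H && ic >= 1L && ic <= H) {
          Q[pp, (kc - 1L) * k + kr] <- (ic - 1L) * H + ir
        }
      }
    }
  }
  g <- list(H = H, Hout = Hout, c_in = c_in, k = k, s = s, p = p,
            P = P, K = k * k * c_in, Q = Q, cache = new.env(parent = emptyenv()))
  class(g) <- "conv_geom"
  g
}

# per-batch-size row-index table: rows[, offset] gathers the offset's source
# rows from the zero-row-augmented activation matrix
geom_rows <- function(g, N) {
  key <- as.character(N)
  rows <- g$cache[[key]]
  if (is.null(rows)) {
    zero_row <- N * g$H^2 + 1L
    rows <- matrix(0L, N * g$P, ncol(g$Q))
    n_seq <- seq_len(N)
    for (kk in seq_len(ncol(g$Q))) {
      q <- g$Q[, kk]
      base <- rep((q - 1L) * N, each = N) + n_seq
      base[rep(q == 0L, each = N)] <- zero_row
      rows[, kk] <- base
    }
    g$cache[[key]] <- rows
  }
  rows
}

with_zero_row <- function(X) rbind(X, 0)

# X: (N*H^2) x c_in; W: (k^2*c_in) x c_out; returns Y: (N*P) x c_out
conv_fwd <- function(X, W, b, g, N) {
  rows <- geom_rows(g, N)
  Xaug <- with_zero_row(X)
  colsmat <- do.call(cbind, lapply(seq_len(ncol(rows)), function(kk) {
    Xaug[rows[, kk], , drop = FALSE]
  }))
  Y <- colsmat %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, colsmat = colsmat)
}

conv_bwd <- function(dY, colsmat, W, g, N) {
  c_in <- g$c_in
  rows <- geom_rows(g, N)
  dW <- crossprod(colsmat, dY)
  db <- colSums(dY)
  dcols <- dY %*% t(W)
  dXaug <- matrix(0, N * g$H^2 + 1L, c_in)
  for (kk in seq_len(ncol(rows))) {
    r <- rows[, kk]
    dXaug[r, ] <- dXaug[r, , drop = FALSE] +
      dcols[, (kk - 1L) * c_in + seq_len(c_in), drop = FALSE]
  }
  list(dX = dXaug[-nrow(dXaug), , drop = FALSE], dW = dW, db = db)
}

# transposed convolution: g is the geometry of the matching conv going the
# other way (large -> small); g$c_in is the channel count of the LARGE side.
# U: (N*P) x c_small; W: (k^2 * c_large) x c_small; b: length c_large.
# Output Y: (N*H^2) x c_large; upsamples g$Hout -> g$H.
deconv_fwd <- function(U, W, b, g, N) {
  c_large <- g$c_in
  rows <- geom_rows(g, N)
  tmp <- U %*% t(W)                      # (N*P) x (k^2 * c_large)
  Yaug <- matrix(0, N * g$H^2 + 1L, c_large)
  for (kk in seq_len(ncol(rows))) {
    r <- rows[, kk]
    Yaug[r, ] <- Yaug[r, , drop = FALSE] +
      tmp[, (kk - 1L) * c_large + seq_len(c_large), drop = FALSE]
  }
  Y <- Yaug[-nrow(Yaug), , drop = FALSE]
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, U = U)
}

deconv_bwd <- function(dY, U, W, g, N) {
  rows <- geom_rows(g, N)
  dYaug <- with_zero_row(dY)
  dcols <- do.call(cbind, lapply(seq_len(ncol(rows)), function(kk) {
    dYaug[rows[, kk], , drop = FALSE]
  }))
  dU <- dcols %*% W
  dW <- crossprod(dcols, U)
  db <- colSums(dY)
  list(dU = dU, dW = dW, db = db)
}

relu <- function(x) pmax(x, 0)
sigmoid_mat <- function(x) 1 / (1 + exp(-x))

# zero-copy layout changes between batch-major (N x (P * C)) matrices used
# by the dense layers and the (N * P) x C convolutional layout
to_flat <- function(A, N) {
  stopifnot(nrow(A) %% N == 0)
  dim(A) <- c(N, nrow(A) / N * ncol(A))
  A
}

to_conv_layout <- function(A, channels) {
  stopifnot(ncol(A) %% channels == 0)
  dim(A) <- c(nrow(A) * ncol(A) / channels, channels)
  A
}
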