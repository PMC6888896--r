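#' The 24-2 perimetry grid in a 12 x 12 frame
#'
#' Builds the fixed right-eye (OD) Humphrey 24-2 test pattern embedded in a
#' 12 x 12 pixel frame. The 24-2 pattern has 54 stimulus locations on a 6
#' degree lattice (rows of 4/6/8/9/9/8/6/4 points spanning -27..+21 degrees
#' horizontally and -21..+21 vertically); the two locations at (15, +/-3)
#' degrees fall on the physiologic blind spot and are excluded, leaving the
#' 52 informative locations carried by every [vf_cohort] row. Padding the
#' irregular outline with zeros yields the square 12 x 12 image a
#' convolutional network can consume.
#'
#' @return An object of class `vf_mask`: a list with
#'   * `shape`: `c(12L, 12L)`,
#'   * `informative`: 12 x 12 logical matrix marking the 52 informative cells,
#'   * `index`: 12 x 12 integer matrix, 0 on pad cells, location index 1..52
#'     (reading order: top row first, left to right) on informative cells,
#'   * `coords`: tibble with one row per location
#'     (`loc`, `row`, `col`, `x_deg`, `y_deg`).
#' @examples
#' m <- vf_mask()
#' sum(m$informative)  # 52
#' @export
vf_mask <- function() {
  xs <- seq(-27, 21, by = 6)
  ys <- seq(21, -21, by = -6)
  half_width <- function(y) switch(as.character(abs(y)),
    "21" = 9, "15" = 15, "9" = 21, "3" = 27
  )
  pts <- do.call(rbind, lapply(ys, function(y) {
    keep <- xs >= -half_width(y) & xs <= half_width(y)
    data.frame(x_deg = xs[keep], y_deg = y)
  }))
  # blind spot of the right eye: (15, +/-3) degrees
  pts <- pts[!(pts$x_deg == 15 & abs(pts$y_deg) == 3), ]
  # centre the 8-row x 9-column lattice in the 12 x 12 frame
  pts$row <- (21 - pts$y_deg) / 6 + 3   # rows 3..10
  pts$col <- (pts$x_deg + 27) / 6 + 2   # cols 2..10
  pts <- pts[order(pts$row, pts$col), ]
  stopifnot(nrow(pts) == 52)
  pts$loc <- seq_len(52)

  index <- matrix(0L, 12, 12)
  index[cbind(pts$row, pts$col)] <- pts$loc
  structure(
    list(
      shape = c(12L, 12L),
      informative = index > 0L,
      index = index,
      coords = tibble::as_tibble(pts[, c("loc", "row", "col", "x_deg", "y_deg")])
    ),
    class = "vf_mask"
  )
}

#' @export
print.vf_mask <- function(x, ...) {
  cat("<vf_mask> 24-2 grid:", sum(x$informative), "informative cells in a",
      paste(x$shape, collapse = " x "), "frame\n")
  invisible(x)
}

#' Permutation that re-indexes a left-eye field onto the right-eye grid
#'
#' Left-eye (OS) fields are mirror images of right-eye (OD) fields. The OS
#' chart uses the horizontally mirrored grid layout; its 52 values are read in
#' the same top-to-bottom, left-to-right order as the OD chart. This returns
#' the permutation `p` such that `td_od <- td_os[p]` places each OS value at
#' the anatomically matching OD location (frame column `c` maps to `13 - c`
#' in 1-based indexing, i.e. `11 - c` 0-based).
#'
#' Applying the permutation twice restores the original ordering (mirroring is
#' an involution).
#'
#' @param mask A [vf_mask()].
#' @return Integer vector of length 52.
#' @export
os_to_od_permutation <- function(mask = vf_mask()) {
  mirrored <- mask$index[, rev(seq_len(ncol(mask$index)))] > 0
  # reading-order (row-major) rank of each informative cell of the OS layout
  cells <- which(mirrored, arr.ind = TRUE)
  cells <- cells[order(cells[, "row"], cells[, "col"]), , drop = FALSE]
  os_rank <- matrix(0L, 12, 12)
  os_rank[cells] <- seq_len(nrow(cells))
  perm <- integer(52)
  for (j in seq_len(52)) {
    at <- which(mask$index == j, arr.ind = TRUE)
    perm[j] <- os_rank[at[1], 13 - at[2]]
  }
  perm
}

#' Convert all fields in a cohort to right-eye orientation
#'
#' Rows with `laterality == "OS"` have their 52 total-deviation values
#' re-indexed by the horizontal mirror of the grid and are relabelled `"OD"`;
#' right-eye rows pass through unchanged. Converting to a single orientation
#' lets one network serve both eyes.
#'
#' @param data A [vf_cohort] tibble.
#' @param mask A [vf_mask()].
#' @return The cohort with all rows in OD orientation.
#' @export
convert_to_right_eye <- function(data, mask = vf_mask()) {
  lat <- data$laterality
  if (!all(lat %in% c("OD", "OS"))) {
    rlang::abort("`laterality` must be 'OD' or 'OS'.")
  }
  os <- lat == "OS"
  if (any(os)) {
    perm <- os_to_od_permutation(mask)
    # td_od[j] = td_os[perm[j]]
    td_od <- td_matrix(data[os, , drop = FALSE])[, perm, drop = FALSE]
    data[os, td_cols()] <- as.data.frame(td_od)
    data$laterality[os] <- "OD"
  }
  data
}

#' Total-deviation normalization map
#'
#' Affine map from decibel total deviation onto `[0, 1]` (with clipping) used
#' to feed fields to the autoencoder. The default range `[-38, +6]` dB covers
#' the clinically observed span of 24-2 total-deviation values and is held
#' fixed across folds so the map is stable and invertible without per-fold
#' state.
#'
#' @param td_min,td_max Range endpoints in dB (`td_min < td_max`).
#' @return An object of class `vf_norm`.
#' @export
vf_norm <- function(td_min = -38, td_max = 6) {
  stopifnot(is.numeric(td_min), is.numeric(td_max), td_min < td_max)
  structure(list(td_min = td_min, td_max = td_max), class = "vf_norm")
}

#' @export
print.vf_norm <- function(x, ...) {
  cat(sprintf("<vf_norm> [%g, %g] dB -> [0, 1]\n", x$td_min, x$td_max))
  invisible(x)
}

#' Normalize / denormalize total-deviation values
#'
#' @param td Numeric vector or matrix of TD values in dB.
#' @param x Numeric vector or matrix of normalized values in `[0, 1]`.
#' @param norm A [vf_norm()].
#' @return `normalize_td()` returns values in `[0, 1]` (clipped);
#'   `denormalize_td()` returns dB values in `[td_min, td_max]`.
#' @export
normalize_td <- function(td, norm = vf_norm()) {
  pmin(pmax((td - norm$td_min) / (norm$td_max - norm$td_min), 0), 1)
}

#' @rdname normalize_td
#' @export
denormalize_td <- function(x, norm = vf_norm()) {
  norm$td_min + x * (norm$td_max - norm$td_min)
}

#' Convert cohort rows to 12 x 12 normalized field images
#'
#' Each visit's 52 TD values are normalized to `[0, 1]` and placed at their
#' grid cells; pad cells are exactly 0. Images are returned flattened
#' (column-major) so a batch is an `N x 144` matrix, the form consumed by the
#' autoencoder.
#'
#' @param data A [vf_cohort] tibble (rows must be in OD orientation).
#' @param mask A [vf_mask()].
#' @param norm A [vf_norm()].
#' @return Numeric matrix `nrow(data) x 144` with values in `[0, 1]`.
#' @export
fields_to_images <- function(data, mask = vf_mask(), norm = vf_norm()) {
  td <- td_matrix(data)
  images_from_td(td, mask, norm)
}

#' @rdname fields_to_images
#' @param td Numeric matrix `N x 52` of TD values in dB.
#' @export
images_from_td <- function(td, mask = vf_mask(), norm = vf_norm()) {
  x <- normalize_td(td, norm)
  n <- nrow(x)
  out <- matrix(0, n, 144)
  cell <- (mask$coords$col - 1L) * 12L + mask$coords$row  # column-major pixel
  out[, cell] <- x[, mask$coords$loc, drop = FALSE]
  out
}

#' Recover TD values from normalized field images
#'
#' Inverse of [fields_to_images()]: extracts the 52 informative pixels and
#' maps them back to dB. Round-tripping reproduces the TD values clipped to
#' the normalization range.
#'
#' @param images Numeric matrix `N x 144` (flattened 12 x 12 images).
#' @inheritParams fields_to_images
#' @return Numeric matrix `N x 52` of TD values in dB.
#' @export
images_to_td <- function(images, mask = vf_mask(), norm = vf_norm()) {
  if (is.null(dim(images))) images <- matrix(images, nrow = 1)
  cell <- (mask$coords$col - 1L) * 12L + mask$coords$row
  x <- images[, cell, drop = FALSE][, order(mask$coords$loc), drop = FALSE]
  denormalize_td(x, norm)
}
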