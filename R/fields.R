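#' Longitudinal visual-field cohorts as tibbles
#'
#' Throughout the package a cohort is an ordinary tibble with one row per
#' visual-field test (visit) and the columns
#'
#' * `patient_id` (character), `status` (`"normal"`, `"suspect"`,
#'   `"glaucoma"`), `laterality` (`"OD"` or `"OS"`),
#' * `years` (years from that patient's baseline visit, baseline = 0),
#' * `fl_rate`, `fp_rate` (fixation-loss and false-positive rates in
#'   `[0, 1]`),
#' * `td_01` .. `td_52` (total deviation in dB at the 52 informative 24-2
#'   locations, ordered as in [vf_mask()]'s `index`).
#'
#' `as_vf_cohort()` validates the columns, orders rows by patient and time,
#' and returns the tibble unchanged otherwise; it is called by readers and
#' the simulator so user code rarely needs it directly.
#'
#' @param data A data frame in the layout above.
#' @return A validated cohort tibble.
#' @name vf_cohort
NULL

#' @rdname vf_cohort
#' @export
as_vf_cohort <- function(data) {
  need <- c("patient_id", "status", "laterality", "years",
            "fl_rate", "fp_rate", td_cols())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("cohort is missing column(s): ",
                        paste(utils::head(missing, 5), collapse = ", ")))
  }
  if (!all(data$laterality %in% c("OD", "OS"))) {
    rlang::abort("`laterality` must be 'OD' or 'OS'.")
  }
  if (!all(data$status %in% c("normal", "suspect", "glaucoma"))) {
    rlang::abort("`status` must be 'normal', 'suspect' or 'glaucoma'.")
  }
  bad_rate <- with(data, fl_rate < 0 | fl_rate > 1 | fp_rate < 0 | fp_rate > 1)
  if (any(bad_rate)) rlang::abort("fl_rate/fp_rate must lie in [0, 1].")
  td <- td_matrix(data)
  if (!all(is.finite(td))) rlang::abort("td_01..td_52 must all be finite.")
  data |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$patient_id, .data$years)
}

#' @rdname vf_cohort
#' @export
td_cols <- function() sprintf("td_%02d", 1:52)

#' Extract the N x 52 total-deviation matrix from a cohort
#'
#' @param data A [vf_cohort] tibble.
#' @return Numeric matrix with one row per visit.
#' @export
td_matrix <- function(data) {
  as.matrix(data[, td_cols(), drop = FALSE])
}

#' Reliability filter for visual-field tests
#'
#' A test is kept unless it has more than 33% fixation losses or more than
#' 15% false-positive errors (strict inequalities, so a field at exactly the
#' threshold is kept).
#'
#' @param data A [vf_cohort] tibble.
#' @return `qc_keep()` returns a logical vector (`TRUE` = keep);
#'   `qc_filter()` returns the filtered cohort with the number of excluded
#'   rows reported via a message and stored in attribute `"n_excluded"`.
#' @export
qc_keep <- function(data) {
  !(data$fl_rate > 0.33 | data$fp_rate > 0.15)
}

#' @rdname qc_keep
#' @export
qc_filter <- function(data) {
  keep <- qc_keep(data)
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    message(sprintf("qc_filter: excluded %d of %d fields (FL > 33%% or FP > 15%%)",
                    n_excl, length(keep)))
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "n_excluded") <- n_excl
  out
}

#' Global field summaries: mean deviation and pattern standard deviation
#'
#' `field_md()` is the unweighted arithmetic mean of the 52 TD values, a
#' surrogate for the device-reported mean deviation (which uses eccentricity
#' weights not reproduced here). `field_psd()` is the standard deviation of
#' TD about its mean, a surrogate for pattern standard deviation used only
#' for simulation summaries and plots. `add_field_summaries()` appends both
#' as columns `md` and `psd`.
#'
#' @param td Numeric matrix `N x 52` (or vector of length 52).
#' @param data A [vf_cohort] tibble.
#' @return Numeric vector (`field_md`, `field_psd`) or the cohort with `md`
#'   and `psd` columns (`add_field_summaries`).
#' @export
field_md <- function(td) {
  if (is.null(dim(td))) td <- matrix(td, nrow = 1)
  rowMeans(td)
}

#' @rdname field_md
#' @export
field_psd <- function(td) {
  if (is.null(dim(td))) td <- matrix(td, nrow = 1)
  apply(td, 1, stats::sd)
}

#' @rdname field_md
#' @export
add_field_summaries <- function(data) {
  td <- td_matrix(data)
  data$md <- field_md(td)
  data$psd <- field_psd(td)
  data
}

#' Read / write the longitudinal cohort CSV format
#'
#' One row per visit with the [vf_cohort] columns. `read_vf_csv()` validates
#' the layout on the way in.
#'
#' @param path File path.
#' @param data A [vf_cohort] tibble.
#' @return `read_vf_csv()` returns a validated cohort tibble;
#'   `write_vf_csv()` returns `data` invisibly.
#' @export
read_vf_csv <- function(path) {
  as_vf_cohort(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_vf_csv
#' @export
write_vf_csv <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}
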