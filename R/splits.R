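#' Patient-level train/validation/test split
#'
#' Assigns every patient (all of their visits together) to one of the three
#' subsets by an independent draw with the given probabilities, mirroring
#' random sampling of patients with 80%/10%/10% probability. Because the
#' draw is per patient, the realized proportions fluctuate around the
#' probabilities; no visit of a patient ever crosses subsets.
#'
#' @param data A [vf_cohort] tibble.
#' @param probs Named numeric vector of probabilities for
#'   `train`, `validation`, `test`; must sum to 1.
#' @param seed Integer seed making the assignment reproducible.
#' @return The cohort with an added `split` factor column
#'   (`train`/`validation`/`test`).
#' @export
split_patients <- function(data,
                           probs = c(train = 0.8, validation = 0.1, test = 0.1),
                           seed = 1L) {
  stopifnot(length(probs) == 3, abs(sum(probs) - 1) < 1e-8, all(probs >= 0))
  ids <- unique(data$patient_id)
  labels <- c("train", "validation", "test")
  assign <- withr::with_seed(seed, {
    sample(labels, length(ids), replace = TRUE, prob = probs)
  })
  map <- stats::setNames(assign, ids)
  data$split <- factor(map[data$patient_id], levels = labels)
  data
}

#' Patient-level cross-validation folds
#'
#' Builds `k` splits in which every patient serves in the test subset of
#' exactly one fold: patients are randomly partitioned into `k` test groups,
#' and within each fold the remaining patients are assigned to train or
#' validation with probabilities proportional to `probs["train"]` and
#' `probs["validation"]`.
#'
#' @inheritParams split_patients
#' @param k Number of folds (default 5).
#' @return A tibble with columns `fold`, `patient_id`, `split`; join it to a
#'   cohort with [apply_fold()].
#' @export
make_folds <- function(data, k = 5L,
                       probs = c(train = 0.8, validation = 0.1, test = 0.1),
                       seed = 1L) {
  stopifnot(k >= 2)
  ids <- unique(data$patient_id)
  if (k > length(ids)) {
    rlang::abort("`k` cannot exceed the number of patients.")
  }
  p_val <- probs[["validation"]] / (probs[["train"]] + probs[["validation"]])
  withr::with_seed(seed, {
    test_fold <- sample(rep_len(seq_len(k), length(ids)))
    purrr::map_dfr(seq_len(k), function(f) {
      split <- ifelse(test_fold == f, "test",
                      ifelse(stats::runif(length(ids)) < p_val,
                             "validation", "train"))
      tibble::tibble(fold = f, patient_id = ids, split = split)
    })
  })
}

#' Attach one fold's split assignment to a cohort
#'
#' @param data A [vf_cohort] tibble.
#' @param folds Output of [make_folds()].
#' @param fold Which fold to apply.
#' @return The cohort with a `split` column for that fold.
#' @export
apply_fold <- function(data, folds, fold) {
  f <- folds[folds$fold == fold, c("patient_id", "split")]
  dplyr::left_join(data, f, by = "patient_id")
}
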