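#' Clinically shaped defect archetypes on the 24-2 grid
#'
#' Nonnegative 52-vectors describing where glaucomatous loss concentrates,
#' each normalized to unit mean over its support (so a loading of `d` dB
#' deepens the defect by `d` dB on average within the affected region):
#' superior and inferior arcuate (Bjerrum) regions, a superior nasal step, a
#' superior paracentral defect, and uniform diffuse loss. Arcuate defects
#' respect the horizontal meridian, as glaucomatous damage does.
#'
#' @param mask A [vf_mask()].
#' @return A 52 x 5 matrix with columns `sup_arcuate`, `inf_arcuate`,
#'   `nasal_step`, `paracentral`, `diffuse`.
#' @export
defect_archetypes <- function(mask = vf_mask()) {
  co <- mask$coords
  r <- sqrt(co$x_deg^2 + co$y_deg^2)
  sup_arc <- co$y_deg > 0 & r >= 9 & r <= 24
  inf_arc <- co$y_deg < 0 & r >= 9 & r <= 24
  nasal <- co$x_deg <= -15 & co$y_deg > 0 & co$y_deg <= 9
  parac <- r <= 11 & co$y_deg > 0
  diffuse <- rep(TRUE, 52)
  a <- cbind(
    sup_arcuate = as.numeric(sup_arc),
    inf_arcuate = as.numeric(inf_arc),
    nasal_step = as.numeric(nasal),
    paracentral = as.numeric(parac),
    diffuse = as.numeric(diffuse)
  )
  # unit mean over support
  sweep(a, 2, colSums(a) / colSums(a > 0), "/")
}

#' Parameters of the synthetic longitudinal cohort
#'
#' Defaults emulate the demographic and clinical structure of a large
#' longitudinal glaucoma cohort: a 17%/58%/25% normal/suspect/glaucoma mix,
#' pooled baseline mean deviation of -3.55 dB, a mean of 7.61 visits
#' (heavily over-dispersed, SD ~ 7.35) over a mean 4.95-year follow-up, and
#' ~2 dB per-location test-retest noise. Baseline MD is drawn from
#' status-specific normal components truncated to `md_range`; the component
#' means/SDs are calibrated so the pooled truncated mixture mean equals
#' `md_baseline_mean`. Glaucomatous eyes carry localized archetype defects
#' that deepen over time; suspects carry mild defects and slow drift;
#' normals are stable.
#'
#' @param p_status Status probabilities (normal, suspect, glaucoma).
#' @param md_baseline_mean,md_baseline_sd Pooled baseline MD target (dB);
#'   recorded for reference, realized through `md_by_status`.
#' @param md_by_status List of `c(mean, sd)` per status for the baseline MD
#'   draw (dB).
#' @param md_range Truncation range for the baseline MD draw (dB).
#' @param mean_visits Mean number of visits; visit count is
#'   `2 + NegBin(size = visit_dispersion, mu = mean_visits - 2)`.
#' @param visit_dispersion Negative-binomial size parameter.
#' @param mean_followup_years Mean follow-up; inter-visit gaps are Gamma
#'   with shape 4 and mean `mean_followup_years / (mean_visits - 1)`.
#' @param noise_sd Per-location test-retest noise SD (dB).
#' @param rate_mean,rate_sd Per-status mean/SD of the true MD slope
#'   (dB/year, truncated at 0 from above for suspects/glaucoma).
#' @param localized_share_baseline,localized_share_rate Fraction of the
#'   baseline deficit / progression rate carried by the localized archetype
#'   (the rest is diffuse).
#' @param td_range Clipping range for generated TD values (dB).
#' @param fl_fp_max Upper bound of the Uniform(0, max) reliability-index
#'   draws.
#' @param p_os Probability a patient's tested eye is the left eye.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(
    p_status = c(normal = 0.17, suspect = 0.58, glaucoma = 0.25),
    md_baseline_mean = -3.55,
    md_baseline_sd = 5.71,
    md_by_status = list(normal = c(mean = 1.0, sd = 1.5),
                        suspect = c(mean = -0.5, sd = 2.5),
                        glaucoma = c(mean = -11.611, sd = 4.0)),
    md_range = c(-30, 2),
    mean_visits = 7.61,
    visit_dispersion = 0.65,
    mean_followup_years = 4.95,
    noise_sd = 2,
    rate_mean = c(normal = 0, suspect = -0.05, glaucoma = -0.5),
    rate_sd = c(normal = 0, suspect = 0.05, glaucoma = 0.3),
    localized_share_baseline = c(normal = 0, suspect = 0.3, glaucoma = 0.6),
    localized_share_rate = c(normal = 0, suspect = 0.5, glaucoma = 0.8),
    td_range = c(-38, 6),
    fl_fp_max = 0.1,
    p_os = 0.5) {
  stopifnot(abs(sum(p_status) - 1) < 1e-8, all(p_status >= 0),
            noise_sd >= 0, mean_visits >= 2, visit_dispersion > 0,
            mean_followup_years > 0, td_range[1] < td_range[2])
  structure(as.list(environment()), class = "cohort_params")
}

# baseline TD pattern with MD exactly md0: a localized defect of the given
# archetype carrying `share` of the total deficit, the rest diffuse. The
# defect depth is capped ~2 dB inside the physical floor (excess deficit is
# shifted into the diffuse component) so that clipping does not bias MD.
baseline_pattern <- function(md0, arch, share, td_range) {
  f <- mean(arch)
  depth <- share * max(0, -md0) / f
  if (is.finite(td_range[1])) {
    floor_cap <- (md0 - (td_range[1] + 2)) / (1 - f)
    depth <- max(0, min(depth, floor_cap))
  }
  (md0 + depth * f) - depth * arch
}

# status-specific truncated-normal baseline MD draw (rejection sampling)
draw_baseline_md <- function(status, params) {
  ms <- params$md_by_status[[status]]
  lo <- params$md_range[1]
  hi <- params$md_range[2]
  repeat {
    x <- stats::rnorm(1, ms[["mean"]], ms[["sd"]])
    if (x >= lo && x <= hi) return(x)
  }
}

#' Simulate one patient-eye series (with ground truth)
#'
#' Draws a status, a baseline TD pattern whose MD matches a status-specific
#' truncated-normal draw, a true per-location progression-rate pattern
#' concentrated on a defect archetype, a visit schedule, and noisy per-visit
#' TD values (`baseline + t * rate + N(0, noise_sd^2)` per location, clipped
#' to `td_range`). Uses the current RNG state; seed via
#' [simulate_cohort()] or [withr::with_seed()].
#'
#' @param params A [cohort_params()].
#' @param id Patient identifier.
#' @param mask A [vf_mask()].
#' @return A list with `series` (a [vf_cohort] tibble for one patient) and
#'   `truth` (one-row tibble with the status, true baseline pattern
#'   `base_01..base_52`, and true rate pattern `rate_01..rate_52` in dB/year,
#'   all in right-eye orientation).
#' @export
simulate_patient <- function(params = cohort_params(), id = "P00001",
                             mask = vf_mask()) {
  archetypes <- defect_archetypes(mask)
  status <- sample(names(params$p_status), 1, prob = params$p_status)

  md0 <- draw_baseline_md(status, params)
  arch <- archetypes[, sample(ncol(archetypes) - 1, 1)]  # localized shapes only
  baseline <- baseline_pattern(md0, arch,
                               params$localized_share_baseline[[status]],
                               params$td_range)

  share_r <- params$localized_share_rate[[status]]
  if (status == "normal") {
    rate <- rep(0, 52)
  } else {
    rd <- min(0, stats::rnorm(1, params$rate_mean[[status]],
                              params$rate_sd[[status]]))
    depth_r <- share_r * (-rd) / mean(arch)
    rate <- (1 - share_r) * rd - depth_r * arch
  }

  n_visits <- 2 + stats::rnbinom(1, size = params$visit_dispersion,
                                 mu = params$mean_visits - 2)
  gap_mean <- params$mean_followup_years / (params$mean_visits - 1)
  gaps <- stats::rgamma(n_visits - 1, shape = 4, rate = 4 / gap_mean)
  times <- c(0, cumsum(gaps))

  noise <- matrix(stats::rnorm(n_visits * 52, 0, params$noise_sd), n_visits, 52)
  td <- outer(rep(1, n_visits), baseline) + outer(times, rate) + noise
  td <- pmin(pmax(td, params$td_range[1]), params$td_range[2])

  laterality <- if (stats::runif(1) < params$p_os) "OS" else "OD"
  if (laterality == "OS") {
    # store in the left-eye chart's reading order; convert_to_right_eye()
    # restores right-eye orientation (the permutation is an involution)
    td <- td[, os_to_od_permutation(mask), drop = FALSE]
  }

  series <- tibble::tibble(
    patient_id = id,
    status = status,
    laterality = laterality,
    years = times,
    fl_rate = stats::runif(n_visits, 0, params$fl_fp_max),
    fp_rate = stats::runif(n_visits, 0, params$fl_fp_max)
  )
  series[td_cols()] <- as.data.frame(td)

  truth <- tibble::tibble(patient_id = id, status = status, md_baseline = md0)
  truth[sprintf("base_%02d", 1:52)] <- as.list(baseline)
  truth[sprintf("rate_%02d", 1:52)] <- as.list(rate)
  list(series = series, truth = truth)
}

#' Simulate a longitudinal visual-field cohort
#'
#' @param n_patients Number of patient-eyes.
#' @param params A [cohort_params()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @param mask A [vf_mask()].
#' @return A list with `cohort` (a [vf_cohort] tibble, one row per visit)
#'   and `truth` (one row per patient with true baseline and rate patterns).
#' @examples
#' sim <- simulate_cohort(25, seed = 7)
#' dplyr::count(sim$cohort, status)
#' @export
simulate_cohort <- function(n_patients, params = cohort_params(), seed = 1L,
                            mask = vf_mask()) {
  stopifnot(n_patients >= 1)
  ids <- sprintf("P%05d", seq_len(n_patients))
  sims <- withr::with_seed(seed, {
    lapply(ids, function(id) simulate_patient(params, id, mask))
  })
  list(
    cohort = as_vf_cohort(dplyr::bind_rows(lapply(sims, `[[`, "series"))),
    truth = dplyr::bind_rows(lapply(sims, `[[`, "truth"))
  )
}

#' Simulate a stable (null) cohort
#'
#' Every patient is a non-progressing glaucoma-labelled eye: TD at each visit
#' is the baseline pattern plus iid noise, with a true rate of zero at every
#' location and a fixed evenly spaced visit schedule. Used to measure the
#' specificity (type-I error) of progression tests, which should flag ~5% of
#' these series at alpha = 0.05.
#'
#' @param n_patients Number of patient-eyes.
#' @param n_visits Visits per patient (evenly spaced, >= 3).
#' @param followup_years Total follow-up span in years.
#' @param params A [cohort_params()] (baseline and noise parameters reused).
#' @param seed Integer seed.
#' @param mask A [vf_mask()].
#' @return A [vf_cohort] tibble.
#' @export
null_cohort <- function(n_patients, n_visits = 8, followup_years = 5,
                        params = cohort_params(), seed = 1L,
                        mask = vf_mask()) {
  stopifnot(n_visits >= 3)
  archetypes <- defect_archetypes(mask)
  times <- seq(0, followup_years, length.out = n_visits)
  ids <- sprintf("N%05d", seq_len(n_patients))
  rows <- withr::with_seed(seed, {
    lapply(ids, function(id) {
      md0 <- draw_baseline_md("glaucoma", params)
      arch <- archetypes[, sample(ncol(archetypes) - 1, 1)]
      baseline <- baseline_pattern(
        md0, arch, params$localized_share_baseline[["glaucoma"]],
        params$td_range)
      noise <- matrix(stats::rnorm(n_visits * 52, 0, params$noise_sd),
                      n_visits, 52)
      td <- outer(rep(1, n_visits), baseline) + noise
      td <- pmin(pmax(td, params$td_range[1]), params$td_range[2])
      out <- tibble::tibble(
        patient_id = id, status = "glaucoma", laterality = "OD",
        years = times,
        fl_rate = stats::runif(n_visits, 0, params$fl_fp_max),
        fp_rate = stats::runif(n_visits, 0, params$fl_fp_max)
      )
      out[td_cols()] <- as.data.frame(td)
      out
    })
  })
  as_vf_cohort(dplyr::bind_rows(rows))
}
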