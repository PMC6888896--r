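# Shared fixtures, built once per test run and memoised across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small synthetic cohort for fast unit tests
small_sim <- function() fixture("small_sim", function() {
  simulate_cohort(60, seed = 42)
})

# a small trained 2-D model shared by encode/decode, grid and prediction tests
small_fit <- function() fixture("small_fit", function() {
  sp <- split_patients(small_sim()$cohort, seed = 42)
  vae_train(sp[sp$split == "train", ], sp[sp$split == "validation", ],
            vae_config(latent_dim = 2, channels = c(8, 16), epochs = 25,
                       lr = 1e-3, seed = 9))
})

# the full-scale study cohort used by the qualitative-reproduction and
# parameter-recovery checks
study_sim <- function() fixture("study_sim", function() {
  simulate_cohort(2000, seed = 2026)
})

# one toy patient series with a known linear trend in every TD location
toy_series <- function(rate = rep(-1, 52), base = rep(0, 52),
                       times = seq(0, 6, by = 0.75), noise_sd = 0,
                       id = "T00001", status = "glaucoma", seed = 1) {
  withr::with_seed(seed, {
    n <- length(times)
    td <- outer(rep(1, n), base) + outer(times, rate) +
      matrix(stats::rnorm(n * 52, 0, noise_sd), n, 52)
    out <- tibble::tibble(patient_id = id, status = status,
                          laterality = "OD", years = times,
                          fl_rate = 0.01, fp_rate = 0.01)
    out[td_cols()] <- as.data.frame(td)
    out
  })
}
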