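Package: vfvae
Title: Latent-Space Modelling of Visual Field Progression with a
    Generalized Variational Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling longitudinal 24-2 standard automated
    perimetry data with a maximum mean discrepancy (MMD) regularized
    variational autoencoder. Provides the 24-2 grid geometry and
    quality-control preparation of total-deviation visual fields, a
    synthetic longitudinal glaucoma cohort simulator, a convolutional
    encoder/decoder trained with Adam and an MMD latent-space
    regularizer, zero-sum constrained OLS global rate-of-progression
    tests on latent trajectories (linear and joint-F quadratic) with a
    mean-deviation slope comparator, specificity-matched progression hit
    rates with bootstrap confidence intervals, and two-stage prediction
    of future visual fields benchmarked against pointwise linear
    regression with one-sided Wilcoxon comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
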