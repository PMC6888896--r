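---
title: "Latent-space modelling of visual field progression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space modelling of visual field progression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Standard automated perimetry (SAP) measures light sensitivity at 52
informative locations of the 24-2 test pattern and is the clinical
workhorse for detecting and following glaucomatous functional loss. Its
two standard summaries sit at opposite extremes: mean deviation (MD)
collapses the field to one number and dilutes localized damage, while
pointwise (PW) per-location regression follows all 52 locations but is
extremely noisy, because test–retest variability at a single location is
large. `vfvae` implements a middle path: an unsupervised autoencoder
compresses each field into a small number of latent features, progression
is assessed as the *mean rate of change of the latent features*, and
future fields are predicted by extrapolating latent trajectories and
decoding them back to field space.

## Data representation

A visual field is the vector of total-deviation (TD) values, in dB, at
the 52 informative 24-2 locations (the two blind-spot points are
excluded). Fields are stored one visit per row in plain tibbles
(`patient_id`, `status`, `laterality`, `years`, reliability indices, and
`td_01..td_52`). Preparation follows the conventional recipe:

* tests with more than 33% fixation losses or more than 15%
  false-positive errors are discarded (strict inequalities);
* left eyes are mirrored onto the right-eye grid (an involutive
  re-indexing of the 52 locations);
* TD is affinely mapped from `[-38, +6]` dB to `[0, 1]` with clipping.
  The range is fixed rather than data-driven so the map is identical in
  every fold and invertible without stored state; it covers the span of
  clinically observed 24-2 TD values;
* the irregular 52-point outline is zero-padded into a 12 × 12 image.
  Note the asymmetry this creates: a pad value of 0 in normalized space
  corresponds to maximal loss. We pad in normalized space (the simplest
  convention) and train the reconstruction loss on all 144 pixels; a
  masked-loss variant would weight only informative pixels and is an
  obvious extension.

The 24-2 layout itself is the standard Humphrey pattern: rows of
4/6/8/9/9/8/6/4 points on a 6° lattice spanning −27°..+21° horizontally
and ±21° vertically, minus the two points at (15°, ±3°) on the
physiologic blind spot. Any fixed bijection between the 52 values and
frame cells would serve the model equally; the standard layout keeps
heatmaps clinically readable.

## The generalized autoencoder

The encoder applies two 3 × 3, stride-2 convolutions (12 → 6 → 3 pixels,
with `c1 = 32` and `c2 = 64` feature maps by default), reshapes, and maps
through an identity-activation dense layer to `L` latent features. The
decoder mirrors it: dense layer, reshape to 3 × 3 × `c2`, two stride-2
transposed convolutions (3 → 6 → 12), and a final stride-1 3 × 3 layer
with sigmoid activation producing the reconstructed image in (0, 1).
Hidden activations are ReLU. Two decoder details are deliberate:

* **Deterministic encoder.** Regularization acts on the *aggregate*
  encoded distribution via the maximum mean discrepancy (MMD), not on
  per-point posteriors via KL, so no reparameterized sampling is needed;
  the decoder plays the role of the mean of a Gaussian observation model,
  which is why decoded fields are de-noised.
* **Decoder tail width.** A strict channel mirror would hand the final
  sigmoid layer a single feature map at 12 × 12 resolution. In practice
  that bottleneck cannot even overfit a single field (optimization stalls
  with individual pixels stuck at zero), so the last upsampling stage
  outputs `max(4, c1/4)` maps (8 at the default width) before the
  sigmoid layer. This retains the mirrored 64 → 32 channel taper while
  keeping the output stage trainable.

The loss on a minibatch of `n` images is

```
total = MSE(x, x_hat) + lambda * MMD^2(z, z_prior),
```

with the mean squared error taken over all 144 pixels, `z` the `n × L`
encoded batch, and `z_prior` a fresh standard-normal sample of the same
size. `MMD^2` is the biased V-statistic with Gaussian kernel
`k(a,b) = exp(-||a-b||^2 / (2 sigma^2))`; we scale the bandwidth with the
latent dimension (`sigma^2 = L`), so that typical prior-sample distances
(which grow like `sqrt(2L)`) stay inside the kernel's sensitive range for
every `L` in the 1..15 sweep.

**Choice of `lambda`.** On these images the two loss components have the
same order of magnitude: pixel MSE starts near 0.1–0.2 and the squared
MMD of a mismatched batch is 0.1–1. The default `lambda = 10` therefore
already makes the latent-matching pressure dominant early in training
while leaving reconstruction gradients visible throughout; much larger
weights (e.g. 10³) empirically freeze reconstruction (a single repeated
field cannot be reconstructed below 0.2 MAE in normalized units), and
`lambda = 0` removes the prior alignment entirely. Both the weight and
the bandwidth are configurable in `vae_config()`.

Training uses minibatch Adam (default `lr = 1e-4`, 100 epochs, batch size
100, all configurable), records per-epoch train and validation loss
components, and returns the parameters from the epoch with minimal
validation total loss. Validation losses are evaluated batchwise with a
fresh prior sample per batch, matching the training-loss semantics. The
entire run is a deterministic function of the seed. One practical
caveat: the validation total is dominated by the weighted MMD term,
whose minimum over epochs can precede reconstruction convergence on
small cohorts (a few hundred patients), in which case early epochs get
selected; inspect `tidy(fit)` and extend training or lower `lambda` if
the selected reconstruction looks premature. On cohort sizes of a
thousand patients and up the selected epoch is late and stable. The network and its
backpropagation are implemented directly in R as batched matrix algebra
(images are tiny, so convolutions reduce to nine gather/GEMM steps per
layer); gradients are verified against finite differences in the test
suite.

## Rates of progression

For a patient with `n` visits encoded into an `n × L` latent series, the
linear global-rate model stacks all features:

```
z_il = a_l + (beta + delta_l) t_i + eps_il,   sum_l delta_l = 0.
```

Feature-specific intercepts `a_l` absorb each feature's baseline level;
the sum-to-zero constraint on the interaction makes `beta` literally the
*mean rate of change across features*, and the two-sided t-test of
`beta = 0` (pooled residual variance, `nL - 2L` degrees of freedom) is
the progression call at `alpha = 0.05`. With a shared time grid this
`beta` equals the arithmetic mean of the `L` per-feature OLS slopes — an
identity the tests exploit as an oracle. The non-linear variant adds
global and sum-to-zero quadratic terms and tests the two global terms
jointly with a nested-model F test. The reduced model keeps the
sum-to-zero slope deviations (they are nuisance structure, not the
hypothesis), which requires building those columns explicitly rather
than via formula shorthand.

Pooling the residual variance across features assumes homoscedastic
latent noise; this is what makes the latent test powerful at very short
follow-up, where the MD comparator's OLS has one or two residual degrees
of freedom while the stacked model has `8n - 16` at `L = 8`.

The comparator is the standard MD slope: OLS of MD on time, flagged when
the slope is significantly *negative* (one-sided, `alpha = 0.05`). The
one-sided reading makes all methods operate at 95% specificity, so
progression *hit rates* (fraction of glaucoma patients flagged, computed
at 2, 4, 6 years and full follow-up, using only visits at or before the
cutoff, minimum 3 visits, 4 for the quadratic test) are directly
comparable across methods. Percentile bootstrap intervals over patients
quantify uncertainty, and multi-fold runs average across folds.

One caveat carried over from the method's definition: the global rate is
a *signed average* across features. Under the MMD prior the latent
coordinate system is sign- (indeed rotation-) unidentified, so without a
convention the projections of a worsening field onto the axes can point
in opposite directions and cancel in the average. `vae_train()` therefore
standardizes axis orientation after training: every latent axis is
negated, together with the matching decoder row, until it correlates
positively with MD on the training set. This is exactly the sign
convention used for principal components or factor loadings — it changes
no reconstruction, no loss value and no MMD (all are sign-invariant) —
but it makes "mean rate of change" directionally coherent: deterioration
pushes all severity-correlated features the same way. The remaining
early-follow-up advantage over the MD slope then comes from both this
coherence and degrees-of-freedom pooling.

## Predicting future fields

Two-stage prediction: encode the first `k` visits, fit each latent
dimension's OLS trajectory (intercept + time, optionally + time²), evaluate
at the held-out visit's observed time, decode, and denormalize. The
benchmark is the established PW baseline: independent OLS per location on
the same `k` visits, extrapolated to the same time, unclamped (an
optional clamp exists). Accuracy is mean absolute error over exactly the
52 informative locations. Decoded predictions are bounded by construction
(sigmoid), PW predictions are not — the characteristic failure mode of PW
at long horizons from few visits. Paired one-sided Wilcoxon signed-rank
tests compare the two (zero differences dropped; exact null distribution
for n ≤ 25 without ties; exact sign-flip enumeration over midranks for
tied samples up to n = 14, since ties invalidate the tabulated exact
distribution; normal approximation with continuity correction beyond), at the Bonferroni-corrected level 0.05/900 ≈ 0.00006;
the divisor is the comparison family's printed constant, taken as given.

## The synthetic cohort

Real longitudinal SAP cohorts of this kind are not publicly available, so
the package ships a generator whose defaults emulate the published
demographic structure of a large clinical cohort: 17%/58%/25%
normal/suspect/glaucoma mix; pooled baseline MD −3.55 dB; mean 7.61
visits (shifted negative binomial, dispersion 0.65, matching the large
SD of 7.35); mean follow-up 4.95 years (Gamma inter-visit gaps, shape 4);
reliability indices Uniform(0, 0.1); per-location Gaussian test–retest
noise with SD 2 dB; all TD clipped to [−38, +6] dB.

Status-specific baseline MD components — normal N(1.0, 1.5), suspect
N(−0.5, 2.5), glaucoma N(−11.6, 4.0), truncated to [−30, 2] — were
calibrated once, in closed form, so the truncated mixture mean equals the
pooled −3.55 dB target (the implied pooled SD is 5.3 dB, slightly below
the published 5.71; only the mean was targeted). Defects are localized on
clinically shaped archetypes (superior/inferior Bjerrum arcuates, a
superior nasal step, a paracentral defect, diffuse loss), each normalized
to unit mean over its support. Glaucomatous eyes put 60% of their
baseline deficit and 80% of their progression on the archetype;
suspects 30%/50% with mean slope −0.05 dB/y; normals are stable. These
shares, and the glaucoma rate distribution N(−0.5, 0.3) dB/y truncated at
zero, are the generator's definition of "localized progression" — chosen
once as clinically plausible values, not fitted.

What the generator deliberately omits: heteroscedastic noise (real
test–retest variability grows with damage depth), floor effects beyond
hard clipping, learning and fatigue effects, and eye–eye correlation.
Consequently, passing tests demonstrate internal consistency of the
methods under a realistic but idealized data process, not clinical
performance.

## Numerical and scale choices

* Degenerate fits (zero residual variance, too few visits) return
  `p = NA`, never a flag, with a warning.
* `qr.solve` / `lm` are used for all least squares; no hand-rolled
  normal equations in the implementation (tests use them as oracles).
* Finite-difference gradient checks perturb all parameters away from
  zero first: at initialization some ReLU preactivations are exactly
  zero (transposed convolutions of sparse activations), where the
  subgradient convention and a central difference legitimately disagree.
* The test suite's full-scale run uses 2,000 synthetic patients with an
  `L = 8`, (32, 64)-channel model trained for 20 epochs at `lr = 1e-3`;
  this compressed regime (fewer epochs, larger steps than the reference
  100 × 1e-4 schedule) reaches a well-converged validation loss on the
  ~12,000-image training set and keeps the suite fast. Null-calibration
  checks use 2,000 simulated latent series.
* Cross-validation folds assign every patient to exactly one test fold;
  the remaining patients are redrawn into train/validation at the
  renormalized 8:1 odds within each fold.

## Known limitations

* The latent global rate can cancel across features (see above); a speed
  (norm-based) statistic would not, but is a different estimand.
* MD here is the unweighted TD mean, not the device's
  eccentricity-weighted MD; PSD likewise is a plain SD surrogate, used
  only inside the simulator.
* MMD weight and bandwidth interact with `L`; the `sigma^2 = L` scaling
  keeps the sweep comparable but is a convention, not an optimum.
* Reconstruction treats pad pixels as real zeros; a masked loss is the
  natural refinement.
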