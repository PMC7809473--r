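---
title: "Overlapping subnetworks of the social brain: model, assumptions, and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlapping subnetworks of the social brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlapnet)
```

## The problem

Grey-matter volumes of functionally related brain regions co-vary across
individuals. For the 36-region social brain atlas, `overlapnet` asks: which
*few* latent patterns account for that covariation, allowing a region to
participate in several patterns at once? The tool is a family of autoencoders
with a K = 15 bottleneck; each latent unit defines one **hidden subnetwork**
via its decoder weights, and participant-wise unit activations ("subnetwork
expressions") feed a supervised arm that predicts social-lifestyle markers.

## Model and assumptions

An autoencoder reconstructs z-scored volumes `x` through
`h = sigma(W_enc x + b)`, `x_hat = W_dec h + c`. Assumptions worth making
explicit:

- **Linear covariance structure.** The decomposition targets second-order
  structure. With identity activations the optimum is the top-K principal
  subspace; `closed_form_linear_ae()` computes it exactly and serves both as
  an independent oracle for training code and as a fast deterministic backend
  (`architectures = "oracle"`). ReLU variants exist to *test* whether
  nonlinearity helps; on linearly generated data they cannot, and the test
  suite asserts the linear oracle's dominance rather than any deep advantage.
- **Subnetworks may overlap.** Nothing constrains decoder columns to disjoint
  supports; overlap is read off the relevance matrix.
- **Unit ambiguity.** Latent units are defined up to permutation and sign.
  Every cross-model comparison therefore first sign-aligns rows (largest
  |weight| positive) and then solves an optimal assignment (Hungarian
  algorithm, implemented in-package and verified against brute-force
  enumeration) maximizing total |Pearson r|. The matching rule is a
  documented convention, not an estimated quantity.

### Training objective vs evaluation metric

Gradients come from mean squared reconstruction error; evaluation and model
selection use the mean absolute error (MAE) on z-scored volumes and the
**explained-variance score** `1 - MAE`, which is 1 exactly at perfect
reconstruction. Reporting both MAE and the score reconciles the two usages of
"explained variance" in this literature; all selection uses the score.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| bottleneck K | 15 | units | canonical configuration of the examined family |
| latent plans | 15; 25-15-25; 25-20-15-20-25 | units/layer | the examined 1/3/5-latent-layer variants |
| optimizer, lr | RMSprop, 1e-3 | — | the family's stated training setup |
| penalty grid | 1e-4…1e-1 (4 log steps) | — | decade grid around useful penalty strength |
| batch, epochs, patience | 128, 500, 20 | — | standard reproducible defaults (unstated upstream) |
| smoothing FWHM | 5 | mm | homogenizes local anatomy before averaging |
| sphere diameter | 5 (2.5/7.5 supported) | mm | diameter read literally; radius 2.5 mm |
| CV plan | 5 outer 50/50, 10 inner 90/10 | splits | outer estimates generalization, inner picks hyperparameters |
| logistic l2 grid | 10^-3…10^3, 7 log steps | — | the stated grid |
| forest grid | depth/split/leaf in {2, 6}, 100 trees | — | the stated grid |

Numerical conventions: z-scoring uses the population SD (ddof 0) and, by
default, scalers are fit on training rows only (`zscore_scope =
"train_only"`); a `"global"` mode mirrors workflows that z-score before
splitting, at a documented leakage risk. Smoothing uses reflect (half-sample
symmetric) padding, which makes the convolution operator symmetric and hence
mass-conserving; kernels are truncated at 4 sigma. Atlas mm coordinates map
to the nearest voxel through the inverse affine; sphere membership is tested
on voxel-center distance. Trait median splits send ties to "less social".
Masked units in per-subnetwork scoring are fixed at their *training-set mean
activation*, not zero, because biases make zero non-neutral.

## The synthetic world

`synthetic_spec()` states the generative world once:

- `X = Z W' + E`: n x 36 volumes from K = 15 latent factors. Factor variances
  follow a geometric profile (ratio 0.8, leading variance 4) so a dominance
  ordering with an elbow exists. Latents are Gaussian (a t(5) option exists
  for robustness stress tests); residuals are iid Gaussian, SD 0.5 by default
  (moderate noise).
- Loadings have sparse supports (6 regions/factor) covering all regions, with
  three **hub** regions forced into the first three factors' supports —
  emulating the finding that a few regions (accumbens, temporo-parietal
  junction, medial prefrontal cortex) load on several dominant subnetworks.
  With `orthonormal = TRUE` the loadings are symmetrically orthogonalized so
  individual factors are identifiable from second moments.
- Traits: `P(more social) = plogis(beta_t' z + gamma_t * sex)`, sex ~
  Bernoulli(0.5), age ~ U(45, 80); by default trait t loads on factor t with
  effect 1.5 and sex effect 0.5 — six traits, mirroring the six lifestyle
  markers.

What the generator does **not** emulate: realistic demographic structure,
site/scanner effects, non-Gaussian volume distributions, spatial
autocorrelation between regions beyond the planted loadings, and
trait-trait correlations. A green recovery test therefore establishes that
the *algorithms* are correct under the stated model, not that the scientific
findings reproduce; the original cohort results are not reproducible without
the access-restricted data and are never asserted.

### Identifiability and the scale of recovery tests

Parameter-recovery and stability properties are asserted on the **generative
(raw, centered) scale**, not after per-region z-scoring. Z-scoring divides
each region by its own SD; this rescales the planted loading matrix row-wise,
destroying the orthonormality that makes individual factors identifiable by
PCA and inflating regions with near-zero loadings to unit variance. On raw
data, noise-free orthonormal loadings with distinct variances are recovered
essentially exactly (matched |r| > 0.99 at n = 20,000), and split-half
solutions agree at mean matched |r| > 0.9; after z-scoring the trailing
factors' eigen-gaps fall below sampling resolution at desk-scale n and the
same statistics drop to ~0.89. The pipeline itself still z-scores — as the
field does — because real analyses care about the standardized solution, not
about recovering a known truth.

One related honest limitation: the four-way replication example (4 disjoint
splits of n = 8,000) reaches a minimum pairwise mean matched |r| of ~0.84 in
this stated world, slightly under a nominal 0.85 — at n = 2,000 per split the
trailing factors (variance ~0.18 against residual variance 0.25) are simply
not stably estimable. The replication machinery is tested for correctness
(disjointness, exhaustiveness, self-agreement); the 0.85 bound is not
asserted.

## Design choices that were genuinely open

- **Relevance side.** Subnetwork maps are read off *decoder* weights (unit to
  region), since the analyses describe each subnetwork's contribution to
  regional volume; encoder-side maps are available via `side = "encoder"`.
  For deep decoders the relevance is the product of decoder weight matrices —
  exact for identity activations, a linearization under ReLU.
- **"Covariance" penalty.** Interpreted as the cross-covariance (XCov)
  decorrelation penalty on bottleneck activations,
  `0.5 * sum_{k != l} Cov(h_k, h_l)^2` per batch; its analytic gradient is
  verified against numerical differentiation in the tests.
- **Layer naming.** Prose "six-layered" counts input/output layers; the
  implemented latent plans are exactly 15, 25-15-25, 25-20-15-20-25.
- **Winner rule.** Best mean held-out score, ties toward fewer parameters.
- **Chance calibration.** Outer folds are stratified half-splits, so the
  across-split SD of accuracy degenerates (test composition is fixed); the
  Monte-Carlo error band for the null-calibration test is therefore the
  binomial SE of test-set accuracy, `sqrt(0.25 * 0.75 / n_test)`.
- **Aggregating classifier weights across traits** is ambiguous (signed vs
  absolute); `summarize_weights()` emits both and asserts neither as "the"
  rule.
- **Forest estimator.** No tree package is available in the supported
  dependency set, so the one-vs-rest forest is a from-scratch CART
  (gini, per-node feature subsampling, bagging) exposing exactly the
  depth/split/leaf grid; it is a comparator, not the headline estimator.
- **Degenerate inputs.** Zero-variance regions, constant traits, empty
  classes, rank-deficient covariances, and out-of-bounds spheres raise
  classed errors (`zero_variance_error`, `constant_trait_error`,
  `class_imbalance_error`, `rank_error`, `out_of_bounds_error`) naming the
  offending region/participant where applicable.

## What the tests establish

Unit tests pin every operation to an independent oracle or closed form
(brute-force sphere enumeration and voxel loops, Gaussian peak heights,
hand-computed z-scores and XCov values, numerical gradients, brute-force
assignment, E|Z| = sqrt(2/pi)). Property tests cover the invariants
(determinism under seed, sign/permutation invariance, partition properties,
score = 1 - MAE, oracle dominance, tied-weight exactness). The acceptance
suite re-derives the calibration targets: chance-level classification on null
traits, perfect recovery on noise-free rank-15 data, atlas integrity, planted
recovery at two noise levels, variance-order recovery, XCov decorrelation,
extraction equivalence, mean-predictor calibration, separable-trait accuracy,
and split-half stability. Simulation sizes in the default test run are scaled
to finish in minutes on one CPU; the quantities they compute are stated in
each test.
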