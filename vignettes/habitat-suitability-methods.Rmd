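---
title: "Methods: knowledge- and occurrence-driven suitability modelling in habicomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge- and occurrence-driven suitability modelling in habicomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habicomp)
```

`habicomp` implements two modelling families for mapping habitat
suitability of grassland pests on a shared raster grid, and the
comparison machinery needed to contrast them. This vignette explains the
models, their assumptions, the tunable parameters, the synthetic-data
design, and the numerical and design choices a user should know about.

## The two branches and what they estimate

The **multi-criteria branch** is knowledge-driven: environmental layers
are converted to ordinal 1–5 suitability scores by expert grading tables,
then combined per cell. It estimates *potential environmental
suitability* — where conditions are favourable, whether or not the
species has been recorded there. Three combiners are provided:

* `wlcSurface()` — weighted linear combination `HSI_i = Σ_j w_j x_ij`,
  with weights from `ahpWeights()` (principal eigenvector of a reciprocal
  pairwise-comparison matrix; consistency ratio must be below 0.1).
* `topsisSurface()` — relative closeness to the per-variable ideal best
  and worst cells in weighted score space. Scores are standardised by
  dividing by 5, not per-variable min–max: min–max would inflate the
  influence of a nearly constant variable, while `x/5` preserves the
  absolute meaning of the ordinal scale.
* `owaSurface()` — ordered weighted averaging. Per cell, scores are
  sorted descending and combined with order weights
  `u_j = (Σ_{k≤j} r_k)^α − (Σ_{k≤j−1} r_k)^α`, where `r` is the criterion
  weight vector reordered by the cell's own ranking. `α < 1` emphasises a
  cell's best attributes (optimistic), `α > 1` its worst (conservative),
  and `α = 1` reproduces the weighted linear combination exactly — a
  telescoping identity the test suite asserts to 1e-12.

The **occurrence branch** is data-driven: presences plus uniformly drawn
pseudo-absences (1:3 ratio, presence cells excluded) feed a logistic
baseline fitted by ridge-stabilised IRLS, evaluated by stratified
repeated cross-validation, and a TSS-weighted ensemble combines members
that pass the selection gates (TSS > 0.7 and AUC > 0.9, strictly). It
estimates *occurrence-constrained* suitability: it is rewarded exactly
for separating presences from background, so point-based metrics (AUC,
TSS) structurally favour this branch over MCA; they measure
discrimination, not ecological validity.

## Key parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| grading tables | shipped set | — | expert mapping of values to scores 1–5 |
| judgment matrix | shipped 12×12 | 1–9 scale | source of AHP weights, CR < 0.1 |
| OWA `alpha` | demo list 1e-4…1e4 | — | decision attitude; clamped to [1e-4, 1e4] |
| `minDistKm` (thinning) | 5 | km | minimum great-circle separation of records |
| `rhoThreshold` (screening) | 0.75 | — | max tolerated pairwise Spearman rho |
| pseudo-absence `ratio` | 3 | — | pseudo-absences per presence |
| `l2` (logistic ridge) | 1e-4 | — | stabiliser against quasi-separation |
| CV `k`, `repeats` | 10, 10 | — | stratified fold design |
| ensemble `tssMin`, `aucMin` | 0.7, 0.9 | — | strict member selection gates |
| class thresholds | 0.6, 0.8 | — | fixed upper class boundaries |
| `gamma` (sampler) | 2 | — | occurrence selection exponent |

The α clamp matches the extreme decision attitudes the package treats as
boundary scenarios; exact 0 or ∞ are ill-defined in the order-weight
formula. Thinning uses the haversine distance because coordinates are
geographic — 5 km corresponds to different longitude spans at different
latitudes.

## The synthetic landscape: what it emulates, and what it does not

`genEnvStack()` builds twelve autocorrelated layers (Gaussian-kernel
smoothed white noise — only the presence of spatial autocorrelation
matters, not the covariance family). Two design features emulate real
arid-region structure, chosen once when the generator was designed:

1. **A shared latent gradient.** Climate, vegetation, soil and hydrology
   co-vary along an "oasis-to-desert" axis; each variable loads on a
   common latent field (loadings ≤ 0.85, so pairwise Spearman
   correlations stay below the 0.75 screening threshold). Aspect is
   independent of it.
2. **Zero-inflated marginals.** A monotone Beta(0.5, 2) quantile skew
   puts the bulk of each variable in its least-suitable grading band
   (cold, dry, sparse vegetation, sandy, far from water), with favourable
   conditions confined to a fringe — desert-basin geography rather than a
   mid-dominated Gaussian landscape. Land cover is desert-dominated for
   the same reason.

Ground truth is the rescaled weighted combination of the graded stack,
and occurrences are drawn without replacement with probability
proportional to `truth^gamma` (γ = 2), jittered within cells, optionally
multiplied by a clustered accessibility field to emulate survey bias.

What the generator does **not** emulate: real climate physics, realistic
hydrographic networks, species-specific biology, temporal dynamics, or
the very sharp spatial concentration of real occurrence records. That
last point matters for interpreting metrics: with γ = 2 the sampler's
selection is deliberately mild, so cross-validated AUC of the synthetic
baseline sits far below what occurrence models achieve on real, strongly
clustered records, and the strict ensemble gates (designed for real-data
performance levels) exclude synthetically fitted members. The demo
pipeline therefore also registers two *simulated external member
surfaces with declared nominal metrics* — one passing, one failing the
gates — so the selection and TSS-weighting logic runs end to end; the
manifest labels them as nominal. Passing tests on this landscape
demonstrate correctness of the machinery, not real-data performance.

## Numerical choices

* **AHP**: power iteration to a relative tolerance of 1e-12; `λ_max` is
  recovered from the stationary vector; orders ≤ 2 are consistent by
  construction. The random-index table covers orders 1–15.
* **IRLS**: deviance-change convergence at 1e-8, intercept unpenalised,
  predictors standardised internally and coefficients reported on the
  input scale; non-convergence raises an error carrying the deviance
  trace. At `l2 = 0` the fit matches `stats::glm()` to 1e-6.
* **Fisher–Jenks**: exact dynamic programming (Rcpp), quadratic in the
  number of values, so `classifySurface()` runs it on a seeded subsample
  of at most 10,000 cells (recorded in the map's parameters); the first
  break is clamped just below the fixed 0.6 threshold with a warning if
  the optimum violates it. Ties in the optimum resolve to the smallest
  split indices.
* **Interval conventions**: grading intervals are half-open `[low, high)`
  applied uniformly (printed grading boundaries are ambiguous); class
  intervals likewise, with the top class closed at 1.0 and the 0.8
  boundary classifying as highly suitable. Values matched by no grading
  rule receive score 1 — the conservative, least-suitable completion of
  gaps in the tables — with a counted warning.
* **CDF normalisation** uses `(rank − 0.5)/n` with average ranks for
  ties: output avoids exact 0/1 and a constant surface maps to 0.5. A
  consequence worth internalising: on a tie-free surface the fixed
  [0.6, 0.8) and [0.8, 1.0] windows *always* contain 20% of valid cells
  each, so CDF-scheme area comparisons are informative only in the lower
  two classes. The acceptance script recomputes exactly this.
* **TSS**: threshold scan over midpoints of sorted unique scores plus one
  candidate below and above the range (so the trivial classifiers are
  included); ties take the lowest threshold. The statistic is reported on
  its algebraic range [−1, 1], although practical summaries often quote
  only [0, 1].
* **OWA ties** in per-cell score ordering break by original variable
  index, making surfaces deterministic.
* **Degenerate inputs**: an all-identical TOPSIS stack scores 0.5
  everywhere with a warning; a both-empty Jaccard comparison is defined
  as 1 (identical emptiness) with a warning; constant layers cannot be
  screened for rank correlation and are flagged and auto-retained.
* **Seeds**: every stochastic operation takes an explicit seed and
  restores the caller's RNG state; the pipeline fans one global seed out
  to fixed per-stage offsets so a stage rerun in isolation reproduces its
  in-pipeline draws. Reruns reproduce artifact checksums bit-for-bit.

## Design choices where the design was open

* **Screening sample**: Spearman correlations are computed over *all*
  valid cells (not occurrence cells only) — the more stable choice, made
  explicit here because either reading is defensible.
* **Collinearity tie-break**: when a pair exceeds the threshold, the
  member with the lower univariate occurrence-vs-background AUC is
  dropped. This replaces an expert-judgment criterion ("clearer
  ecological significance") that a program cannot reproduce, with a
  deterministic, data-driven stand-in.
* **Aspect** is reported as the compass direction of the *uphill*
  gradient (a plane rising due north has aspect N), discretised to nine
  categories with slopes under 1° labelled flat. Users of the usual
  downslope-facing GIS convention should note the 180° difference.
* **AHP structure**: a single-level 12-criterion comparison matrix is
  exposed (the two-level category → variable composition can be emulated
  by multiplying weights); the shipped matrix encodes an ecologically
  ordered importance ranking with entries rounded to the Saaty scale.
* **Ensemble weighting** normalises TSS weights over the selected members
  so they sum to one.
* **Grading tables are shipped as given**, including the deliberately
  non-monotone overwintering-precipitation rows (a mid-range optimum with
  asymmetric shoulders); the package transcribes expert tables, it does
  not "correct" them.
* **MCA evaluation** is a single evaluation of the deterministic surface
  against the full presence/pseudo-absence set (there is nothing to
  cross-validate in a deterministic surface); the occurrence branch is
  cross-validated.
* **Raster exchange format** is the plain-text ESRI ASCII grid: single
  band, human-readable, supported by common GIS tools.

## Problem sizes

The test suite and acceptance script run at desk scale by design: a
200 × 200 cell grid (~1 km cells) for landscape-level checks, 480
occurrence points before thinning, 10 × 10 cross-validation on the demo
sample, Jenks subsamples of 10,000 cells, and toy fixtures (≤ 12 values,
≤ 9 criteria) wherever an exhaustive oracle verifies an estimator. These
sizes were chosen as the smallest at which every mechanism is exercised
meaningfully.

## Known limitations

* The logistic baseline is linear in its predictors; strongly non-monotone
  responses (which the grading tables encode) are not captured by it, and
  no MaxEnt/XGBoost reimplementation is attempted — externally produced
  surfaces can join the ensemble instead.
* Distances to features are vertex-based; geometries must be vertexed
  densely relative to the cell size.
* Reprojection support is limited to geographic coordinates with a local
  equirectangular km scaling; this is adequate for regional extents, not
  for continental ones.
* Greedy seeded thinning is order-dependent; different seeds retain
  different (equally valid) subsets.
* The CDF-forced 20% shares mean cross-model area comparisons after CDF
  normalisation carry information only in the unsuitable/slightly
  classes; hit rates and Jaccard overlap carry the rest.
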