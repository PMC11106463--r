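---
title: "Methods: leakage-aware SMR modelling and exact attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leakage-aware SMR modelling and exact attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialsmr)
```

`spatialsmr` predicts regional standardized mortality ratios from gridded
environmental exposures and socio-economic covariates, evaluates the model
under spatially blocked cross-validation, and explains it with exact
Shapley values. This vignette is the package's account of each method, the
parameters that matter, the numerical choices behind them, and what the
synthetic test bed does and does not establish about real data.

## 1. From gridded exposures to region features

Exposure inputs are per-cell time series on a regular grid (e.g. daily
pollutant concentrations). The aggregation order is fixed and deliberate:
**temporal first, spatial second**. For each cell, `temporal_stats()`
computes the mean and standard deviation over time; `zonal_mean()` then
averages each per-cell map within region boundaries, yielding two features
per pollutant (`mean p`, `std p`). Averaging over time first preserves the
within-year variability signal (`std p`) that a spatial-first order would
destroy.

Choices a user can revisit:

- **Standard deviation convention** — population (divide by `n`,
  default) or sample. Population std is well defined for a single time
  step; the two differ by `sqrt(n/(n-1))`, immaterial at a year of daily
  data but made explicit rather than silent.
- **Cell weighting** — none. Cells are averaged unweighted within a
  region; on the ~0.1° grids this emulates, cell areas vary only mildly
  with latitude, and neither area nor population weighting is obviously
  right, so the plain mean is used.
- **Polygon assignment** (`assign_cells()`) uses cell-center containment,
  the common zonal-statistics default; cells outside every polygon are
  dropped with a logged count, and a region that captures no cell centers
  is a hard error (the region is too small for the grid resolution).
- **Missing data** are an error, never skipped: the reanalysis products
  this emulates are gap-free, and silent NA handling would corrupt the
  temporal statistics invisibly.

## 2. Indirect standardization and outliers

Expected deaths import reference (national) age-specific rates into each
region's own age structure, `E_i = Σ_a pop_{i,a} · rate_a`, and
`SMR_i = O_i / E_i`. Two identities anchor the implementation and are
enforced by tests: when the reference rates are derived from the pooled
study regions, total expected equals total observed exactly; and jointly
scaling populations and deaths leaves every SMR unchanged.

Outlying regions are flagged by Tukey fences at `k = 1.5` times the IQR,
with quartiles by linear interpolation (the default `quantile()` type).
The fence rule replaces a discretionary visual exclusion with an
auditable one; flagged regions are retained in all output tables with
`outlier = TRUE` and excluded only from modelling. Both `k` and the
exclusion itself are configurable, because fence-based flagging on ~100
regions is a screening device, not a hypothesis test.

## 3. Semivariogram and the spatial range

The empirical semivariogram uses the Matheron estimator,
`γ(h) = 1/(2N(h)) Σ (z_i − z_j)²` over pairs in each lag bin. The ½
factor follows the semivariogram convention; range detection is invariant
to it because the sill is estimated on the same scale. Defaults: 15
equal-width bins from zero to half the maximum pairwise distance (the
standard heuristic that keeps late bins populated), Euclidean distances
for planar synthetic grids and haversine (Earth radius 6371 km) for
lon/lat centroids.

The range — the plateau onset beyond which observations are effectively
uncorrelated — is detected automatically rather than visually: the sill
is estimated by the sample variance of the values, and the range is the
center of the first bin whose moving-average-smoothed (window 3)
semivariance reaches `0.95 × sill`. The 0.95 threshold matches the
exponential covariance used by the generator, `C(d) = sill·exp(−3d/range)`,
which retains 5% correlation at `d = range`. If no bin reaches the
threshold the last non-empty bin center is returned with a
`converged = FALSE` flag rather than an error, so a flat (pure-nugget)
surface still yields usable blocks. A manual `cut_override` in the
pipeline reproduces any discretionary choice.

**Known limitation (quantified by the tests).** The sample variance
underestimates the sill when the study domain is only a small multiple of
the range, because the field's mean is itself estimated from correlated
data. On a 20×20 grid with range 10 (domain twice the range, mean
pairwise correlation ≈ 0.11) the deflation is ≈ 11%, which shifts the
0.95 crossing from `h = 10` to `h ≈ 6`, and realization noise then leaves
roughly two thirds of replicates within a factor of two of the true range
(the acceptance script reports this rate). On a 30×30 domain the same
estimator recovers the range within a factor of two in well over 90% of
replicates (checked in the unit tests). The bias matters for blocking:
an underestimated range means a smaller dendrogram cut, hence smaller
blocks and weaker train/validation separation — the anti-conservative
direction for leakage control. When the domain is tight relative to the
suspected correlation range, prefer `cut_override` with a generous cut
over the automatic estimate.

## 4. Spatial blocking

`cluster_regions()` applies agglomerative hierarchical clustering to the
inter-region distance matrix and cuts the dendrogram at the semivariogram
range. **Complete linkage is the default because it alone guarantees the
property that makes the cut meaningful**: every block's internal diameter
is bounded by the cut distance, so no two regions closer than the
correlation range can be separated into different CV folds. Average and
single linkage are available but forfeit that bound. Ties in merge
heights are resolved deterministically by `hclust`; block labels are
renumbered in order of first appearance so partitions are stable across
platforms and region orderings (the tests verify permutation invariance
of the partition). A cut yielding a single block is an error with an
actionable message, since cross-validation is then impossible. Block
count is always an outcome of the cut, never a target: the number of
spatially coherent communities a geography supports at a given
correlation range is an empirical fact, not a tuning knob.

No contiguity constraint is imposed — clustering metric distances usually
yields near-contiguous blocks, and a hard constraint would trade the
diameter guarantee for cosmetics.

## 5. Cross-validation, metrics, and the leakage comparison

One random forest is trained per leave-one-block-out fold (library-default
hyperparameters — `ntree = 500`, `mtry = p/3` — unless overridden), and
each region is predicted exactly once out-of-fold. Headline `r²` and MAE
are **pooled** over the concatenated out-of-fold predictions; per-fold
values are also reported but are unstable on folds of a handful of
regions (per-fold `r²` is undefined on singleton or constant folds and
reported as `NA`). Per-fold seeds derive from the master seed by a fixed
counter, so any fold can be reproduced in isolation.

`compare_cv_schemes()` runs the spatial scheme and region-shuffled
k-fold CV (default `k = 10`) on identical data and reports both pooled
`r²` values and their gap. On spatially confounded data the gap is
positive: random folds let the forest exploit neighbourhood similarity
between training and validation regions. The package's acceptance
experiment makes this a reproducible property: across 20 synthetic worlds
whose mortality signal is a latent spatial field *absent from the
features*, random CV reports higher `r²` than spatial CV in ≥ 90% of
replicates with a mean gap above 0.1 — spurious skill, since the features
are causally inert by construction.

Permutation importance (default 10 repeats) measures score degradation
when one feature column is shuffled; a feature the trees never split on
degrades nothing and scores exactly zero.

## 6. Exact Shapley attribution

Attributions follow the coalition-game formulation with the
**interventional** value function: `f_x(F)` is the mean model prediction
over a background sample with the instance's values substituted on the
coalition `F`. A plausible alternative reading — retraining the model
with and without each feature — is exponential in model fits and is not
what tree-attribution frameworks compute; the interventional expectation
is the semantics adopted here, with the background defaulting to the full
training set.

Two independent routes are implemented and cross-checked:

1. **Subset enumeration** (`exact_shapley()`): all `2^p` coalitions,
   capped at `p ≤ 12`, model-agnostic. This is the reference
   implementation — a direct transcription of the defining sum.
2. **Interventional tree traversal** (`tree_shapley()`, Rcpp): for a
   forest, each leaf is an axis-aligned box, so for one background row the
   coalition game decomposes into per-leaf indicator games whose Shapley
   values have closed forms (`+(u−1)!v!/(u+v)!` for features that must be
   in the coalition, `−u!(v−1)!/(u+v)!` for features that must be out,
   where `u` and `v` count those features on the leaf's path). Summing
   over leaves, background rows and trees reproduces enumeration exactly
   in polynomial time.

The tests enforce the axioms on both routes: efficiency
(`base + Σ phi = prediction`) to 1e-6 relative on every instance, exact
agreement between routes on a 10-feature forest with full-training
background, zero attribution for features constant in training (dummy
axiom), and symmetry. Global importance is the mean of `|phi|` over
regions, ties broken lexicographically. By default explanations come from
a full-data refit after CV assessment — the CV answers "how well does
this generalize", the refit answers "what does the model actually use";
explaining per-fold models is possible by passing them directly.

## 7. The synthetic test bed

`build_world()` composes the generative model the analysis assumes:

| Component | Default | Rationale |
|---|---|---|
| Grid | 20×20 cells | desk-scale; dense Cholesky GRF is exact here |
| Regions | 60, contiguous | grown by seeded 4-neighbour accretion, guaranteeing connectivity on small grids (Voronoi cannot) |
| Exposure fields | exponential GRF, range 10, sill 1, nugget 0 | effective-range parameterisation `C(d)=sill·e^{−3d/range}`; range at half the domain exercises the blocking machinery |
| Time | 365 steps, iid noise sd 1 | a year of daily data; temporal mean is unbiased for the base field |
| Features | 15 total: 2 pollutants × (mean, std) + 11 iid noise columns | noise socio-economic stand-ins give recovery tests a clean null |
| Ages | 5 classes, rates 5e-4 … 0.04 /person-year | rising steeply with age, as respiratory-cancer rates do |
| Population | ~1e5 per region (lognormal, sd 0.4 log units) | expected deaths of a few hundred, so Poisson noise on SMR (sd ≈ 0.04–0.07) is realistic but does not drown the planted effects |
| Effects | betas ±0.3 per sd of feature, on features 1–2 | moderate, recoverable effect sizes |

Features are standardized before the betas apply, so effect sizes are
comparable across features; deaths are Poisson with mean `E_i · exp(Σ
beta_j x_ij)`. Everything is deterministic given the master seed, which
fans out to stages by fixed offsets, so any stage can be rerun alone.

`simulate_confounded_world()` is the leakage scenario: features are zonal
means of independent GRFs (spatially smooth, causally inert) and the
mortality signal is a separate latent GRF. Nearby regions then share both
feature vectors and outcomes without any feature→outcome link — the
precise condition under which random CV rewards memorisation.

**What passing tests do not show.** The generator draws stationary
isotropic Gaussian fields, iid temporal noise, a shared age pyramid, and
exact Poisson counts. Real exposure surfaces are non-stationary
(orography, sources), real temporal noise is autocorrelated and seasonal,
real age structures covary with the outcome, and real death counts are
overdispersed and spatially smoothed by care-seeking across borders.
Passing on the test bed certifies the *machinery* — estimators match
their definitions, guarantees hold, leakage is detected when present — not
that any particular real-world analysis is unconfounded.

## 8. Numerical choices and degenerate inputs

- GRF simulation adds a `1e-10` diagonal jitter before Cholesky; fields
  at near-zero sill or with coincident points are therefore equal only to
  ≈ 1e-4, which the documentation and tests reflect.
- Semivariogram bins are half-open `(lo, hi]` with the lower boundary of
  the first bin included; empty bins carry `NA` semivariance and zero
  pair count, and all-empty binnings are an error.
- `r²` is a hard error for a constant observed vector (the denominator
  vanishes); cross-validation reports `NA` instead when the pooled truth
  is constant, since a degenerate target is a data property, not a bug.
- SMR requires strictly positive expected deaths and errors naming the
  offending region; zero observed deaths are a valid SMR of 0.
- Outlier flagging requires ≥ 4 values (quartiles are meaningless below);
  region growth requires `n_regions ≤` cell count.
- All JSON artifacts are written at full double precision and all
  randomness flows from seeds, so pipeline reruns are bit-identical — the
  property the end-to-end determinism test asserts on checksums.

## 9. Problem sizes used by the test suite

The suite exercises study-scale conditions where the property demands it
(20 worlds of 60 regions for the leakage experiment; 20 replicate worlds
for feature recovery; 50 random instances for estimator-oracle equality)
and desk-scale fixtures everywhere else (10–14 cell grids, 12–30
regions, forests of 30–200 trees), keeping a full run to a few minutes
while leaving every contract covered.
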