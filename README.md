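# spatialsmr

Leakage-aware spatial modelling of standardized mortality ratios (SMR),
with exact Shapley feature attribution.

`spatialsmr` is for epidemiologists and spatial data scientists who model
small-area mortality from gridded environmental exposures (e.g. air-quality
reanalysis fields) and socio-economic covariates, and who need two things
that naive workflows get wrong:

1. **Honest cross-validation.** Regional health outcomes and their
   predictors are spatially autocorrelated. Randomly splitting regions into
   CV folds places near neighbours of every validation region in the
   training set, so the model is partly rewarded for memorising
   neighbourhoods — *spatial data leakage*. The package estimates the
   spatial correlation range of the SMR surface from its empirical
   semivariogram, builds spatially coherent blocks by cutting a
   hierarchical clustering of inter-region distances at that range, and
   evaluates models by leave-one-block-out CV. A built-in comparison
   quantifies how much a random CV scheme overstates skill on the same
   data.
2. **Exact explanation.** Per-region, per-feature Shapley attributions of
   the fitted model, computed exactly — by subset enumeration for small
   feature counts and by an interventional tree-traversal algorithm for
   random forests (identical values, polynomial time) — plus the global
   mean-|phi| feature ranking.

A synthetic-data module simulates the whole data-generating process —
Gaussian random field exposure surfaces with a known correlation range,
contiguous regions partitioning the grid, age-structured populations, and
Poisson deaths with known log-linear feature effects — so every stage of
the chain is testable against ground truth.

## The statistics in brief

- **Indirect standardization.** Expected deaths apply reference age-specific
  rates to each region's age pyramid, `E_i = Σ_a pop_{i,a} · rate_a`, and
  the standardized mortality ratio is `SMR_i = O_i / E_i`. Regions flagged
  as outliers by Tukey fences (`[Q1 − 1.5·IQR, Q3 + 1.5·IQR]`) on the SMR
  distribution are excluded from modelling but retained in output tables.
- **Empirical semivariogram** (Matheron): for lag bin `h`,
  `γ(h) = 1/(2N(h)) Σ_{pairs in h} (z_i − z_j)²`. The range is the first
  (smoothed) bin where `γ` reaches `0.95 ×` the sample variance — the
  plateau onset beyond which observations are effectively uncorrelated.
- **Spatial blocking.** Complete-linkage hierarchical clustering of the
  distance matrix, cut at the range, guarantees every block's internal
  diameter is at most the cut; leave-one-block-out folds then never split
  correlated neighbours across train and validation.
- **Model and metrics.** A random forest regressor (library defaults)
  predicts SMR from the features; skill is summarised by
  `r² = 1 − Σ(y_i − ŷ_i)² / Σ(y_i − ȳ)²` and `MAE = (1/n) Σ|y_i − ŷ_i|`
  pooled over out-of-fold predictions, plus permutation feature importance.
- **Shapley attribution.**
  `Φ_j(x) = Σ_{F ⊆ S∖{j}} |F|!(|S|−|F|−1)!/|S|! · [f_x(F ∪ {j}) − f_x(F)]`
  with the interventional value function `f_x(F)` = mean model prediction
  over background rows with the instance's values substituted on `F`.
  Attributions satisfy efficiency: `base + Σ_j Φ_j` equals the prediction.

## Worked example: demonstrating spatial leakage

Simulate a world where the mortality signal is a smooth latent spatial
field that is *not* among the model features, while the features are
spatially autocorrelated but causally inert — the configuration in which
random CV flatters a model most:

```r
library(spatialsmr)

world <- simulate_confounded_world(grid_side = 20, n_regions = 60, seed = 1)
smr_kept <- world$smr[!world$smr$outlier, ]
regions  <- world$regions[!world$smr$outlier, ]
features <- world$features[!world$smr$outlier, ]

dm <- pairwise_distances(regions)
rownames(dm) <- colnames(dm) <- as.character(regions$region_id)
sv <- estimate_range(empirical_semivariogram(smr_kept$smr, dm))
glance(sv)
#> # A tibble: 1 × 5
#>    sill range converged n_bins n_pairs
#>   <dbl> <dbl> <lgl>      <int>   <int>
#> 1 0.103  6.78 TRUE          15    1116

blocks <- cluster_regions(dm, cut_distance = sv$range_estimate)
glance(blocks)
#> # A tibble: 1 × 5
#>   n_blocks cut_distance linkage  min_size max_size
#>      <int>        <dbl> <chr>       <int>    <int>
#> 1       12         6.78 complete        2        8

cv <- fit_predict_cv(features, smr_kept, locv_folds(blocks), seed = 1)
cv
#> <smr_cv> 12 folds, 60 regions
#>   pooled r2 = 0.0547, pooled MAE = 0.2481

compare_cv_schemes(features, smr_kept, blocks, k_random = 10,
                   n_repeats = 3, seed = 1)[, c("r2_spatial", "r2_random", "gap")]
#> # A tibble: 1 × 3
#>   r2_spatial r2_random   gap
#>        <dbl>     <dbl> <dbl>
#> 1     0.0547     0.191 0.136
```

The SMR surface plateaus at a lag of ≈ 6.8 grid units, giving 12 spatial
blocks. Under honest leave-one-block-out CV the forest has essentially no
skill (r² ≈ 0.05) — correct, since the features carry no causal signal —
but random 10-fold CV reports r² ≈ 0.19. The gap of ≈ 0.14 is pure spatial
leakage.

Explanation of a fitted model takes one line each for local attributions
and the global ranking:

```r
fit  <- fit_forest_full(features, smr_kept, seed = 1)
shap <- shapley_all_regions(fit, features)   # exact, interventional
head(global_rank(shap), 3)
#> # A tibble: 3 × 3
#>   feature mean_abs_phi  rank
#>   <chr>          <dbl> <int>
#> 1 feat_2        0.0608     1
#> 2 feat_8        0.0500     2
#> 3 feat_6        0.0274     3
autoplot(shap)   # beeswarm-style summary plot
```

`run_pipeline(build_world(synthetic_config(...)), out_dir)` executes the
whole chain — zonal aggregation, standardization, variogram, blocking,
CV, scheme comparison, importance, Shapley — writing each stage's artifact
and a checksummed manifest; identical seeds give bit-identical outputs.

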