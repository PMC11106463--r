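# Cross-validated random forest regression of SMR, the r2 / MAE metrics,
# permutation importance, and the spatial-vs-random scheme comparison.

test_that("r2 and mae match their single-line oracles", {
  expect_equal(r2(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(2, 4, 9)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_equal(r2(c(1, 2, 3), c(1, 2, 2)), 0.5)

  expect_equal(mae(c(1, 2), c(1, 2)), 0)
  expect_equal(mae(c(1, 2, 3), c(2, 2, 2)), 2 / 3)

  withr::with_seed(8, {
    for (rep in 1:20) {
      y <- rnorm(50); yhat <- rnorm(50)
      expect_equal(r2(y, yhat),
                   1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
                   tolerance = 1e-12)
      expect_equal(mae(y, yhat), mean(abs(y - yhat)), tolerance = 1e-12)
      # shifting predictions by c changes MAE by at most c
      expect_lte(mae(y, yhat + 0.3), mae(y, yhat) + 0.3 + 1e-12)
    }
  })

  expect_error(r2(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("leave-one-block-out folds partition the regions", {
  pts <- data.frame(region_id = paste0("r", 1:15),
                    x = c(rnorm(5, 0), rnorm(5, 20), rnorm(5, 40)), y = 0)
  dm <- pairwise_distances(pts)
  b <- cluster_regions(dm, cut_distance = 10)
  folds <- locv_folds(b)
  expect_equal(length(folds), b$n_blocks)
  val <- unlist(lapply(folds, `[[`, "validation"))
  expect_setequal(val, pts$region_id)
  expect_equal(anyDuplicated(val), 0L)
  for (f in folds) {
    expect_length(intersect(f$train, f$validation), 0)
    expect_setequal(c(f$train, f$validation), pts$region_id)
  }
})

test_that("fit_predict_cv predicts every region once, deterministically", {
  w <- tiny_world(seed = 5)
  target <- tibble::tibble(region_id = w$mortality$region_id,
                           smr = smr(w$mortality$deaths, w$mortality$expected))
  dm <- pairwise_distances(w$regions)
  rownames(dm) <- colnames(dm) <- as.character(w$regions$region_id)
  b <- cluster_regions(dm, cut_distance = 4)
  folds <- locv_folds(b)

  cv1 <- fit_predict_cv(w$features, target, folds,
                        model_config = list(ntree = 60), seed = 3)
  expect_setequal(cv1$predictions$region_id, as.character(target$region_id))
  expect_equal(anyDuplicated(cv1$predictions$region_id), 0L)
  expect_lte(cv1$pooled$r2, 1)
  expect_gte(cv1$pooled$mae, 0)

  cv2 <- fit_predict_cv(w$features, target, folds,
                        model_config = list(ntree = 60), seed = 3)
  expect_identical(cv1$predictions, cv2$predictions)

  # constant target: trees predict the training mean, MAE collapses
  const <- dplyr::mutate(target, smr = 0.7)
  cvc <- suppressWarnings(  # the forest warns on a degenerate response
    fit_predict_cv(w$features, const, folds,
                   model_config = list(ntree = 30), seed = 1)
  )
  expect_lt(cvc$pooled$mae, 1e-10)
  expect_true(is.na(cvc$pooled$r2))

  expect_error(
    fit_predict_cv(w$features[-1, ], target, folds, seed = 1),
    "different region sets"
  )
})

test_that("an informative feature yields out-of-fold skill", {
  withr::with_seed(12, {
    n <- 120
    feats <- tibble::tibble(region_id = paste0("r", 1:n),
                            signal = rnorm(n), junk = rnorm(n))
    target <- tibble::tibble(region_id = feats$region_id,
                             smr = feats$signal + rnorm(n, 0, 0.2))
    folds <- lapply(1:4, function(k) {
      idx <- seq(k, n, by = 4)
      list(train = feats$region_id[-idx], validation = feats$region_id[idx])
    })
    cv <- fit_predict_cv(feats, target, folds,
                         model_config = list(ntree = 150), seed = 2)
    expect_gt(cv$pooled$r2, 0.5)
  })
})

test_that("permutation importance isolates used features", {
  withr::with_seed(21, {
    n <- 80
    feats <- tibble::tibble(region_id = paste0("r", 1:n),
                            signal = rnorm(n),
                            noise = rnorm(n),
                            frozen = rep(1, n))
    target <- tibble::tibble(region_id = feats$region_id,
                             smr = 2 * feats$signal + rnorm(n, 0, 0.1))
    fit <- fit_forest_full(feats, target, model_config = list(ntree = 150),
                           seed = 4)
    imp <- permutation_importance(fit, feats, target, n_repeats = 10, seed = 9)
    expect_equal(imp$feature[imp$rank == 1], "signal")
    # a constant feature is never split on: degradation is exactly zero
    expect_equal(imp$importance[imp$feature == "frozen"], 0)
    # pure noise stays in a band around zero
    expect_lt(abs(imp$importance[imp$feature == "noise"]), 0.15)
  })
})

test_that("random CV outscores spatial CV on confounded worlds", {
  res <- lapply(1:3, function(s) {
    w <- simulate_confounded_world(grid_side = 14, n_regions = 30,
                                   n_features = 6, grf_range = 7, seed = s)
    keep <- !w$smr$outlier
    feats <- w$features[keep, ]
    smrk <- w$smr[keep, ]
    dm <- pairwise_distances(w$regions[keep, ])
    rownames(dm) <- colnames(dm) <- as.character(w$regions$region_id[keep])
    sv <- estimate_range(empirical_semivariogram(smrk$smr, dm))
    b <- cluster_regions(dm, cut_distance = sv$range_estimate)
    compare_cv_schemes(feats, smrk, b, k_random = 5, n_repeats = 2,
                       model_config = list(ntree = 150), seed = s)
  })
  gaps <- vapply(res, function(r) r$gap, numeric(1))
  expect_gt(mean(gaps), 0)

  # determinism of the comparison under a fixed seed
  w <- simulate_confounded_world(grid_side = 12, n_regions = 20,
                                 n_features = 4, grf_range = 6, seed = 9)
  dm <- pairwise_distances(w$regions)
  rownames(dm) <- colnames(dm) <- as.character(w$regions$region_id)
  b <- cluster_regions(dm, cut_distance = 6)
  c1 <- compare_cv_schemes(w$features, w$smr, b, k_random = 4, n_repeats = 2,
                           model_config = list(ntree = 50), seed = 5)
  c2 <- compare_cv_schemes(w$features, w$smr, b, k_random = 4, n_repeats = 2,
                           model_config = list(ntree = 50), seed = 5)
  expect_identical(c1, c2)
})
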