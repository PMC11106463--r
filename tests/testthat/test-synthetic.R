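# Synthetic world generator: region growth, Gaussian random fields,
# exposure series, Poisson mortality, and full-world composition.

test_that("make_regions partitions the grid into connected regions", {
  # degenerate partitions
  one <- make_regions(1, 1, seed = 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$region_id, 1L)
  singletons <- make_regions(4, 16, seed = 1)
  expect_equal(sort(unique(singletons$region_id)), 1:16)
  expect_equal(nrow(singletons), 16)

  # general case: total surjective membership, connectivity by flood fill
  cells <- make_regions(10, 7, seed = 1)
  expect_equal(nrow(cells), 100)
  expect_false(any(is.na(cells$region_id)))
  expect_setequal(unique(cells$region_id), 1:7)
  expect_true(all(table(cells$region_id) >= 1))
  expect_true(oracle_regions_connected(cells, 10))

  expect_error(make_regions(3, 10), "exceeds")
})

test_that("simulate_grf honours its covariance model", {
  pts <- expand.grid(x = 1:5, y = 1:5)
  # near-zero sill: field collapses to zero (up to the stabilizing jitter)
  z0 <- simulate_grf(pts, range = 2, sill = 1e-14, nugget = 0, seed = 1)
  expect_lt(max(abs(z0)), 1e-4)

  # coincident points with no nugget are perfectly correlated
  dup <- data.frame(x = c(1, 1, 4), y = c(2, 2, 4))
  zd <- simulate_grf(dup, range = 3, sill = 1, nugget = 0, seed = 2)
  expect_equal(unname(zd[1]), unname(zd[2]), tolerance = 1e-4)

  # Monte-Carlo: pooled semivariance at lags >= range matches the sill
  grid <- expand.grid(x = 1:20, y = 1:20)
  dm <- as.matrix(dist(grid))
  far <- dm >= 10 & upper.tri(dm)
  pooled <- mean(vapply(1:50, function(s) {
    z <- simulate_grf(grid, range = 10, sill = 1, nugget = 0, seed = 100 + s)
    diffs <- outer(z, z, "-")[far]
    mean(diffs^2) / 2
  }, numeric(1)))
  expect_gt(pooled, 0.85)
  expect_lt(pooled, 1.15)
})

test_that("exposure series have the stated temporal structure", {
  base <- c(-1, 0, 2)
  exact <- simulate_exposure_series(base, n_timesteps = 4, temporal_sd = 0, seed = 1)
  expect_equal(exact, matrix(base, 3, 4), ignore_attr = TRUE)
  one <- simulate_exposure_series(base, n_timesteps = 1, temporal_sd = 1, seed = 1)
  expect_equal(dim(one), c(3L, 1L))

  # chi-square bounds on the sample sd at n = 365
  series <- simulate_exposure_series(rep(0, 400), 365, temporal_sd = 1, seed = 3)
  sds <- apply(series, 1, sd)
  expect_gte(mean(sds >= 0.85 & sds <= 1.15), 0.95)
  # temporal mean is unbiased for the base field
  expect_lt(abs(mean(rowMeans(series))), 0.02)
})

test_that("simulate_mortality draws Poisson deaths at E * RR", {
  # three regions with x = (1, 0, -1) standardize to exactly (1, 0, -1);
  # region 1 has E = 100 and beta = ln 2, so its deaths average 200
  pop3 <- tibble::tibble(region_id = rep(1:3, each = 1), age_class = "a1",
                         population = 5000)
  feats <- tibble::tibble(region_id = 1:3, x1 = c(1, 0, -1))
  reps <- vapply(1:1000, function(s) {
    simulate_mortality(pop3, feats, betas = log(2), active = 1L,
                       national_rates = 0.02, seed = s)$deaths[1]
  }, integer(1))
  expect_gt(mean(reps), 190)  # Poisson mean 200, CI by normal approximation
  expect_lt(mean(reps), 210)
  feats1 <- tibble::tibble(region_id = 1L, x1 = 1)

  # zero population implies zero deaths
  pop0 <- tibble::tibble(region_id = 1L, age_class = "a1", population = 0)
  expect_warning(
    d0 <- simulate_mortality(pop0, feats1, numeric(0), integer(0), 0.02, seed = 1),
    "degenerate"
  )
  expect_equal(d0$deaths, 0L)

  pop_neg <- tibble::tibble(region_id = 1L, age_class = "a1", population = -5)
  expect_error(
    simulate_mortality(pop_neg, feats, numeric(0), integer(0), 0.02),
    "negative population"
  )
})

test_that("null-model SMR is centred on 1 across regions and replicates", {
  smrs <- unlist(lapply(1:3, function(s) {
    w <- build_world(synthetic_config(
      grid_side = 10, n_regions = 12, n_timesteps = 10, n_pollutants = 1,
      n_features = 4, active_features = integer(0), betas = numeric(0),
      grf_range = 5, seed = s
    ))
    smr(w$mortality$deaths, w$mortality$expected)
  }))
  se <- sd(smrs) / sqrt(length(smrs))
  expect_lt(abs(mean(smrs) - 1), 3 * se)
})

test_that("build_world is deterministic and keeps its bookkeeping", {
  w1 <- tiny_world(seed = 7)
  w2 <- tiny_world(seed = 7)
  expect_identical(w1$features, w2$features)
  expect_identical(w1$mortality, w2$mortality)
  expect_identical(w1$cells, w2$cells)

  w <- build_world(synthetic_config(grid_side = 10, n_regions = 12,
                                    n_timesteps = 10, n_features = 15,
                                    active_features = c(1, 2),
                                    betas = c(0.3, -0.3), grf_range = 5,
                                    seed = 2))
  expect_equal(ncol(w$features) - 1, 15)
  expect_equal(unname(which(w$true_betas != 0)), c(1L, 2L))

  # world-level invariants: total membership, non-empty regions, aligned axes
  expect_false(any(is.na(w$cells$region_id)))
  expect_setequal(w$regions$region_id, unique(w$cells$region_id))
  expect_true(all(table(w$cells$region_id) >= 1))
  expect_setequal(unique(w$population$age_class), w$rates$age_class)
})

test_that("synthetic_config rejects inconsistent settings", {
  expect_error(synthetic_config(n_regions = 500, grid_side = 10), "exceeds")
  expect_error(synthetic_config(active_features = c(1, 99)), "active_features")
  expect_error(synthetic_config(active_features = c(1, 2), betas = 0.3), "betas")
  expect_error(synthetic_config(national_rates = c(0.1, 0.2)), "length")
})
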