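# Synthetic worlds with the statistical structure the analysis assumes:
# spatially autocorrelated exposure fields, contiguous regions partitioning a
# regular grid, age-structured populations and Poisson death counts whose log
# relative risk is linear in a known subset of standardized region features.

#' Configuration for a synthetic world
#'
#' Bundles and validates every parameter of the synthetic data generator.
#' Defaults describe the package's standard test bed: a 20 x 20 unit grid
#' partitioned into 60 contiguous regions, exposure fields drawn from a
#' Gaussian random field with effective range 10 grid units, a year of daily
#' observations, and age-structured mortality with rates typical of
#' respiratory cancer.
#'
#' @param grid_side Cells per axis of the square grid.
#' @param n_regions Number of contiguous regions partitioning the grid.
#' @param n_timesteps Time steps (days) per exposure series.
#' @param grf_range Effective range of the exposure random fields, in grid
#'   units: the distance at which covariance drops to 5% of the sill.
#' @param grf_sill Variance (sill) of the exposure random fields.
#' @param grf_nugget Nugget variance (micro-scale noise) of the fields.
#' @param temporal_sd Standard deviation of the day-to-day noise added to
#'   each cell's base field value.
#' @param n_pollutants Number of independent exposure fields; each yields a
#'   temporal-mean and a temporal-sd feature after zonal aggregation.
#' @param n_features Total feature count; columns beyond the
#'   `2 * n_pollutants` exposure features are iid standard normal
#'   socio-economic stand-ins.
#' @param active_features Integer indices (1-based) of features with a
#'   nonzero effect on log relative risk.
#' @param betas Log relative risk per unit of standardized feature, one per
#'   active feature.
#' @param n_age_classes Number of age classes.
#' @param national_rates Reference death rates per person-year, one per age
#'   class, each in (0, 1).
#' @param pop_mean Mean region population (total over age classes).
#' @param seed Integer master seed.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
#' @examples
#' cfg <- synthetic_config(grid_side = 8, n_regions = 6, n_timesteps = 30)
synthetic_config <- function(grid_side = 20,
                             n_regions = 60,
                             n_timesteps = 365,
                             grf_range = 10,
                             grf_sill = 1,
                             grf_nugget = 0,
                             temporal_sd = 1,
                             n_pollutants = 2,
                             n_features = 15,
                             active_features = c(1L, 2L),
                             betas = c(0.3, -0.3),
                             n_age_classes = 5,
                             national_rates = c(5e-4, 1e-3, 4e-3, 1.2e-2, 4e-2),
                             pop_mean = 1e5,
                             seed = 1L) {
  stopifnot(
    grid_side >= 1, n_regions >= 1, n_timesteps >= 1,
    grf_range > 0, grf_sill > 0, grf_nugget >= 0, temporal_sd >= 0,
    n_pollutants >= 1, n_features >= 2 * n_pollutants,
    n_age_classes >= 1, length(national_rates) == n_age_classes,
    all(national_rates > 0), all(national_rates < 1),
    pop_mean > 0
  )
  if (n_regions > grid_side^2) {
    stop("invalid config: n_regions (", n_regions, ") exceeds number of grid cells (",
         grid_side^2, ")", call. = FALSE)
  }
  active_features <- as.integer(active_features)
  if (length(active_features) > 0) {
    if (any(active_features < 1L | active_features > n_features)) {
      stop("invalid config: active_features must lie in 1..n_features", call. = FALSE)
    }
    if (length(betas) != length(active_features)) {
      stop("invalid config: betas must have one entry per active feature", call. = FALSE)
    }
  }
  structure(
    list(
      grid_side = as.integer(grid_side), n_regions = as.integer(n_regions),
      n_timesteps = as.integer(n_timesteps), grf_range = grf_range,
      grf_sill = grf_sill, grf_nugget = grf_nugget, temporal_sd = temporal_sd,
      n_pollutants = as.integer(n_pollutants), n_features = as.integer(n_features),
      active_features = active_features, betas = as.numeric(betas),
      n_age_classes = as.integer(n_age_classes),
      national_rates = as.numeric(national_rates),
      pop_mean = pop_mean, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

#' Partition a square grid into contiguous regions
#'
#' Grows regions from randomly placed seed cells by repeated accretion of
#' cells adjacent (4-neighbour) to an already-assigned cell, so every
#' region's cell set is connected and the regions partition the grid.
#'
#' @param grid_side Cells per axis.
#' @param n_regions Number of regions; must not exceed `grid_side^2`.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per cell: `cell_id`, cell-center
#'   coordinates `x`, `y` (grid units, 1-based), and `region_id`.
#' @export
#' @examples
#' cells <- make_regions(grid_side = 6, n_regions = 4, seed = 1)
#' table(cells$region_id)
make_regions <- function(grid_side, n_regions, seed = 1L) {
  n_cells <- grid_side^2
  if (n_regions > n_cells) {
    stop("invalid config: n_regions (", n_regions, ") exceeds number of cells (",
         n_cells, ")", call. = FALSE)
  }
  stopifnot(n_regions >= 1)
  coords <- expand.grid(x = seq_len(grid_side), y = seq_len(grid_side))
  assignment <- withr::with_seed(seed, {
    memb <- rep(NA_integer_, n_cells)
    seeds <- sample.int(n_cells, n_regions)
    memb[seeds] <- seq_len(n_regions)
    # 4-neighbour adjacency on the row-major grid
    neighbours <- function(i) {
      x <- coords$x[i]; y <- coords$y[i]
      out <- integer(0)
      if (x > 1) out <- c(out, i - 1L)
      if (x < grid_side) out <- c(out, i + 1L)
      if (y > 1) out <- c(out, i - grid_side)
      if (y < grid_side) out <- c(out, i + grid_side)
      out
    }
    unassigned <- which(is.na(memb))
    while (length(unassigned) > 0) {
      # frontier: unassigned cells adjacent to an assigned cell (always
      # non-empty on a connected grid)
      frontier <- unassigned[vapply(unassigned, function(i) {
        any(!is.na(memb[neighbours(i)]))
      }, logical(1))]
      pick <- frontier[sample.int(length(frontier), 1L)]
      nb <- neighbours(pick)
      nb <- nb[!is.na(memb[nb])]
      memb[pick] <- memb[nb[sample.int(length(nb), 1L)]]
      unassigned <- unassigned[unassigned != pick]
    }
    memb
  })
  tibble::tibble(
    cell_id = seq_len(n_cells),
    x = as.numeric(coords$x),
    y = as.numeric(coords$y),
    region_id = assignment
  )
}

#' Simulate a Gaussian random field on arbitrary points
#'
#' Draws one realization of a zero-mean Gaussian process with exponential
#' covariance `C(d) = sill * exp(-3 d / range)` (so the covariance falls to
#' 5% of the sill at `d = range`, the effective range), plus independent
#' nugget noise, by dense Cholesky factorization of the covariance matrix.
#' Intended for desk-scale grids (up to a few thousand points).
#'
#' @param cell_coords Data frame with columns `x` and `y` (planar units).
#' @param range Effective range, same units as the coordinates; > 0.
#' @param sill Process variance; > 0.
#' @param nugget Nugget variance; >= 0.
#' @param seed Integer seed.
#'
#' @return Numeric vector with one value per row of `cell_coords`.
#' @export
#' @examples
#' pts <- expand.grid(x = 1:10, y = 1:10)
#' z <- simulate_grf(pts, range = 5, sill = 1, nugget = 0, seed = 1)
simulate_grf <- function(cell_coords, range, sill, nugget = 0, seed = 1L) {
  stopifnot(range > 0, sill > 0, nugget >= 0)
  xy <- as.matrix(cell_coords[, c("x", "y")])
  n <- nrow(xy)
  d <- as.matrix(stats::dist(xy))
  sigma <- sill * exp(-3 * d / range)
  # small diagonal jitter keeps the factorization stable for smooth fields
  ch <- tryCatch(
    chol(sigma + diag(1e-10 * max(sill, 1), n)),
    error = function(e) {
      stop("covariance matrix not positive definite after jitter (n = ", n,
           ", range = ", range, "): ", conditionMessage(e), call. = FALSE)
    }
  )
  withr::with_seed(seed, {
    z <- drop(crossprod(ch, rnorm(n)))
    if (nugget > 0) z <- z + rnorm(n, sd = sqrt(nugget))
    z
  })
}

#' Add temporal noise to a base exposure field
#'
#' Expands a static per-cell field into a multi-day series by adding iid
#' Gaussian noise at each time step, so the temporal mean per cell is an
#' unbiased estimate of the base field and the temporal standard deviation
#' is approximately `temporal_sd`.
#'
#' @param base_field Numeric vector, one value per cell.
#' @param n_timesteps Number of time steps; >= 1.
#' @param temporal_sd Standard deviation of the per-step noise; >= 0.
#' @param seed Integer seed.
#'
#' @return Numeric matrix, cells x timesteps.
#' @export
simulate_exposure_series <- function(base_field, n_timesteps, temporal_sd, seed = 1L) {
  stopifnot(n_timesteps >= 1, temporal_sd >= 0)
  n <- length(base_field)
  withr::with_seed(seed, {
    noise <- matrix(rnorm(n * n_timesteps, sd = temporal_sd), nrow = n)
    series <- base_field + noise
    dimnames(series) <- list(NULL, NULL)
    series
  })
}

#' Simulate observed deaths under a log-linear relative-risk model
#'
#' Computes expected deaths per region by applying reference age-specific
#' rates to the region's age structure, multiplies by a relative risk
#' `RR_i = exp(sum_j beta_j * x_ij)` over the active (standardized)
#' features, and draws Poisson death counts.
#'
#' @param population Long tibble: `region_id`, `age_class`, `population`.
#' @param features Tibble with `region_id` and one column per feature.
#'   Columns are standardized (zero mean, unit variance) internally before
#'   the betas are applied.
#' @param betas Log relative risks, one per entry of `active`.
#' @param active Integer indices (1-based, into the feature columns) or
#'   character names of the features with nonzero effect. May be empty.
#' @param national_rates Named or ordered vector of death rates per
#'   person-year, one per age class (matching `population$age_class` levels).
#' @param seed Integer seed.
#'
#' @return Tibble: `region_id`, `expected` (deaths under reference rates),
#'   `relative_risk`, `deaths` (integer Poisson draw).
#' @export
simulate_mortality <- function(population, features, betas, active,
                               national_rates, seed = 1L) {
  if (any(population$population < 0)) {
    stop("invalid input: negative population counts", call. = FALSE)
  }
  exp_tbl <- expected_deaths(population, tibble::tibble(
    age_class = sort(unique(population$age_class)),
    rate = as.numeric(national_rates)
  ))
  feat_cols <- setdiff(names(features), "region_id")
  if (is.character(active)) active <- match(active, feat_cols)
  stopifnot(length(betas) == length(active))
  xmat <- scale(as.matrix(features[, feat_cols, drop = FALSE]))
  eta <- if (length(active) > 0) {
    drop(xmat[, active, drop = FALSE] %*% betas)
  } else {
    rep(0, nrow(features))
  }
  rr <- exp(eta)[match(exp_tbl$region_id, features$region_id)]
  if (any(exp_tbl$expected == 0 & rr > 0)) {
    warning("degenerate region(s) with zero expected deaths: ",
            paste(exp_tbl$region_id[exp_tbl$expected == 0], collapse = ", "))
  }
  deaths <- withr::with_seed(seed, rpois(nrow(exp_tbl), exp_tbl$expected * rr))
  tibble::tibble(
    region_id = exp_tbl$region_id,
    expected = exp_tbl$expected,
    relative_risk = rr,
    deaths = as.integer(deaths)
  )
}

# Age-structure helper: region populations around pop_mean, split over age
# classes by a shared pyramid with mild regional perturbation.
simulate_population <- function(region_ids, n_age_classes, pop_mean, seed) {
  withr::with_seed(seed, {
    n <- length(region_ids)
    totals <- stats::rlnorm(n, meanlog = log(pop_mean), sdlog = 0.4)
    base_shares <- rev(seq_len(n_age_classes))^1.2
    base_shares <- base_shares / sum(base_shares)
    purrr::map_dfr(seq_len(n), function(i) {
      w <- base_shares * exp(rnorm(n_age_classes, sd = 0.1))
      w <- w / sum(w)
      tibble::tibble(
        region_id = region_ids[i],
        age_class = paste0("age_", seq_len(n_age_classes)),
        population = round(totals[i] * w)
      )
    })
  })
}

#' Build a complete synthetic world
#'
#' Composes the generator stages: contiguous regions on a grid, Gaussian
#' random field exposure surfaces expanded into daily series, zonal
#' exposure features (temporal mean/sd aggregated within regions), iid
#' socio-economic stand-in features, age-structured populations, and
#' Poisson deaths with the configured planted effects. Deterministic given
#' the config seed.
#'
#' @param config A [synthetic_config()].
#'
#' @return A list of class `synthetic_world` with elements `cells` (cell
#'   table with region membership), `series` (named list of cell x time
#'   matrices, one per pollutant), `regions` (tibble with region centroids),
#'   `population` (long tibble), `rates` (age-class reference rates),
#'   `mortality` (expected, relative risk, observed deaths), `features`
#'   (region x feature tibble), `true_betas` (named vector over feature
#'   columns) and `true_range`.
#' @export
#' @examples
#' world <- build_world(synthetic_config(grid_side = 8, n_regions = 6,
#'                                       n_timesteps = 20))
#' world$features
build_world <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  # fixed offsets fan the master seed out to stages so each is reproducible
  # in isolation
  seed_of <- function(k) derive_seed(cfg$seed, k)
  cells <- make_regions(cfg$grid_side, cfg$n_regions, seed = seed_of(1L))

  series <- lapply(seq_len(cfg$n_pollutants), function(p) {
    base <- simulate_grf(cells, range = cfg$grf_range, sill = cfg$grf_sill,
                         nugget = cfg$grf_nugget, seed = seed_of(10L + p))
    simulate_exposure_series(base, cfg$n_timesteps, cfg$temporal_sd,
                             seed = seed_of(30L + p))
  })
  names(series) <- paste0("pol", seq_len(cfg$n_pollutants))

  grid <- grid_fields(cells, series)
  exposure <- build_exposure_features(grid)

  n_noise <- cfg$n_features - 2L * cfg$n_pollutants
  noise <- withr::with_seed(seed_of(50L), {
    m <- matrix(rnorm(nrow(exposure) * n_noise), nrow = nrow(exposure))
    colnames(m) <- paste0("socio_", seq_len(n_noise))
    m
  })
  features <- dplyr::bind_cols(exposure, tibble::as_tibble(noise))

  regions <- cells |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")

  population <- simulate_population(regions$region_id, cfg$n_age_classes,
                                    cfg$pop_mean, seed = seed_of(60L))
  mortality <- simulate_mortality(population, features, cfg$betas,
                                  cfg$active_features, cfg$national_rates,
                                  seed = seed_of(70L))

  feat_cols <- setdiff(names(features), "region_id")
  true_betas <- setNames(rep(0, length(feat_cols)), feat_cols)
  if (length(cfg$active_features) > 0) {
    true_betas[cfg$active_features] <- cfg$betas
  }

  structure(
    list(
      config = cfg, cells = cells, series = series, regions = regions,
      population = population,
      rates = tibble::tibble(age_class = paste0("age_", seq_len(cfg$n_age_classes)),
                             rate = cfg$national_rates),
      mortality = mortality, features = features,
      true_betas = true_betas, true_range = cfg$grf_range
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("<synthetic_world>\n")
  cat("  grid: ", x$config$grid_side, "x", x$config$grid_side,
      " (", nrow(x$cells), " cells), ", nrow(x$regions), " regions\n", sep = "")
  cat("  pollutants: ", length(x$series), ", timesteps: ",
      x$config$n_timesteps, "\n", sep = "")
  cat("  features: ", length(x$true_betas), " (",
      sum(x$true_betas != 0), " active)\n", sep = "")
  invisible(x)
}

#' Simulate a spatially confounded world for leakage experiments
#'
#' Builds a world in which the mortality signal is driven by a latent
#' smooth spatial field that is *not* among the model features, while the
#' features themselves are spatially autocorrelated fields (zonal means of
#' independent Gaussian random fields). Features carry no causal effect,
#' but because features and target share smooth spatial structure, nearby
#' regions have similar feature vectors and similar SMRs: randomly
#' splitting regions across folds then leaks neighbourhood information into
#' validation, while spatially blocked folds do not. This is the test bed
#' for demonstrating spatial cross-validation leakage.
#'
#' @param grid_side Cells per axis.
#' @param n_regions Number of contiguous regions.
#' @param n_features Number of autocorrelated (causally inert) features.
#' @param grf_range Effective range of all fields, grid units.
#' @param beta_latent Log relative risk per standard deviation of the
#'   latent spatial field.
#' @param n_age_classes,national_rates,pop_mean As in [synthetic_config()].
#' @param seed Integer seed.
#'
#' @return A list with `regions`, `features`, `smr` (tibble with
#'   `region_id`, `observed`, `expected`, `smr`), and `latent` (the
#'   region-level confounding field).
#' @export
simulate_confounded_world <- function(grid_side = 20, n_regions = 60,
                                      n_features = 8, grf_range = 10,
                                      beta_latent = 0.3,
                                      n_age_classes = 5,
                                      national_rates = c(5e-4, 1e-3, 4e-3, 1.2e-2, 4e-2),
                                      pop_mean = 1e5,
                                      seed = 1L) {
  seed_of <- function(k) derive_seed(seed, k)
  cells <- make_regions(grid_side, n_regions, seed = seed_of(1L))
  memb <- cells$region_id

  feat_list <- lapply(seq_len(n_features), function(j) {
    f <- simulate_grf(cells, range = grf_range, sill = 1, nugget = 0,
                      seed = seed_of(100L + j))
    zonal_mean(f, memb)$value
  })
  region_ids <- sort(unique(memb))  # zonal_mean() output order
  features <- tibble::as_tibble(setNames(feat_list, paste0("feat_", seq_len(n_features))))
  features <- dplyr::bind_cols(tibble::tibble(region_id = region_ids), features)

  latent_cell <- simulate_grf(cells, range = grf_range, sill = 1, nugget = 0,
                              seed = seed_of(200L))
  latent <- zonal_mean(latent_cell, memb)$value

  regions <- cells |>
    dplyr::group_by(.data$region_id) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  population <- simulate_population(regions$region_id, n_age_classes,
                                    pop_mean, seed = seed_of(60L))
  aug <- dplyr::bind_cols(features, tibble::tibble(.latent = latent))
  mortality <- simulate_mortality(population, aug, betas = beta_latent,
                                  active = ".latent",
                                  national_rates = national_rates,
                                  seed = seed_of(70L))
  smr_tbl <- smr_table(
    observed = tibble::tibble(region_id = mortality$region_id,
                              deaths = mortality$deaths),
    population = population,
    rates = tibble::tibble(age_class = paste0("age_", seq_len(n_age_classes)),
                           rate = national_rates)
  )
  list(regions = regions, features = features, smr = smr_tbl, latent = latent)
}
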