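# End-to-end driver: aggregate -> standardize -> variogram -> blocks ->
# leave-one-block-out CV -> scheme comparison -> explanation -> report,
# writing every stage's artifact plus a manifest with checksums.

`%||%` <- function(a, b) if (is.null(a)) b else a

# master seed -> stage/fold seed, kept inside the 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1000 + k) %% 2147483647)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full SMR modelling pipeline on a synthetic world
#'
#' Executes the complete analysis chain on a [build_world()] result:
#' zonal aggregation of the exposure series into region features, indirect
#' standardization into an SMR table with outlier flagging, empirical
#' semivariogram and range estimation on the SMR surface, hierarchical
#' spatial blocking cut at the range, leave-one-block-out random forest
#' cross-validation, the spatial-vs-random CV leakage comparison,
#' permutation importance, and Shapley attribution of a full-data refit.
#' Every stage's artifact is written under `out_dir` and hash-listed in a
#' manifest; the whole run is deterministic given `seed`.
#'
#' @param world A `synthetic_world` from [build_world()].
#' @param out_dir Output directory; created if absent.
#' @param seed Master seed; defaults to the world's config seed. Fans out
#'   to per-stage seeds by fixed offsets.
#' @param n_bins Semivariogram bins.
#' @param threshold Plateau threshold for [estimate_range()].
#' @param smooth_window Smoothing window for [estimate_range()].
#' @param linkage Clustering linkage for [cluster_regions()].
#' @param cut_override Optional manual dendrogram cut distance; default is
#'   the estimated semivariogram range.
#' @param k_random,cv_repeats Random-CV folds and shuffle repeats for
#'   [compare_cv_schemes()].
#' @param importance_repeats Permutation-importance repeats.
#' @param model_config Forest hyperparameter overrides.
#' @param explain_method `"tree"` or `"exact"` for [shapley_all_regions()].
#'
#' @return Invisibly, a list with every stage's in-memory result
#'   (`features`, `smr`, `variogram`, `blocks`, `cv`, `comparison`,
#'   `importance`, `shapley`, `ranking`, `manifest`).
#' @export
run_pipeline <- function(world, out_dir, seed = NULL,
                         n_bins = 15, threshold = 0.95, smooth_window = 3,
                         linkage = "complete", cut_override = NULL,
                         k_random = 10, cv_repeats = 3,
                         importance_repeats = 10,
                         model_config = list(), explain_method = "tree") {
  stopifnot(inherits(world, "synthetic_world"))
  seed <- as.integer(seed %||% world$config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifact <- function(name) file.path(out_dir, name)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  features <- run_stage("aggregate", {
    grid <- grid_fields(world$cells, world$series)
    exposure <- build_exposure_features(grid)
    socio_cols <- setdiff(names(world$features), names(exposure))
    feats <- dplyr::left_join(exposure,
                              world$features[, c("region_id", socio_cols)],
                              by = "region_id")
    emit(write_feature_table(feats, artifact("features.csv")))
    feats
  })

  smr_tbl <- run_stage("standardize", {
    tbl <- smr_table(
      observed = tibble::tibble(region_id = world$mortality$region_id,
                                deaths = world$mortality$deaths),
      population = world$population,
      rates = world$rates
    )
    emit(write_smr_table(tbl, artifact("smr.csv")))
    tbl
  })

  keep <- smr_tbl$region_id[!smr_tbl$outlier]
  regions_kept <- world$regions[world$regions$region_id %in% keep, ]
  smr_kept <- smr_tbl[smr_tbl$region_id %in% keep, ]
  feats_kept <- features[features$region_id %in% keep, ]

  sv <- run_stage("variogram", {
    dm <- pairwise_distances(regions_kept)
    rownames(dm) <- colnames(dm) <- as.character(regions_kept$region_id)
    sv <- empirical_semivariogram(
      smr_kept$smr[match(regions_kept$region_id, smr_kept$region_id)],
      dm, n_bins = n_bins
    )
    sv <- estimate_range(sv, threshold = threshold,
                         smooth_window = smooth_window)
    readr::write_csv(sv$bins, artifact("variogram_bins.csv"))
    emit(artifact("variogram_bins.csv"))
    jsonlite::write_json(
      list(sill = sv$sill_estimate, range = sv$range_estimate,
           converged = sv$converged, seed = seed),
      artifact("variogram.json"), auto_unbox = TRUE, digits = NA
    )
    emit(artifact("variogram.json"))
    attr(sv, "distmat") <- dm
    sv
  })

  blocks <- run_stage("blocks", {
    cut <- cut_override %||% sv$range_estimate
    b <- cluster_regions(attr(sv, "distmat"), cut_distance = cut,
                         linkage = linkage)
    emit(write_blocks(b, artifact("blocks.csv")))
    b
  })

  cv <- run_stage("fit", {
    cv <- fit_predict_cv(feats_kept, smr_kept, locv_folds(blocks),
                         model_config = model_config, seed = seed)
    readr::write_csv(cv$predictions, artifact("cv_predictions.csv"))
    emit(artifact("cv_predictions.csv"))
    cv
  })

  comparison <- run_stage("compare_cv", {
    compare_cv_schemes(feats_kept, smr_kept, blocks, k_random = k_random,
                       n_repeats = cv_repeats, model_config = model_config,
                       seed = seed)
  })

  run_stage("metrics", {
    jsonlite::write_json(
      list(
        pooled = as.list(cv$pooled),
        per_fold = cv$per_fold,
        comparison = as.list(comparison),
        seed = seed
      ),
      artifact("metrics.json"), auto_unbox = TRUE, digits = NA
    )
    emit(artifact("metrics.json"))
  })

  full_fit <- run_stage("refit", {
    fit_forest_full(feats_kept, smr_kept, model_config = model_config,
                    seed = seed + 500L)
  })

  importance <- run_stage("importance", {
    imp <- permutation_importance(full_fit, feats_kept, smr_kept,
                                  n_repeats = importance_repeats,
                                  seed = seed + 600L)
    readr::write_csv(imp, artifact("importance.csv"))
    emit(artifact("importance.csv"))
    imp
  })

  shap <- run_stage("explain", {
    sh <- shapley_all_regions(full_fit, feats_kept, method = explain_method,
                              seed = seed + 700L)
    readr::write_csv(sh$phi, artifact("shapley_phi.csv"))
    emit(artifact("shapley_phi.csv"))
    rk <- global_rank(sh)
    readr::write_csv(rk, artifact("shapley_rank.csv"))
    emit(artifact("shapley_rank.csv"))
    jsonlite::write_json(
      list(base_value = sh$base_value, method = sh$method, seed = seed),
      artifact("shapley.json"), auto_unbox = TRUE, digits = NA
    )
    emit(artifact("shapley.json"))
    sh
  })

  manifest <- run_stage("report", {
    man <- list(
      seed = seed,
      n_regions = nrow(smr_tbl),
      n_outliers = sum(smr_tbl$outlier),
      n_blocks = blocks$n_blocks,
      artifacts = lapply(setNames(written, basename(written)), function(p) {
        list(md5 = unname(tools::md5sum(p)), bytes = file.size(p))
      })
    )
    jsonlite::write_json(man, artifact("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    man
  })

  invisible(list(
    features = features, smr = smr_tbl, variogram = sv, blocks = blocks,
    cv = cv, comparison = comparison, importance = importance,
    shapley = shap, ranking = global_rank(shap), manifest = manifest,
    out_dir = out_dir
  ))
}
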