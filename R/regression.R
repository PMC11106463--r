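# Random forest regression of SMR on region features under
# leave-one-block-out cross-validation, the r2 / MAE metrics, permutation
# feature importance, and the spatial-vs-random CV comparison that
# quantifies spatial data leakage.

#' Coefficient of determination
#'
#' `r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`. May be negative
#' when predictions are worse than the mean of the observed values.
#'
#' @param y Observed values; must not be constant, length >= 2.
#' @param yhat Predicted values, same length.
#'
#' @return A single dimensionless number, at most 1.
#' @export
#' @examples
#' r2(c(1, 2, 3), c(1, 2, 2))  # 0.5
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("r2 undefined for constant observed values", call. = FALSE)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

#' Mean absolute error
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#'
#' @return Mean of `|y - yhat|`, in the units of `y`.
#' @export
#' @examples
#' mae(c(1, 2, 3), c(2, 2, 2))  # 2/3
mae <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 1)
  mean(abs(y - yhat))
}

#' Leave-one-block-out cross-validation folds
#'
#' One fold per spatial block: the block is the validation set, all other
#' regions form the training set. Folds partition the regions.
#'
#' @param assignment A [cluster_regions()] result with >= 2 blocks.
#'
#' @return List of folds, each a list with `train` and `validation`
#'   character vectors of region ids.
#' @export
locv_folds <- function(assignment) {
  stopifnot(inherits(assignment, "block_assignment"), assignment$n_blocks >= 2)
  labs <- assignment$labels
  lapply(sort(unique(labs$block)), function(b) {
    list(
      train = labs$region_id[labs$block != b],
      validation = labs$region_id[labs$block == b]
    )
  })
}

# Random k-fold partition of region ids (region-level shuffling).
random_folds <- function(region_ids, k, seed) {
  n <- length(region_ids)
  stopifnot(k >= 2, k <= n)
  idx <- withr::with_seed(seed, sample.int(n))
  fold_of <- rep(seq_len(k), length.out = n)[order(idx)]
  lapply(seq_len(k), function(f) {
    list(
      train = region_ids[fold_of != f],
      validation = region_ids[fold_of == f]
    )
  })
}

# Internal: random forest fit with library defaults unless overridden.
fit_forest <- function(x, y, model_config = list(), seed = 1L) {
  args <- c(list(x = as.data.frame(x), y = y), model_config)
  withr::with_seed(seed, do.call(randomForest::randomForest, args))
}

#' Fit and predict under a cross-validation scheme
#'
#' Trains one random forest per fold on the training regions only and
#' predicts its held-out validation regions, so every region is predicted
#' exactly once out-of-fold. The forest uses the library's default
#' hyperparameters unless overridden through `model_config`. Per-fold
#' seeds derive from the master seed by a fixed counter so results are
#' reproducible fold by fold.
#'
#' @param features Tibble: `region_id` plus numeric feature columns, no
#'   missing values. Outlier regions should be excluded upstream.
#' @param target Tibble with `region_id` and `smr` (or a named numeric
#'   vector keyed by region id).
#' @param folds List of folds as produced by [locv_folds()].
#' @param model_config Named list of `randomForest` arguments (e.g.
#'   `ntree`, `mtry`, `nodesize`).
#' @param seed Integer master seed.
#'
#' @return An object of class `smr_cv`: list with `predictions` (tibble:
#'   `region_id`, `fold`, `y_true`, `y_pred`), `pooled` (tibble with
#'   pooled `r2` and `mae` over the concatenated out-of-fold predictions),
#'   `per_fold` (tibble of per-fold metrics; per-fold r2 is `NA` for folds
#'   too small or constant), `models` (one forest per fold) and `seed`.
#' @export
fit_predict_cv <- function(features, target, folds, model_config = list(),
                           seed = 1L) {
  feat_cols <- setdiff(names(features), "region_id")
  y_all <- target_vector(target)
  if (!setequal(features$region_id, names(y_all))) {
    stop("features and target cover different region sets", call. = FALSE)
  }
  x <- as.data.frame(features[, feat_cols, drop = FALSE])
  rownames(x) <- as.character(features$region_id)
  if (any(!is.finite(as.matrix(x)))) {
    stop("missing or non-finite feature values", call. = FALSE)
  }

  fold_fits <- purrr::imap(folds, function(fold, k) {
    tr <- as.character(fold$train); va <- as.character(fold$validation)
    fit <- fit_forest(x[tr, , drop = FALSE], y_all[tr], model_config,
                      seed = derive_seed(seed, k))
    list(
      model = fit,
      predictions = tibble::tibble(
        region_id = va,
        fold = k,
        y_true = unname(y_all[va]),
        y_pred = unname(predict(fit, x[va, , drop = FALSE]))
      )
    )
  })
  models <- purrr::map(fold_fits, "model")
  predictions <- dplyr::bind_rows(purrr::map(fold_fits, "predictions"))

  if (anyDuplicated(predictions$region_id) > 0) {
    stop("folds overlap: some region predicted more than once", call. = FALSE)
  }
  per_fold <- predictions |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      r2 = if (dplyr::n() >= 2 && var(.data$y_true) > 0)
        r2(.data$y_true, .data$y_pred) else NA_real_,
      mae = mae(.data$y_true, .data$y_pred),
      .groups = "drop"
    )
  pooled <- tibble::tibble(
    r2 = if (var(predictions$y_true) > 0)
      r2(predictions$y_true, predictions$y_pred) else NA_real_,
    mae = mae(predictions$y_true, predictions$y_pred),
    n = nrow(predictions),
    n_folds = length(folds)
  )
  structure(
    list(predictions = predictions, pooled = pooled, per_fold = per_fold,
         models = models, feat_cols = feat_cols, seed = seed),
    class = "smr_cv"
  )
}

# Accept either a tibble (region_id, smr) or a named vector.
target_vector <- function(target) {
  if (is.data.frame(target)) {
    stopifnot(all(c("region_id", "smr") %in% names(target)))
    setNames(target$smr, as.character(target$region_id))
  } else {
    stopifnot(!is.null(names(target)))
    target
  }
}

#' @export
print.smr_cv <- function(x, ...) {
  cat("<smr_cv> ", x$pooled$n_folds, " folds, ", x$pooled$n, " regions\n",
      "  pooled r2 = ", signif(x$pooled$r2, 4),
      ", pooled MAE = ", signif(x$pooled$mae, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname fit_predict_cv
#' @param x An `smr_cv` object.
#' @param ... Unused.
#' @export
tidy.smr_cv <- function(x, ...) x$predictions

#' @rdname fit_predict_cv
#' @export
glance.smr_cv <- function(x, ...) x$pooled

#' @rdname fit_predict_cv
#' @param object An `smr_cv` object.
#' @export
autoplot.smr_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$y_true, y = .data$y_pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "darkgreen") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue", linewidth = 0.5) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "observed SMR", y = "predicted SMR") +
    ggplot2::theme_minimal()
}

#' Permutation feature importance
#'
#' Importance of a feature is the mean degradation of the model's score on
#' evaluation data when that feature's column is randomly permuted,
#' averaged over repeats. A feature the model never uses degrades nothing
#' and scores exactly zero.
#'
#' @param model A fitted regressor accepted by `predict()` (e.g. a random
#'   forest from [fit_predict_cv()] or [fit_forest_full()]).
#' @param features Tibble: `region_id` + feature columns (evaluation data,
#'   ideally held out from training).
#' @param target Target tibble or named vector, as in [fit_predict_cv()].
#' @param metric `"r2"` (default) or `"mae"`; degradation is
#'   `score_original - score_permuted` for r2 and `mae_permuted -
#'   mae_original` for MAE, so larger is always more important.
#' @param n_repeats Permutations per feature; default 10.
#' @param seed Integer seed.
#'
#' @return Tibble: `feature`, `importance` (mean degradation),
#'   `importance_sd`, `rank` (1 = most important).
#' @export
permutation_importance <- function(model, features, target, metric = c("r2", "mae"),
                                   n_repeats = 10, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(n_repeats >= 1)
  feat_cols <- setdiff(names(features), "region_id")
  x <- as.data.frame(features[, feat_cols, drop = FALSE])
  y <- unname(target_vector(target)[as.character(features$region_id)])
  score <- function(yhat) if (metric == "r2") r2(y, yhat) else -mae(y, yhat)
  base <- score(predict(model, x))
  res <- withr::with_seed(seed, {
    purrr::map_dfr(feat_cols, function(f) {
      deg <- vapply(seq_len(n_repeats), function(r) {
        xp <- x
        xp[[f]] <- x[[f]][sample.int(nrow(x))]
        base - score(predict(model, xp))
      }, numeric(1))
      tibble::tibble(feature = f, importance = mean(deg),
                     importance_sd = sd(deg))
    })
  })
  res$rank <- rank(-res$importance, ties.method = "first")
  dplyr::arrange(res, .data$rank)
}

#' Fit a random forest on all regions
#'
#' Full-data refit used after cross-validated assessment, e.g. as the
#' model to explain with Shapley attributions.
#'
#' @inheritParams fit_predict_cv
#' @return A `randomForest` fit.
#' @export
fit_forest_full <- function(features, target, model_config = list(), seed = 1L) {
  feat_cols <- setdiff(names(features), "region_id")
  y <- unname(target_vector(target)[as.character(features$region_id)])
  fit_forest(features[, feat_cols, drop = FALSE], y, model_config, seed = seed)
}

#' Compare spatial and random cross-validation schemes
#'
#' Runs leave-one-block-out CV and region-shuffled k-fold CV on identical
#' data and reports the pooled r2 of each together with their difference.
#' Under spatial autocorrelation, random folds place near neighbours of
#' each validation region in the training set, inflating apparent skill;
#' the gap `r2_random - r2_spatial` measures that leakage.
#'
#' @inheritParams fit_predict_cv
#' @param assignment A [cluster_regions()] block assignment.
#' @param k_random Number of random folds; default 10.
#' @param n_repeats Random-shuffle repeats to average over; default 5.
#'
#' @return Tibble with one row: `r2_spatial`, `r2_random` (mean over
#'   repeats), `gap` (`r2_random - r2_spatial`), `mae_spatial`,
#'   `mae_random`, `n_blocks`, `k_random`, `n_repeats`.
#' @export
compare_cv_schemes <- function(features, target, assignment, k_random = 10,
                               n_repeats = 5, model_config = list(), seed = 1L) {
  cv_sp <- fit_predict_cv(features, target, locv_folds(assignment),
                          model_config, seed = seed)
  reps <- purrr::map_dfr(seq_len(n_repeats), function(r) {
    folds <- random_folds(as.character(features$region_id), k_random,
                          seed = derive_seed(seed, 500L + r))
    cv <- fit_predict_cv(features, target, folds, model_config,
                         seed = derive_seed(seed, 700L + r))
    tibble::tibble(r2 = cv$pooled$r2, mae = cv$pooled$mae)
  })
  tibble::tibble(
    r2_spatial = cv_sp$pooled$r2,
    r2_random = mean(reps$r2),
    gap = mean(reps$r2) - cv_sp$pooled$r2,
    mae_spatial = cv_sp$pooled$mae,
    mae_random = mean(reps$mae),
    n_blocks = assignment$n_blocks,
    k_random = k_random,
    n_repeats = n_repeats
  )
}
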