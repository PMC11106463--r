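# Shapley feature attributions for model predictions:
# phi_j(x) = sum over F subset of S\{j} of
#            |F|! (|S|-|F|-1)! / |S|! * [f_x(F u {j}) - f_x(F)]
# with the interventional value function f_x(F) = mean over background rows
# b of the model prediction on the composite row taking the instance's
# values on F and b's elsewhere. Two routes: direct subset enumeration for
# any model (small feature counts), and an exact tree-traversal algorithm
# for random forests that gives identical values in polynomial time.

#' Exact Shapley attribution by subset enumeration
#'
#' Enumerates all 2^p feature coalitions, evaluates the interventional
#' value function for each (averaging model predictions over the
#' background sample), and combines marginal contributions with the
#' Shapley combinatorial weights. Exponential in the feature count, so
#' capped at 12 features; use [tree_shapley()] beyond that.
#'
#' @param predict_fn Function taking a data frame of rows and returning
#'   numeric predictions (e.g. `function(d) predict(fit, d)`).
#' @param instance A single row to explain: named numeric vector or
#'   one-row data frame.
#' @param background Data frame (or matrix) of background rows with the
#'   same feature columns; non-empty.
#'
#' @return List with `phi` (named numeric vector, one entry per feature)
#'   and `base_value` (the value function of the empty coalition, i.e. the
#'   mean background prediction). `base_value + sum(phi)` equals the model
#'   prediction at `instance` (efficiency).
#' @export
#' @examples
#' fit <- stats::lm(mpg ~ wt + hp, data = mtcars)
#' ex <- exact_shapley(function(d) predict(fit, d),
#'                     instance = mtcars[1, c("wt", "hp")],
#'                     background = mtcars[, c("wt", "hp")])
#' ex$base_value + sum(ex$phi)  # equals predict(fit, mtcars[1, ])
exact_shapley <- function(predict_fn, instance, background) {
  if (is.data.frame(instance)) {
    stopifnot(nrow(instance) == 1)
    instance <- unlist(instance[1, , drop = TRUE])
  }
  background <- as.data.frame(background)
  stopifnot(nrow(background) >= 1)
  feat <- names(instance)
  stopifnot(!is.null(feat), all(feat %in% names(background)))
  background <- background[, feat, drop = FALSE]
  p <- length(feat)
  if (p > 12) {
    stop("subset enumeration capped at 12 features (got ", p, "); ",
         "use tree_shapley() for larger models", call. = FALSE)
  }
  m <- nrow(background)
  n_masks <- bitwShiftL(1L, p)
  masks <- seq_len(n_masks) - 1L
  member <- vapply(seq_len(p), function(j) {
    bitwAnd(masks, bitwShiftL(1L, j - 1L)) > 0L
  }, logical(n_masks))          # n_masks x p
  # one big prediction call over every (coalition, background row) composite
  big <- background[rep(seq_len(m), times = n_masks), , drop = FALSE]
  for (j in seq_len(p)) {
    rows <- rep(member[, j], each = m)
    big[rows, j] <- instance[[j]]
  }
  preds <- predict_fn(big)
  v <- rowMeans(matrix(preds, nrow = n_masks, byrow = TRUE))

  sizes <- rowSums(member)
  lf <- lfactorial(0:p)
  # weight for |F| given p players: |F|! (p - |F| - 1)! / p!
  wt <- exp(lf[1:p] + lf[p:1] - lf[p + 1])
  phi <- vapply(seq_len(p), function(j) {
    without <- !member[, j]
    f_sizes <- sizes[without]
    with_j <- masks[without] + bitwShiftL(1L, j - 1L)
    sum(wt[f_sizes + 1] * (v[with_j + 1L] - v[without]))
  }, numeric(1))
  list(phi = setNames(phi, feat), base_value = v[1])
}

#' Exact interventional Shapley attributions for a random forest
#'
#' Traverses every tree of the forest once per leaf, background row and
#' instance, exploiting the fact that each leaf is an axis-aligned box so
#' the coalition game decomposes into indicator games with closed-form
#' Shapley values. Produces exactly the values that subset enumeration
#' over the same background would, in polynomial time, with no sampling.
#'
#' @param model A regression `randomForest` fit.
#' @param newdata Data frame of rows to explain (feature columns matching
#'   the training data).
#' @param background Data frame of background rows; defaults to `newdata`.
#'
#' @return List with `phi` (matrix, rows = instances, columns = features)
#'   and `base_value` (mean forest prediction over the background).
#' @export
tree_shapley <- function(model, newdata, background = newdata) {
  stopifnot(inherits(model, "randomForest"), model$type == "regression")
  feat <- rownames(model$importance)
  newdata <- as.data.frame(newdata)[, feat, drop = FALSE]
  background <- as.data.frame(background)[, feat, drop = FALSE]
  # assembled directly from the forest components (equivalent to getTree,
  # which cannot represent single-node trees)
  fo <- model$forest
  trees <- lapply(seq_len(model$ntree), function(k) {
    n <- fo$ndbigtree[k]
    cbind(fo$leftDaughter[seq_len(n), k], fo$rightDaughter[seq_len(n), k],
          fo$bestvar[seq_len(n), k], fo$xbestsplit[seq_len(n), k],
          fo$nodestatus[seq_len(n), k], fo$nodepred[seq_len(n), k])
  })
  phi <- forest_interventional_shap(trees, as.matrix(newdata),
                                    as.matrix(background))
  colnames(phi) <- feat
  list(phi = phi, base_value = mean(predict(model, background)))
}

#' Shapley attributions for every region
#'
#' Explains the model's prediction for each region, producing the
#' per-region, per-feature attribution matrix behind the summary plot and
#' the global importance ranking. The exact tree-traversal route is the
#' default; subset enumeration is available for models with at most 12
#' features and gives identical values.
#'
#' @param model A fitted regression `randomForest`.
#' @param features Tibble: `region_id` + feature columns (the rows to
#'   explain).
#' @param background Background rows for the interventional expectation;
#'   default: the feature table itself (full training background). May be
#'   capped with `background_size`.
#' @param method `"tree"` (default) or `"exact"`.
#' @param background_size Optional cap on background rows (seeded
#'   subsample); `NULL` keeps all.
#' @param seed Seed for the background subsample.
#'
#' @return An object of class `shapley_matrix`: list with `phi` (tibble:
#'   `region_id` + one column per feature), `base_value`, `method`, and
#'   `features` (the explained rows, for plotting).
#' @export
shapley_all_regions <- function(model, features, background = NULL,
                                method = c("tree", "exact"),
                                background_size = NULL, seed = 1L) {
  method <- match.arg(method)
  feat_cols <- setdiff(names(features), "region_id")
  x <- features[, feat_cols, drop = FALSE]
  bg <- if (is.null(background)) x else as.data.frame(background)[, feat_cols, drop = FALSE]
  if (!is.null(background_size) && background_size < nrow(bg)) {
    keep <- withr::with_seed(seed, sample.int(nrow(bg), background_size))
    bg <- bg[keep, , drop = FALSE]
  }
  if (method == "tree") {
    res <- tree_shapley(model, x, bg)
    phi <- res$phi
    base <- res$base_value
  } else {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      exact_shapley(function(d) predict(model, d), as.data.frame(x)[i, , drop = FALSE], bg)
    })
    phi <- do.call(rbind, lapply(rows, function(r) r$phi))
    base <- rows[[1]]$base_value
  }
  structure(
    list(
      phi = dplyr::bind_cols(tibble::tibble(region_id = features$region_id),
                             tibble::as_tibble(phi)),
      base_value = base,
      method = method,
      features = features
    ),
    class = "shapley_matrix"
  )
}

#' Global feature ranking by mean absolute attribution
#'
#' Orders features by the mean of |phi| over all explained regions (the
#' ordering used in attribution summary plots), breaking ties
#' lexicographically by feature name.
#'
#' @param shap A [shapley_all_regions()] result.
#'
#' @return Tibble: `feature`, `mean_abs_phi`, `rank` (1 = most important).
#' @export
global_rank <- function(shap) {
  stopifnot(inherits(shap, "shapley_matrix"))
  phi <- shap$phi[, setdiff(names(shap$phi), "region_id"), drop = FALSE]
  out <- tibble::tibble(
    feature = names(phi),
    mean_abs_phi = vapply(phi, function(col) mean(abs(col)), numeric(1))
  )
  out <- out[order(-out$mean_abs_phi, out$feature), ]
  out$rank <- seq_len(nrow(out))
  out
}

#' @export
print.shapley_matrix <- function(x, ...) {
  cat("<shapley_matrix> ", nrow(x$phi), " regions x ",
      ncol(x$phi) - 1, " features (", x$method, " method)\n",
      "  base value: ", signif(x$base_value, 5), "\n", sep = "")
  invisible(x)
}

#' @rdname shapley_all_regions
#' @param x A `shapley_matrix` object.
#' @param ... Unused.
#' @export
tidy.shapley_matrix <- function(x, ...) {
  phi_long <- tidyr::pivot_longer(x$phi, -"region_id",
                                  names_to = "feature", values_to = "phi")
  feat_long <- tidyr::pivot_longer(x$features, -"region_id",
                                   names_to = "feature", values_to = "feature_value")
  dplyr::left_join(phi_long, feat_long, by = c("region_id", "feature"))
}

#' @rdname shapley_all_regions
#' @param object A `shapley_matrix` object.
#' @export
autoplot.shapley_matrix <- function(object, ...) {
  df <- tidy(object)
  rk <- global_rank(object)
  df$feature <- factor(df$feature, levels = rev(rk$feature))
  df <- df |>
    dplyr::group_by(.data$feature) |>
    dplyr::mutate(scaled_value = if (diff(range(.data$feature_value)) > 0)
      (.data$feature_value - min(.data$feature_value)) /
        diff(range(.data$feature_value)) else 0.5) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi, y = .data$feature,
                                   colour = .data$scaled_value)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.7, size = 1.5) +
    ggplot2::scale_colour_gradient(low = "#3b7fb6", high = "#d1495b",
                                   breaks = c(0, 1),
                                   labels = c("low", "high")) +
    ggplot2::labs(x = "Shapley value (effect on predicted SMR)", y = NULL,
                  colour = "feature\nvalue") +
    ggplot2::theme_minimal()
}
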