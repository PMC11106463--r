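# Shapley attributions: the subset-enumeration route, the interventional
# tree-traversal route, their equivalence, and the axioms (efficiency,
# symmetry, dummy).

make_forest <- function(n = 60, p = 6, seed = 1, ntree = 80,
                        gen = function(X) 2 * X[[1]] - X[[2]] + rnorm(nrow(X), 0, 0.2)) {
  withr::with_seed(seed, {
    X <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(X) <- paste0("f", seq_len(p))
    y <- gen(X)
    list(X = X, y = y,
         fit = randomForest::randomForest(X, y, ntree = ntree))
  })
}

test_that("exact enumeration satisfies the Shapley axioms", {
  # constant model: all attribution goes to the base value
  const_fn <- function(d) rep(5, nrow(d))
  inst <- c(a = 1, b = 2, c = 3)
  bg <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  ex <- exact_shapley(const_fn, inst, bg)
  expect_equal(unname(ex$phi), c(0, 0, 0))
  expect_equal(ex$base_value, 5)

  # additive model with an all-zeros background: phi_j = x_j exactly
  add_fn <- function(d) rowSums(d)
  bg0 <- as.data.frame(matrix(0, 4, 3)); names(bg0) <- names(inst)
  exa <- exact_shapley(add_fn, inst, bg0)
  expect_equal(exa$phi, inst, tolerance = 1e-12)
  expect_equal(exa$base_value, 0)

  # symmetry: interchangeable features with equal instance values share
  # credit (the background must treat them interchangeably too)
  sym_fn <- function(d) d$a * d$b + d$a + d$b
  inst_s <- c(a = 1.3, b = 1.3)
  v <- rnorm(15)
  bg_s <- data.frame(a = v, b = v)
  exs <- exact_shapley(sym_fn, inst_s, bg_s)
  expect_equal(exs$phi[["a"]], exs$phi[["b"]], tolerance = 1e-12)

  bg13 <- as.data.frame(matrix(0, 2, 13))
  names(bg13) <- paste0("x", 1:13)
  expect_error(
    exact_shapley(add_fn, setNames(rnorm(13), paste0("x", 1:13)), bg13),
    "capped at 12"
  )
})

test_that("exact and tree routes agree to numerical precision", {
  forest <- make_forest(n = 50, p = 6, seed = 2)
  tr <- tree_shapley(forest$fit, forest$X[1:8, ], background = forest$X)
  for (i in 1:8) {
    ex <- exact_shapley(function(d) predict(forest$fit, d),
                        forest$X[i, ], forest$X)
    expect_equal(unname(tr$phi[i, ]), unname(ex$phi), tolerance = 1e-9)
    expect_equal(tr$base_value, ex$base_value, tolerance = 1e-9)
  }
})

test_that("both routes satisfy efficiency on every instance", {
  forest <- make_forest(n = 60, p = 5, seed = 3)
  preds <- predict(forest$fit, forest$X)
  tr <- tree_shapley(forest$fit, forest$X, background = forest$X)
  expect_lt(max(abs(tr$base_value + rowSums(tr$phi) - preds)), 1e-6)
  for (i in c(1, 25, 60)) {
    ex <- exact_shapley(function(d) predict(forest$fit, d),
                        forest$X[i, ], forest$X)
    expect_lt(abs(ex$base_value + sum(ex$phi) - preds[i]),
              1e-6 * max(1, abs(preds[i])))
  }
})

test_that("a feature constant in training gets exactly zero attribution", {
  withr::with_seed(4, {
    X <- data.frame(f1 = rnorm(50), f2 = rnorm(50), dead = rep(2, 50))
    y <- X$f1 + rnorm(50, 0, 0.1)
    fit <- randomForest::randomForest(X, y, ntree = 60)
  })
  tr <- tree_shapley(fit, X[1:5, ], background = X)
  expect_equal(unname(tr$phi[, "dead"]), rep(0, 5))
  ex <- exact_shapley(function(d) predict(fit, d), X[1, ], X)
  expect_equal(ex$phi[["dead"]], 0)
})

test_that("shapley_all_regions keeps region bookkeeping and invariances", {
  forest <- make_forest(n = 40, p = 4, seed = 6)
  feats <- dplyr::bind_cols(tibble::tibble(region_id = paste0("r", 1:40)),
                            forest$X)
  sh <- shapley_all_regions(forest$fit, feats)
  expect_equal(dim(sh$phi), c(40L, 5L))
  expect_equal(sh$phi$region_id, feats$region_id)

  # exact route agrees with the tree route through the same interface
  sh_ex <- shapley_all_regions(forest$fit, feats[1:3, ], background = forest$X,
                               method = "exact")
  expect_equal(as.matrix(sh_ex$phi[, -1]), as.matrix(sh$phi[1:3, -1]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # permuting feature columns permutes phi columns identically
  perm_feats <- feats[, c("region_id", "f3", "f1", "f4", "f2")]
  sh_p <- shapley_all_regions(forest$fit, perm_feats)
  expect_equal(sh_p$phi[, names(sh$phi)], sh$phi, tolerance = 1e-12)

  expect_s3_class(tidy(sh), "tbl_df")
  expect_s3_class(autoplot(sh), "ggplot")
})

test_that("global_rank orders by mean absolute attribution", {
  forest <- make_forest(n = 50, p = 4, seed = 7)
  feats <- dplyr::bind_cols(tibble::tibble(region_id = 1:50), forest$X)
  sh <- shapley_all_regions(forest$fit, feats)
  rk <- global_rank(sh)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$mean_abs_phi) <= 0))
  expect_equal(rk$feature[1], "f1")  # the dominant planted effect

  # scaling all phi leaves the ranking unchanged
  sh2 <- sh
  sh2$phi[, -1] <- sh2$phi[, -1] * 3.7
  expect_equal(global_rank(sh2)$feature, rk$feature)

  # an all-zero feature ranks last
  sh3 <- sh
  sh3$phi$f2 <- 0
  expect_equal(global_rank(sh3)$feature[4], "f2")
})
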