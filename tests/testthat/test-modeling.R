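# Regression families, evaluation metrics, permutation importance, the grid.

test_that("correlation R-squared behaves as a squared correlation", {
  y <- rnorm(50, 20, 5)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(2 * y + 5, y), 1)     # shift/scale invariant
  expect_equal(r_squared(y, 2 * y + 5), r_squared(2 * y + 5, y))  # symmetric

  # orthogonalised predictor: exactly zero correlation
  set.seed(51)
  x <- rnorm(50)
  x_perp <- residuals(lm(x ~ y))
  expect_equal(r_squared(x_perp, y), 0, tolerance = 1e-12)

  expect_error(r_squared(rep(1, 10), y[1:10]), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("RMSE detects translation that correlation R-squared ignores", {
  y <- rnorm(30, 20, 5)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(y + 2, y), 2)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(25 / 2))
  expect_equal(r_squared(y + 2, y), 1)
  expect_lt(r_squared_ss(y + 2, y), 1)
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("every family fits, predicts deterministically, and is validated", {
  tab <- generate_feature_table(table_config(n_samples = 120, seed = 52))
  X <- tab[, setdiff(names(tab), "label")]
  for (f in model_families()) {
    fit1 <- fit_model(X, tab$label, f, seed = 9)
    fit2 <- fit_model(X, tab$label, f, seed = 9)
    expect_identical(predict(fit1, X), predict(fit2, X))
    expect_gt(r_squared(predict(fit1, X), tab$label), 0.5)
    imp <- feature_importance(fit1)
    expect_named(imp, colnames(X), ignore.order = TRUE)
    expect_true(all(imp >= 0))
  }
  expect_error(fit_model(X, tab$label, "boosted_llama"),
               "decision_tree.*linear")
  expect_error(fit_model(X[1, ], tab$label[1], "linear"), "2 samples")
})

test_that("a noiseless linear law is fit exactly by the linear family", {
  tab <- generate_feature_table(table_config(n_samples = 60, noise_sd = 0,
                                             seed = 53))
  X <- tab[, setdiff(names(tab), "label")]
  fit <- fit_model(X, tab$label, "linear")
  expect_equal(r_squared(predict(fit, X), tab$label), 1, tolerance = 1e-9)
})

test_that("trees out-fit the linear family on a nonlinear response", {
  set.seed(54)
  X <- tibble::tibble(x1 = runif(150, -2, 2), x2 = runif(150, -2, 2))
  y <- sin(2 * X$x1) + abs(X$x2)   # strongly nonlinear, noiseless
  tree <- fit_model(X, y, "extra_trees", seed = 1)
  lin <- fit_model(X, y, "linear", seed = 1)
  expect_lt(rmse(predict(tree, X), y), rmse(predict(lin, X), y))
})

test_that("permutation importance isolates what the model uses", {
  tab <- generate_feature_table(table_config(
    n_samples = 500, n_informative = 1, n_redundant = 0, n_noise = 3,
    noise_sd = 0, effect_sizes = 2, seed = 55))
  X <- tab[, setdiff(names(tab), "label")]
  fit <- fit_model(X, tab$label, "decision_tree", seed = 1)
  pfi <- permutation_importance(fit, X, tab$label, K = 10, seed = 2)

  imp <- tibble::deframe(pfi$importance)
  # the sole informative feature dominates
  expect_gt(imp["inf1"], 0.5)
  # unused columns cannot move the score
  expect_true(all(abs(imp[c("noise1", "noise2", "noise3")]) < 0.01))

  # exact reproducibility of the shuffles
  pfi2 <- permutation_importance(fit, X, tab$label, K = 10, seed = 2)
  expect_identical(pfi$rep_scores, pfi2$rep_scores)
  expect_error(permutation_importance(fit, X, tab$label, K = 0), "K")

  expect_s3_class(autoplot(pfi), "ggplot")
})

test_that("duplicated informative columns split permutation credit", {
  # a model that can spread its reliance across interchangeable copies (a
  # forest picks either copy at random per split) gives each copy less
  # permutation credit than the single original receives
  set.seed(56)
  x <- rnorm(400)
  y <- 2 * x
  single <- tibble::tibble(a = x)
  dup <- tibble::tibble(a = x, b = x)
  pfi_single <- permutation_importance(
    fit_model(single, y, "random_forest", seed = 1), single, y, K = 10, seed = 3)
  pfi_dup <- permutation_importance(
    fit_model(dup, y, "random_forest", seed = 1), dup, y, K = 10, seed = 3)
  imp_s <- tibble::deframe(pfi_single$importance)
  imp_d <- tibble::deframe(pfi_dup$importance)
  expect_lt(imp_d["a"], imp_s["a"])
  expect_lt(imp_d["b"], imp_s["a"])
})

test_that("the evaluation grid covers every space-family pair", {
  fx <- campaign_fixture()
  tab <- fx$table
  spaces <- list(vegetation_indices = vegetation_index_names(),
                 color_features = color_feature_names(),
                 all_features = feature_names())
  families <- c("decision_tree", "linear", "extra_trees")
  grid <- run_grid(tab[, feature_names()], tab$MMD, spaces, families,
                   protocol = grid_protocol(k_folds = 3, repeats = 1),
                   seed = 5)
  expect_equal(nrow(grid), length(spaces) * length(families))
  expect_true(all(c("r2_cv", "rmse_cv", "r2_holdout", "rmse_holdout",
                    "r2_train", "rmse_train") %in% names(grid)))
  expect_true(all(grid$r2_cv >= 0 & grid$r2_cv <= 1))
  expect_true(all(grid$rmse_cv >= 0))

  # on the training split, a tree ensemble with all features never scores
  # below its restriction to a subset space
  et <- grid[grid$family == "extra_trees", ]
  expect_gte(et$r2_train[et$feature_space == "all_features"],
             max(et$r2_train[et$feature_space != "all_features"]) - 1e-6)

  expect_error(
    run_grid(tab[, feature_names()], tab$MMD, list(bad = c("NGRDI", "nope")),
             families), "nope")
  expect_s3_class(autoplot(grid), "ggplot")
})
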