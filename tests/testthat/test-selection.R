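# Pearson pruning and recursive feature elimination.

test_that("the correlation matrix is a proper Pearson matrix", {
  tab <- generate_feature_table(table_config(n_samples = 100, seed = 31))
  X <- tab[, setdiff(names(tab), "label")]
  r <- pearson_matrix(X)
  expect_equal(diag(r), rep(1, ncol(X)), ignore_attr = TRUE)
  expect_equal(r, t(r))

  X$neg <- -X$inf1
  expect_equal(pearson_matrix(X)["inf1", "neg"], -1)

  X$const <- 1
  expect_error(pearson_matrix(X), "const")
})

test_that("pruning removes exactly the redundant members of each group", {
  tab <- generate_feature_table(table_config(n_samples = 300, seed = 32))
  X <- tab[, setdiff(names(tab), "label")]

  # an exact duplicate: precisely one of the pair survives
  X2 <- X
  X2$dup <- X2$noise1
  rep2 <- prune_correlated(X2, tab$label, threshold = 0.9)
  expect_length(intersect(c("noise1", "dup"), rep2$removed), 1)

  # unattainable threshold: nothing is redundant
  rep3 <- prune_correlated(X, tab$label, threshold = 1.01)
  expect_length(rep3$removed, 0)

  # report invariants: kept/removed partition the features; every removed
  # feature has a kept partner above the threshold
  rep1 <- prune_correlated(X, tab$label, threshold = 0.9)
  expect_setequal(c(rep1$kept, rep1$removed), colnames(X))
  for (f in rep1$removed) {
    partners <- abs(rep1$matrix[f, rep1$kept])
    expect_gte(max(partners), 0.9)
  }
  # no two kept features from the same correlated group
  for (i in rep1$kept) for (j in rep1$kept) {
    if (i != j) expect_lte(abs(rep1$matrix[i, j]), 0.9 + 1e-12)
  }
})

test_that("RFE keeps what drives the label and follows a nested path", {
  tab <- generate_feature_table(table_config(
    n_samples = 200, n_informative = 1, n_redundant = 0, n_noise = 3,
    noise_sd = 0, effect_sizes = 2, seed = 33))
  X <- tab[, setdiff(names(tab), "label")]

  expect_equal(rfe(X, tab$label, "linear", target_n = ncol(X)), colnames(X))
  expect_equal(rfe(X, tab$label, "linear", target_n = 1), "inf1")
  expect_error(rfe(X, tab$label, "linear", target_n = 0), "target_n")
  expect_error(rfe(X, tab$label, "linear", target_n = 10), "target_n")

  # nested elimination: the k-subset sits inside the (k+1)-subset
  for (k in 1:3) {
    expect_true(all(rfe(X, tab$label, "linear", k, seed = 2) %in%
                      rfe(X, tab$label, "linear", k + 1, seed = 2)))
  }

  # determinism
  expect_identical(rfe(X, tab$label, "decision_tree", 2, seed = 4),
                   rfe(X, tab$label, "decision_tree", 2, seed = 4))
})

test_that("RFECV produces a full curve and a parsimonious optimum", {
  tab <- generate_feature_table(table_config(
    n_samples = 150, n_informative = 2, n_redundant = 0, n_noise = 4,
    noise_sd = 0.2, effect_sizes = c(3, 2), seed = 34))
  X <- tab[, setdiff(names(tab), "label")]
  sel <- rfecv(X, tab$label, "linear", k_folds = 5, seed = 1)

  expect_equal(sel$cv_curve$n_features, seq_len(ncol(X)))
  expect_true(all(is.finite(sel$cv_curve$mean_score)))
  expect_length(sel$optimal_subset, sel$optimal_n)
  expect_true(all(sel$optimal_subset %in% colnames(X)))

  # the optimum is the smallest n within tolerance of the curve maximum
  best <- max(sel$cv_curve$mean_score)
  expect_gte(sel$cv_curve$mean_score[sel$optimal_n], best - 1e-9)
  if (sel$optimal_n > 1) {
    expect_true(all(sel$cv_curve$mean_score[seq_len(sel$optimal_n - 1)] <
                      best - 1e-9))
  }

  # past the plateau, more features do not raise the achievable score
  plateau <- sel$cv_curve$mean_score[sel$optimal_n]
  expect_lte(max(sel$cv_curve$mean_score) - plateau, 1e-9)

  expect_error(rfecv(X[1:3, ], tab$label[1:3], "linear", k_folds = 5),
               "fewer rows")
})

test_that("RFECV finds no signal in pure noise", {
  for (s in 1:5) {
    tab <- generate_feature_table(table_config(
      n_samples = 150, n_informative = 1, n_redundant = 0, n_noise = 6,
      effect_sizes = 0, noise_sd = 1, seed = 40 + s))
    X <- tab[, setdiff(names(tab), "label")]
    sel <- rfecv(X, tab$label, "decision_tree", k_folds = 5, seed = s)
    expect_true(all(sel$cv_curve$mean_score <= 0.2))
  }
})

test_that("selection results expose tidy, glance and autoplot views", {
  tab <- generate_feature_table(table_config(n_samples = 120, seed = 35))
  X <- tab[, setdiff(names(tab), "label")]
  sel <- rfecv(X, tab$label, "decision_tree", seed = 3)
  td <- tidy(sel)
  expect_true(all(c("n_features", "mean_score", "optimal") %in% names(td)))
  expect_equal(sum(td$optimal), 1)
  gl <- glance(sel)
  expect_equal(gl$optimal_n, sel$optimal_n)
  expect_s3_class(autoplot(sel), "ggplot")
})
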