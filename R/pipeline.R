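#' Run the full maturity-prediction pipeline on a simulated campaign
#'
#' The end-to-end chain: simulate the campaign, segment every image
#' (ExG + K-means + morphology), extract the 22 features per plot-date,
#' compute corrected maturity labels from calendar dates and the brown-pixel
#' fraction, prune correlated features, select a subset by RFECV for the
#' chosen family, then fit on a random 80% of samples and evaluate on the
#' held-out 20%.
#'
#' @param config A [scene_config()]; its `seed` drives the simulation.
#' @param family Regression family for selection and the final fit.
#' @param harvest_date Harvest date anchoring the calendar labels.
#' @param prune_threshold Absolute-correlation threshold for pruning.
#' @param k_folds RFECV folds.
#' @param holdout_frac Held-out fraction for the final evaluation.
#' @param seed Master seed for segmentation, folds and the split (independent
#'   of the scene seed so data and analysis randomness are separable).
#' @param params Texture extraction parameters, see [texture_params()].
#'
#' @return A `maturity_pipeline` list: the labelled feature `table`, the
#'   `pruning` report, the `selection` result, the fitted `model`, and
#'   `metrics` (held-out correlation R², residual R² and RMSE, plus training
#'   RMSE and sizes).
#' @examples
#' \donttest{
#' cfg <- scene_config(image_size = c(64, 64), n_plots = 6,
#'                     capture_offsets = c(30, 17, 3), seed = 11)
#' res <- run_maturity_pipeline(cfg, family = "decision_tree", seed = 1)
#' res$metrics$r2_holdout
#' }
#' @export
run_maturity_pipeline <- function(config,
                                  family = "gradient_boosting",
                                  harvest_date = as.Date("2021-10-15"),
                                  prune_threshold = 0.9,
                                  k_folds = 5L,
                                  holdout_frac = 0.2,
                                  seed = 0L,
                                  params = texture_params()) {
  series <- generate_time_series(config, harvest_date)
  table <- extract_feature_table(series, params = params,
                                 seed = derive_seed(seed, 1L))
  table <- label_table(table, series, harvest_date)

  X_all <- table[, feature_names()]
  y <- table$MMD
  pruning <- prune_correlated(X_all, y, threshold = prune_threshold)
  X <- X_all[, pruning$kept, drop = FALSE]

  selection <- rfecv(X, y, family, k_folds = k_folds,
                     seed = derive_seed(seed, 2L))
  X_sel <- X[, selection$optimal_subset, drop = FALSE]

  n <- nrow(X_sel)
  test <- with_seed(derive_seed(seed, 3L),
                    sample.int(n, max(1L, round(holdout_frac * n))))
  tr <- setdiff(seq_len(n), test)
  model <- fit_model(X_sel[tr, , drop = FALSE], y[tr], family,
                     seed = derive_seed(seed, 4L))
  pred_te <- predict(model, X_sel[test, , drop = FALSE])
  pred_tr <- predict(model, X_sel[tr, , drop = FALSE])

  structure(
    list(table = table, pruning = pruning, selection = selection,
         model = model, family = family,
         holdout_index = test,
         metrics = list(
           r2_holdout = r_squared(pred_te, y[test]),
           r2_ss_holdout = r_squared_ss(pred_te, y[test]),
           rmse_holdout = rmse(pred_te, y[test]),
           r2_train = r_squared(pred_tr, y[tr]),
           rmse_train = rmse(pred_tr, y[tr]),
           n_samples = n, n_test = length(test),
           n_features_kept = length(pruning$kept),
           n_features_selected = selection$optimal_n)),
    class = "maturity_pipeline")
}

#' @export
print.maturity_pipeline <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<maturity_pipeline> %s on %d plot-date samples\n",
              x$family, m$n_samples))
  cat(sprintf("  pruning: 22 -> %d features; RFECV: %d selected (%s)\n",
              m$n_features_kept, m$n_features_selected,
              paste(x$selection$optimal_subset, collapse = ", ")))
  cat(sprintf("  holdout (n = %d): R^2 = %.3f, RMSE = %.2f days\n",
              m$n_test, m$r2_holdout, m$rmse_holdout))
  invisible(x)
}

#' @export
glance.maturity_pipeline <- function(x, ...) {
  as_tibble(x$metrics[c("r2_holdout", "r2_ss_holdout", "rmse_holdout",
                        "r2_train", "rmse_train", "n_samples",
                        "n_features_kept", "n_features_selected")]) |>
    dplyr::mutate(family = x$family, .before = 1)
}
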