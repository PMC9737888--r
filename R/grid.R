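# The feature-space x model-family evaluation grid.

#' Default named feature spaces
#'
#' The four canonical spaces: the vegetation indices alone, the texture
#' features alone, the colour features alone, and all 22 features. Optimised
#' per-family spaces from [rfecv()] can be appended by name.
#'
#' @param extra Optional named list of additional feature-name subsets.
#' @return Named list of character vectors.
#' @export
default_feature_spaces <- function(extra = list()) {
  c(list(vegetation_indices = vegetation_index_names(),
         texture_features = texture_feature_names(),
         color_features = color_feature_names(),
         all_features = feature_names()),
    extra)
}

#' Evaluation protocol for the grid
#'
#' @param k_folds Folds for the cross-validation metric.
#' @param holdout_frac Test fraction for the holdout metric.
#' @param repeats Number of repetitions (distinct seeds) averaged.
#' @return A protocol list for [run_grid()].
#' @export
grid_protocol <- function(k_folds = 5L, holdout_frac = 0.2, repeats = 5L) {
  stopifnot(k_folds >= 2, holdout_frac > 0, holdout_frac < 1, repeats >= 1)
  list(k_folds = as.integer(k_folds), holdout_frac = holdout_frac,
       repeats = as.integer(repeats))
}

cv_metrics <- function(features, labels, family, k_folds, seed) {
  n <- nrow(features)
  folds <- with_seed(seed, sample(rep(seq_len(k_folds), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    fit <- fit_model(features[tr, , drop = FALSE], labels[tr], family,
                     seed = derive_seed(seed, f))
    pred[!tr] <- predict(fit, features[!tr, , drop = FALSE])
  }
  c(r2 = r_squared(pred, labels), rmse = rmse(pred, labels))
}

holdout_metrics <- function(features, labels, family, frac, seed) {
  n <- nrow(features)
  test <- with_seed(seed, sample.int(n, max(1L, round(frac * n))))
  tr <- setdiff(seq_len(n), test)
  fit <- fit_model(features[tr, , drop = FALSE], labels[tr], family,
                   seed = derive_seed(seed, 99L))
  pred_te <- predict(fit, features[test, , drop = FALSE])
  pred_tr <- predict(fit, features[tr, , drop = FALSE])
  c(r2 = r_squared(pred_te, labels[test]), rmse = rmse(pred_te, labels[test]),
    r2_train = r_squared(pred_tr, labels[tr]),
    rmse_train = rmse(pred_tr, labels[tr]))
}

#' Run the feature-space x model-family grid
#'
#' Evaluates every (feature space, family) pair under the same protocol:
#' k-fold cross-validation R²/RMSE and an 80/20 holdout R²/RMSE (plus
#' training-set metrics), each averaged over `protocol$repeats` repetitions
#' with distinct derived seeds. R² is the correlation-based definition
#' ([r_squared()]); RMSE is in days.
#'
#' @param features Data frame holding at least the union of all space columns.
#' @param labels Numeric response.
#' @param feature_spaces Named list of feature-name subsets,
#'   e.g. [default_feature_spaces()].
#' @param families Model families to evaluate, see [model_families()].
#' @param protocol A [grid_protocol()].
#' @param seed Master seed.
#' @return A `grid_report` tibble: one row per pair with columns
#'   `feature_space`, `family`, `r2_cv`, `rmse_cv`, `r2_holdout`,
#'   `rmse_holdout`, `r2_train`, `rmse_train`.
#' @export
run_grid <- function(features, labels, feature_spaces = default_feature_spaces(),
                     families = model_families(), protocol = grid_protocol(),
                     seed = 0L) {
  stopifnot(length(names(feature_spaces)) == length(feature_spaces))
  for (nm in names(feature_spaces)) {
    missing <- setdiff(feature_spaces[[nm]], colnames(features))
    if (length(missing) > 0) {
      stop_param("feature space '%s' names unknown column(s): %s",
                 nm, paste(missing, collapse = ", "))
    }
  }
  grid <- tidyr::expand_grid(feature_space = names(feature_spaces),
                             family = families)
  rows <- purrr::pmap(grid, function(feature_space, family) {
    cols <- feature_spaces[[feature_space]]
    X <- features[, cols, drop = FALSE]
    reps <- purrr::map(seq_len(protocol$repeats), function(r) {
      s <- derive_seed(seed, r, match(family, MODEL_FAMILIES))
      cv <- cv_metrics(X, labels, family, protocol$k_folds, s)
      ho <- holdout_metrics(X, labels, family, protocol$holdout_frac,
                            derive_seed(s, 7L))
      c(r2_cv = unname(cv["r2"]), rmse_cv = unname(cv["rmse"]),
        r2_holdout = unname(ho["r2"]), rmse_holdout = unname(ho["rmse"]),
        r2_train = unname(ho["r2_train"]), rmse_train = unname(ho["rmse_train"]))
    })
    avg <- colMeans(do.call(rbind, reps))
    tibble(feature_space = feature_space, family = family, !!!as.list(avg))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("grid_report", class(out))
  out
}

#' @export
autoplot.grid_report <- function(object, metric = "r2_cv", ...) {
  ggplot2::ggplot(object, ggplot2::aes(
      x = .data$family, y = .data$feature_space, fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data[[metric]])),
                       size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = metric,
                  title = "Feature space x model family") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Write a grid report as CSV and JSON
#'
#' @param report A `grid_report`.
#' @param csv_path,json_path Output paths (NULL skips).
#' @return Invisibly, the report.
#' @export
write_grid_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(report, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(report)
}
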