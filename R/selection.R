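# Feature selection: Pearson redundancy pruning and recursive feature
# elimination with cross-validation (RFECV).

#' Pearson correlation matrix of a feature table
#'
#' @param table Data frame of numeric feature columns (at least 3 rows).
#'   Non-numeric and list columns are ignored; a constant column is an error
#'   (its correlation is undefined).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(table) {
  num <- table[, vapply(table, function(c) is.numeric(c) && !is.list(c),
                        logical(1)), drop = FALSE]
  m <- as.matrix(num)
  if (nrow(m) < 3) stop_param("need at least 3 rows for correlation")
  sds <- apply(m, 2, sd)
  if (any(sds < 1e-12)) {
    stop_param("constant column(s): %s",
               paste(colnames(m)[sds < 1e-12], collapse = ", "))
  }
  cor(m)
}

# Connected components of the |r| > threshold graph, via union-find.
correlated_groups <- function(r, threshold) {
  p <- ncol(r)
  parent <- seq_len(p)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (p > 1) for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    if (abs(r[i, j]) > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(p), find, integer(1))
}

#' Prune highly correlated features
#'
#' Groups features whose pairwise |r| exceeds the threshold (connected
#' components of the correlation graph) and keeps, within each group, the
#' member most correlated (in absolute value) with the label, removing the
#' rest. Ties keep the earlier column, so the result is deterministic given
#' column order.
#'
#' @param table Data frame of numeric feature columns.
#' @param labels Numeric label vector (used to rank group members).
#' @param threshold Absolute correlation above which two features are
#'   considered redundant.
#' @return A `correlation_report` list: `matrix` (feature correlations),
#'   `kept`, `removed`, `threshold`, and `label_correlation`.
#' @examples
#' tab <- generate_feature_table(table_config(seed = 2))
#' rep <- prune_correlated(dplyr::select(tab, -label), tab$label)
#' rep$removed  # the redundant near-duplicates
#' @export
prune_correlated <- function(table, labels, threshold = 0.9) {
  r <- pearson_matrix(table)
  feats <- colnames(r)
  labels <- as.numeric(labels)
  lab_cor <- vapply(feats, function(f) {
    x <- as.numeric(table[[f]])
    if (sd(labels) < 1e-12) 0 else abs(cor(x, labels))
  }, numeric(1))
  comp <- correlated_groups(r, threshold)
  keep <- logical(length(feats))
  for (g in unique(comp)) {
    members <- which(comp == g)
    best <- members[which.max(lab_cor[members])]  # which.max ties -> earliest
    keep[best] <- TRUE
  }
  structure(
    list(matrix = r, kept = feats[keep], removed = feats[!keep],
         threshold = threshold, label_correlation = lab_cor),
    class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("<correlation_report> |r| > %.2f: kept %d, removed %d feature(s)\n",
              x$threshold, length(x$kept), length(x$removed)))
  if (length(x$removed)) cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.correlation_report <- function(x, ...) {
  tibble(feature = c(x$kept, x$removed),
         status = rep(c("kept", "removed"), c(length(x$kept), length(x$removed))),
         label_correlation = unname(x$label_correlation[c(x$kept, x$removed)]))
}

# One full elimination path: features in removal order (first removed first),
# refitting the model and dropping the single least-important feature until
# one remains. rfe(k) is then the last k entries plus survivors.
rfe_path <- function(features, labels, family, seed) {
  current <- colnames(features)
  removed <- character(0)
  step <- 0L
  while (length(current) > 1L) {
    fit <- fit_model(features[, current, drop = FALSE], labels, family,
                     seed = derive_seed(seed, step))
    imp <- feature_importance(fit)
    worst <- names(imp)[which.min(imp)]  # ties: earliest column
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
    step <- step + 1L
  }
  c(removed, current)  # length p; last element = most persistent feature
}

#' Recursive feature elimination to a fixed size
#'
#' Iteratively fits the model, ranks features by the model's internal
#' importance ([feature_importance()]), and removes the single least
#' important feature until `target_n` remain.
#'
#' @param features Data frame of numeric feature columns.
#' @param labels Numeric response.
#' @param family Model family, see [model_families()].
#' @param target_n Number of features to retain.
#' @param seed Integer seed.
#' @return Character vector of the `target_n` surviving feature names, in
#'   original column order.
#' @export
rfe <- function(features, labels, family, target_n, seed = 0L) {
  p <- ncol(features)
  if (target_n < 1 || target_n > p) {
    stop_param("target_n must lie in [1, %d]", p)
  }
  if (target_n == p) return(colnames(features))
  path <- rfe_path(features, labels, family, seed)
  keep <- path[seq(p - target_n + 1L, p)]
  intersect(colnames(features), keep)
}

#' Recursive feature elimination with cross-validation
#'
#' For each fold of a k-fold split, the RFE elimination path is computed on
#' the training rows alone and every subset size is scored on the held-out
#' rows with the correlation-based R² ([r_squared()]); the per-size scores
#' are averaged over folds into a CV curve. The optimal size is the smallest
#' n whose mean score is within `tol` of the curve's maximum (parsimony
#' tie-break), and the returned subset is the RFE result at that size on the
#' full table.
#'
#' @inheritParams rfe
#' @param k_folds Number of cross-validation folds (rows must be >= folds).
#' @param tol Score tolerance for the parsimony tie-break.
#' @return A `selection_result`: `model_family`, `cv_curve` (tibble
#'   `n_features`, `mean_score`), `optimal_n`, `optimal_subset`, `fold_seed`.
#' @examples
#' \donttest{
#' tab <- generate_feature_table(table_config(n_samples = 150, n_noise = 4,
#'                                            n_redundant = 0, seed = 3))
#' sel <- rfecv(dplyr::select(tab, -label), tab$label, "decision_tree")
#' sel$optimal_subset
#' }
#' @export
rfecv <- function(features, labels, family, k_folds = 5L, seed = 0L,
                  tol = 1e-9) {
  n <- nrow(features); p <- ncol(features)
  if (n < k_folds) stop_param("fewer rows (%d) than folds (%d)", n, k_folds)
  folds <- with_seed(derive_seed(seed, 1L),
                     sample(rep(seq_len(k_folds), length.out = n)))
  scores <- matrix(NA_real_, k_folds, p)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    path <- rfe_path(features[tr, , drop = FALSE], labels[tr], family,
                     seed = derive_seed(seed, 2L, f))
    for (k in seq_len(p)) {
      sub <- path[seq(p - k + 1L, p)]
      fit <- fit_model(features[tr, sub, drop = FALSE], labels[tr], family,
                       seed = derive_seed(seed, 3L, f))
      pred <- predict(fit, features[!tr, sub, drop = FALSE])
      scores[f, k] <- tryCatch(r_squared(pred, labels[!tr]),
                               error = function(e) 0)
    }
  }
  curve <- colMeans(scores)
  optimal_n <- which(curve >= max(curve) - tol)[1]
  subset <- rfe(features, labels, family, optimal_n,
                seed = derive_seed(seed, 4L))
  structure(
    list(model_family = family,
         cv_curve = tibble(n_features = seq_len(p), mean_score = curve),
         fold_scores = scores,
         optimal_n = as.integer(optimal_n), optimal_subset = subset,
         fold_seed = as.integer(seed)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: optimal n = %d (CV R^2 = %.3f)\n",
              x$model_family, x$optimal_n,
              x$cv_curve$mean_score[x$optimal_n]))
  cat("  subset:", paste(x$optimal_subset, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.selection_result <- function(x, ...) {
  dplyr::mutate(x$cv_curve, model_family = x$model_family,
                optimal = .data$n_features == x$optimal_n)
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble(model_family = x$model_family, optimal_n = x$optimal_n,
         best_score = x$cv_curve$mean_score[x$optimal_n],
         n_candidates = nrow(x$cv_curve))
}

#' @export
autoplot.selection_result <- function(object, ...) {
  ggplot2::ggplot(object$cv_curve,
                  ggplot2::aes(x = .data$n_features, y = .data$mean_score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$optimal_n, linetype = "dashed") +
    ggplot2::labs(x = "Number of features", y = "Mean CV R²",
                  title = sprintf("RFECV curve (%s), optimal n = %d",
                                  object$model_family, object$optimal_n)) +
    ggplot2::theme_minimal()
}

#' Write a selection result to JSON (plus the CV curve as CSV)
#'
#' @param x A `selection_result`.
#' @param path Output JSON path; the curve goes to `<path>.curve.csv`.
#' @return Invisibly, `x`.
#' @export
write_selection_result <- function(x, path) {
  jsonlite::write_json(
    list(model_family = x$model_family,
         cv_curve = as.list(stats::setNames(x$cv_curve$mean_score,
                                            x$cv_curve$n_features)),
         optimal_n = x$optimal_n, optimal_subset = x$optimal_subset,
         fold_seed = x$fold_seed),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(x$cv_curve, paste0(path, ".curve.csv"), row.names = FALSE)
  invisible(x)
}
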