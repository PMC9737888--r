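# Permutation feature importance: score drop when one feature column is
# shuffled, PFI_j = s - (1/K) * sum_k s_{k,j}.

#' Permutation feature importance
#'
#' Computes the baseline correlation-based R² of the fitted model on the
#' given data, then, for each feature and each of `K` repetitions, shuffles
#' that single column, re-scores, and reports the mean score drop. A feature
#' the model never uses cannot change predictions when shuffled, so its PFI
#' is 0 up to Monte-Carlo noise.
#'
#' @param object A fitted `maturity_model`.
#' @param features Data frame of feature columns (training or held-out).
#' @param labels Numeric response for scoring.
#' @param K Number of shuffles per feature.
#' @param seed Integer seed (same seed reproduces the shuffles exactly).
#' @return A `pfi_result`: tibble `importance` (`feature`, `pfi`),
#'   `baseline_score`, matrix `rep_scores` (K x features, the permuted
#'   scores per repetition for boxplots), `K`.
#' @examples
#' tab <- generate_feature_table(table_config(n_samples = 120, seed = 4))
#' X <- dplyr::select(tab, -label)
#' fit <- fit_model(X, tab$label, "linear")
#' pfi <- permutation_importance(fit, X, tab$label, K = 5)
#' head(tidy(pfi))
#' @export
permutation_importance <- function(object, features, labels, K = 10L,
                                   seed = 0L) {
  stopifnot(inherits(object, "maturity_model"))
  if (K < 1) stop_param("K must be >= 1")
  x <- as.data.frame(features)[, object$feature_names, drop = FALSE]
  labels <- as.numeric(labels)
  s <- r_squared(predict(object, x), labels)
  p <- ncol(x)
  rep_scores <- matrix(NA_real_, K, p, dimnames = list(NULL, colnames(x)))
  with_seed(seed, {
    for (j in seq_len(p)) {
      for (k in seq_len(K)) {
        xp <- x
        xp[[j]] <- xp[[j]][sample.int(nrow(xp))]
        rep_scores[k, j] <- tryCatch(r_squared(predict(object, xp), labels),
                                     error = function(e) 0)
      }
    }
  })
  pfi <- s - colMeans(rep_scores)
  structure(
    list(importance = tibble(feature = colnames(x), pfi = unname(pfi)),
         baseline_score = s, rep_scores = rep_scores, K = as.integer(K),
         family = object$family),
    class = "pfi_result")
}

#' @export
print.pfi_result <- function(x, ...) {
  cat(sprintf("<pfi_result> %s, baseline R^2 = %.3f, K = %d\n",
              x$family, x$baseline_score, x$K))
  top <- dplyr::arrange(x$importance, dplyr::desc(.data$pfi))
  print(utils::head(top, 5))
  invisible(x)
}

#' @export
tidy.pfi_result <- function(x, ...) {
  dplyr::arrange(x$importance, dplyr::desc(.data$pfi))
}

#' @export
autoplot.pfi_result <- function(object, ...) {
  long <- as_tibble(object$rep_scores) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "feature",
                        values_to = "permuted_score") |>
    dplyr::mutate(drop = object$baseline_score - .data$permuted_score)
  ord <- dplyr::arrange(object$importance, .data$pfi)$feature
  ggplot2::ggplot(long, ggplot2::aes(
      x = .data$drop, y = factor(.data$feature, levels = ord))) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = "Score drop when shuffled (PFI)", y = NULL,
                  title = sprintf("Permutation importance (%s)", object$family)) +
    ggplot2::theme_minimal()
}

#' Write PFI repetition scores as CSV (boxplot data)
#'
#' @param x A `pfi_result`.
#' @param path Output CSV path.
#' @return Invisibly, `x`.
#' @export
write_pfi <- function(x, path) {
  long <- as_tibble(x$rep_scores) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "feature",
                        values_to = "permuted_score") |>
    dplyr::mutate(baseline = x$baseline_score,
                  drop = x$baseline_score - .data$permuted_score)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(x)
}
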