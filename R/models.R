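# The six regression families, behind one interface. Each family is fitted
# via the established implementation (rpart, stats::lm, randomForest,
# xgboost, ranger); AdaBoost.R2 regression has no pre-installed
# implementation and is authored here over rpart base learners.

MODEL_FAMILIES <- c("decision_tree", "linear", "random_forest", "adaboost",
                    "gradient_boosting", "extra_trees")

#' Recognised regression families
#' @return Character vector of family names accepted by [fit_model()].
#' @export
model_families <- function() MODEL_FAMILIES

as_feature_matrix <- function(features) {
  m <- as.matrix(as.data.frame(features))
  if (!is.numeric(m)) stop_param("features must be numeric columns")
  if (is.null(colnames(m))) colnames(m) <- paste0("x", seq_len(ncol(m)))
  m
}

#' Fit one regression family
#'
#' Fits a predictor mapping feature rows to days-to-maturity. All families
#' are deterministic given the seed; hyperparameters are the backing
#' libraries' defaults, lightly pinned for reproducibility, and exposed via
#' `control`.
#'
#' @param features Data frame / tibble of numeric feature columns.
#' @param labels Numeric response (corrected maturity days).
#' @param family One of `r paste(MODEL_FAMILIES, collapse = ", ")`.
#' @param seed Integer seed.
#' @param control Optional named list overriding family hyperparameters
#'   (`n_trees`, `max_depth`, `learning_rate`, `n_rounds`).
#' @return A `maturity_model` object with `predict()`, [feature_importance()],
#'   [tidy()] and [glance()] methods.
#' @examples
#' tab <- generate_feature_table(table_config(n_samples = 80, seed = 1))
#' fit <- fit_model(dplyr::select(tab, -label), tab$label, "linear")
#' rmse(predict(fit, dplyr::select(tab, -label)), tab$label)
#' @export
fit_model <- function(features, labels,
                      family = c("decision_tree", "linear", "random_forest",
                                 "adaboost", "gradient_boosting",
                                 "extra_trees"),
                      seed = 0L, control = list()) {
  if (length(family) != 1L || !family %in% MODEL_FAMILIES) {
    family <- tryCatch(match.arg(family),
                       error = function(e) stop_param(
                         "unknown model family '%s'; valid families: %s",
                         paste(family, collapse = "/"),
                         paste(MODEL_FAMILIES, collapse = ", ")))
  }
  x <- as_feature_matrix(features)
  y <- as.numeric(labels)
  if (nrow(x) != length(y)) stop_param("features and labels disagree in length")
  if (nrow(x) < 2) stop_param("need at least 2 samples")
  ctl <- utils::modifyList(
    list(n_trees = 200L, max_depth = 3L, learning_rate = 0.1,
         n_rounds = 100L, ada_rounds = 50L),
    control)

  fit <- with_seed(seed, switch(family,
    decision_tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, method = "anova",
                   control = rpart::rpart.control(minsplit = 5, cp = 1e-4,
                                                  xval = 0))
    },
    linear = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      lm(.y ~ ., data = df)
    },
    random_forest = randomForest::randomForest(x = x, y = y,
                                               ntree = ctl$n_trees),
    adaboost = fit_adaboost_r2(x, y, n_rounds = ctl$ada_rounds,
                               max_depth = ctl$max_depth),
    gradient_boosting = xgboost::xgb.train(
      params = list(objective = "reg:squarederror", eta = ctl$learning_rate,
                    max_depth = ctl$max_depth, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
      nrounds = ctl$n_rounds, verbose = 0),
    extra_trees = ranger::ranger(
      x = x, y = y, num.trees = ctl$n_trees, splitrule = "extratrees",
      num.random.splits = 1, replace = FALSE, sample.fraction = 1,
      mtry = ncol(x), importance = "impurity", seed = seed,
      num.threads = 1)))

  structure(list(family = family, fit = fit, feature_names = colnames(x),
                 seed = seed, n_train = nrow(x),
                 train_x = x, train_y = y),
            class = "maturity_model")
}

# --- AdaBoost.R2 (Drucker 1997), linear loss, rpart base learners ----------

fit_adaboost_r2 <- function(x, y, n_rounds = 50L, max_depth = 3L) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- data.frame(.y = y, x, check.names = FALSE)
  trees <- list(); betas <- numeric(0)
  for (k in seq_len(n_rounds)) {
    tr <- rpart::rpart(.y ~ ., data = df, weights = w, method = "anova",
                       control = rpart::rpart.control(
                         minsplit = 5, cp = 1e-4, xval = 0,
                         maxdepth = max_depth))
    pred <- predict(tr, df)
    err <- abs(pred - y)
    emax <- max(err)
    if (emax < 1e-12) { trees <- c(trees, list(tr)); betas <- c(betas, 1e-12); break }
    loss <- err / emax
    lbar <- sum(w * loss)
    if (lbar >= 0.5) { if (length(trees) == 0) { trees <- list(tr); betas <- 1 }; break }
    beta <- lbar / (1 - lbar)
    trees <- c(trees, list(tr))
    betas <- c(betas, beta)
    w <- w * beta^(1 - loss)
    w <- w / sum(w)
  }
  structure(list(trees = trees, log_inv_beta = log(1 / betas)),
            class = "adaboost_r2")
}

# Weighted-median combination of the base learners' predictions.
predict_adaboost_r2 <- function(object, newdata) {
  preds <- vapply(object$trees, function(tr) predict(tr, newdata),
                  numeric(nrow(newdata)))
  preds <- matrix(preds, nrow = nrow(newdata))
  wts <- object$log_inv_beta
  half <- sum(wts) / 2
  apply(preds, 1, function(p) {
    o <- order(p)
    p[o][which(cumsum(wts[o]) >= half)[1]]
  })
}

#' @export
predict.maturity_model <- function(object, newdata, ...) {
  x <- as_feature_matrix(newdata)
  x <- x[, object$feature_names, drop = FALSE]
  df <- as.data.frame(x)
  switch(object$family,
    decision_tree = unname(predict(object$fit, df)),
    linear = unname(predict(object$fit, df)),
    random_forest = unname(predict(object$fit, x)),
    adaboost = unname(predict_adaboost_r2(object$fit, df)),
    gradient_boosting = unname(predict(object$fit,
                                       xgboost::xgb.DMatrix(x, nthread = 1))),
    extra_trees = unname(predict(object$fit, data = df)$predictions))
}

#' Model-internal feature importance
#'
#' The ranking attribute used by recursive feature elimination: absolute
#' standardized coefficients for the linear family, impurity/gain importance
#' for the tree families. Features absent from the fitted structure score 0.
#'
#' @param object A fitted `maturity_model`.
#' @return Named numeric vector over the model's features (all >= 0).
#' @export
feature_importance <- function(object) {
  stopifnot(inherits(object, "maturity_model"))
  fn <- object$feature_names
  imp <- stats::setNames(numeric(length(fn)), fn)
  raw <- switch(object$family,
    decision_tree = object$fit$variable.importance,
    linear = {
      cf <- coef(object$fit)[-1]
      sds <- apply(object$train_x, 2, sd)
      abs(cf) * sds[names(cf)]
    },
    random_forest = {
      v <- randomForest::importance(object$fit)[, 1]
      stats::setNames(as.numeric(v), rownames(randomForest::importance(object$fit)))
    },
    adaboost = {
      acc <- stats::setNames(numeric(length(fn)), fn)
      for (k in seq_along(object$fit$trees)) {
        vi <- object$fit$trees[[k]]$variable.importance
        if (!is.null(vi)) acc[names(vi)] <- acc[names(vi)] +
            object$fit$log_inv_beta[k] * vi
      }
      acc
    },
    gradient_boosting = {
      tab <- xgboost::xgb.importance(model = object$fit)
      stats::setNames(tab$Gain, tab$Feature)
    },
    extra_trees = ranger::importance(object$fit))
  raw <- raw[!is.na(names(raw))]
  common <- intersect(names(raw), fn)
  imp[common] <- pmax(as.numeric(raw[common]), 0)
  imp[is.na(imp)] <- 0
  imp
}

#' @export
print.maturity_model <- function(x, ...) {
  cat(sprintf("<maturity_model> family = %s, %d features, %d training samples\n",
              x$family, length(x$feature_names), x$n_train))
  invisible(x)
}

#' @export
glance.maturity_model <- function(x, ...) {
  pred <- predict(x, as.data.frame(x$train_x))
  tibble(family = x$family, n_features = length(x$feature_names),
         n_train = x$n_train,
         r_squared_train = r_squared(pred, x$train_y),
         rmse_train = rmse(pred, x$train_y))
}

#' @export
tidy.maturity_model <- function(x, ...) {
  imp <- feature_importance(x)
  tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
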