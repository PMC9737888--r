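# Evaluation metrics for days-to-maturity regression.

#' Correlation-based coefficient of determination
#'
#' The R² used throughout this package is the squared Pearson correlation
#' between estimates and measurements,
#' \deqn{R^2 = \frac{[\sum_i (X_i - \bar X)(Y_i - \bar Y)]^2}
#'                  {\sum_i (X_i - \bar X)^2 \sum_i (Y_i - \bar Y)^2},}
#' which is symmetric in its arguments and invariant to shifting/scaling of
#' either one — a systematic bias of the predictions does not lower it (use
#' [rmse()] to detect that, or [r_squared_ss()] for the residual-based
#' definition).
#'
#' @param x Estimated values.
#' @param y Measured values (same length, both non-constant).
#' @return Scalar in \eqn{[0, 1]}.
#' @examples
#' r_squared(1:10, 2 * (1:10) + 5)  # 1: shift/scale invariant
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (length(x) < 2) stop_param("need at least 2 observations")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    stop_param("R-squared undefined for a constant vector")
  }
  cor(x, y)^2
}

#' Residual-based coefficient of determination
#'
#' The conventional `1 - SS_res / SS_tot` definition, which does penalise
#' biased or mis-scaled predictions (and can be negative). Provided alongside
#' [r_squared()] so both conventions are available.
#'
#' @inheritParams r_squared
#' @return Scalar, at most 1.
#' @export
r_squared_ss <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (sd(y) < 1e-12) stop_param("R-squared undefined for constant measurements")
  1 - sum((y - x)^2) / sum((y - mean(y))^2)
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of the inputs (days, for maturity labels).
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(25 / 2)
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop_param("x and y must have equal length")
  if (length(x) < 1) stop_param("need at least 1 observation")
  sqrt(mean((y - x)^2))
}
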