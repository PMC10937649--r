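# Correlation and error metrics for real-valued predictions. x is the
# ground truth, y the prediction, following the usual regression-evaluation
# convention.

#' Pearson's correlation coefficient
#'
#' \eqn{r = \sum_i (x_i - \bar x)(y_i - \bar y) /
#' \sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}.
#'
#' @param x Ground-truth values.
#' @param y Predicted values, same length.
#' @return r in \eqn{[-1, 1]}; a constant vector raises an undefined-metric
#'   condition.
#' @export
pearson_r <- function(x, y) {
  check_paired_reals(x, y)
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0)
    stop_undefined("correlation undefined: constant input vector", "pearson_r")
  sum(dx * dy) / den
}

#' Spearman's rank correlation coefficient
#'
#' Pearson's correlation of the rank-transformed vectors; tied observations
#' receive average (mid) ranks.
#'
#' @inheritParams pearson_r
#' @return r_s in \eqn{[-1, 1]}.
#' @export
spearman_r <- function(x, y) {
  check_paired_reals(x, y)
  pearson_r(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

#' Mean absolute error and mean squared error
#'
#' `mae` is the mean of \eqn{|x_i - y_i|}, `mse` the mean of
#' \eqn{(x_i - y_i)^2}. Division by n keeps the values comparable across
#' test sets of different sizes; `sum = TRUE` returns the raw sums instead.
#' MSE penalises large residuals more heavily than MAE.
#'
#' @inheritParams pearson_r
#' @param sum If `TRUE`, return the un-normalised sum of errors.
#' @return A non-negative value.
#' @export
mae <- function(x, y, sum = FALSE) {
  check_paired_reals(x, y)
  e <- abs(x - y)
  if (sum) base::sum(e) else mean(e)
}

#' @rdname mae
#' @export
mse <- function(x, y, sum = FALSE) {
  check_paired_reals(x, y)
  e <- (x - y)^2
  if (sum) base::sum(e) else mean(e)
}

check_paired_reals <- function(x, y) {
  if (length(x) != length(y)) stop_input("'x' and 'y' must have the same length")
  if (length(x) == 0L) stop_input("empty input vectors")
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y))
    stop_input("'x' and 'y' must be numeric with no missing values")
  invisible(TRUE)
}
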