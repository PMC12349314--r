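# Count-to-yield regression: polynomial least squares on (visible count,
# true count) pairs, plain and adjusted coefficients of determination,
# integer yield prediction, and E1/E2 error accounting with the truncation
# convention used by the published tables.

# truncate (floor) to k decimal digits; the small guard absorbs binary
# representation error in values that are exact decimals
trunc_dec <- function(x, k) floor(x * 10^k + 1e-9) / 10^k

#' Fit a count-to-yield polynomial by ordinary least squares
#'
#' Regresses the true fruit count on the single-view detected count with a
#' degree 1 (linear) or degree 2 (quadratic) polynomial.
#'
#' @param pairs data frame with columns `detect` and `actual`.
#' @param degree 1 or 2.
#' @return a `crl_fit`: `degree`, `coefficients` (constant term first),
#'   `r2_plain`, `r2_adjusted`, `n`.
#' @export
fit_polynomial <- function(pairs, degree = 1L) {
  stopifnot(degree %in% c(1L, 2L))
  n <- nrow(pairs)
  if (n < degree + 2L) stop("fit_polynomial: need at least degree + 2 points")
  if (length(unique(pairs$detect)) == 1L)
    stop("fit_polynomial: rank-deficient design (all detect values equal)")
  x <- pairs$detect
  y <- pairs$actual
  fit <- if (degree == 1L) lm(y ~ x) else lm(y ~ x + I(x^2))
  yhat <- fitted(fit)
  structure(list(degree = as.integer(degree),
                 coefficients = unname(coef(fit)),
                 r2_plain = coefficient_of_determination(y, yhat, degree,
                                                         adjusted = FALSE),
                 r2_adjusted = coefficient_of_determination(y, yhat, degree,
                                                            adjusted = TRUE),
                 n = n),
            class = "crl_fit")
}

#' @export
print.crl_fit <- function(x, ...) {
  terms <- c("", "x", "x^2")[seq_len(x$degree + 1L)]
  eq <- paste(rev(sprintf("%.5f%s", x$coefficients, terms)), collapse = " + ")
  cat(sprintf("y = %s\nR2 (plain) = %.5f   R2 (adjusted) = %.5f   n = %d\n",
              eq, x$r2_plain, x$r2_adjusted, x$n))
  invisible(x)
}

#' Coefficient of determination
#'
#' Plain: `1 - SSres/SStot`. Adjusted:
#' `1 - (SSres/(n - p - 1)) / (SStot/(n - 1))` for `p` predictors.
#'
#' @param y observed values.
#' @param y_hat fitted values.
#' @param n_predictors number of model predictors `p`.
#' @param adjusted return the adjusted variant.
#' @return R-squared value.
#' @export
coefficient_of_determination <- function(y, y_hat, n_predictors,
                                         adjusted = FALSE) {
  n <- length(y)
  stopifnot(length(y_hat) == n, n >= n_predictors + 2L)
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("coefficient_of_determination: zero total variance")
  if (!adjusted) return(1 - ss_res / ss_tot)
  1 - (ss_res / (n - n_predictors - 1)) / (ss_tot / (n - 1))
}

#' Predict a whole-tree count from a visible count
#'
#' Evaluates the fitted polynomial and rounds half away from zero to the
#' nearest non-negative integer.
#'
#' @param fit a `crl_fit`.
#' @param detect visible (single-view) count, >= 0; vectorized.
#' @return integer predicted count(s).
#' @export
predict_count <- function(fit, detect) {
  stopifnot(all(detect >= 0))
  v <- outer(detect, 0:fit$degree, "^") %*% fit$coefficients
  r <- sign(v) * floor(abs(v) + 0.5)       # round half away from zero
  as.integer(pmax(r, 0))
}

#' Tree-level prediction error accounting
#'
#' For each tree computes `E1 = |actual - detect|`,
#' `E2 = |actual - predicted|` and the error rate `100 * E2 / actual`,
#' truncated (not rounded) to one decimal for display; the mean error rate is
#' the mean of the per-tree rates truncated to two decimals.
#'
#' @param records data frame with `detect`, `actual`, `predicted` (and
#'   optionally `tree_id`).
#' @param rates optional per-tree percentage rates to average in place of the
#'   computed ones (used to reproduce published tables verbatim).
#' @return list with `table` (records plus `E1`, `E2`, `error_rate`) and
#'   `mean_error_rate` (percent).
#' @export
evaluate_predictions <- function(records, rates = NULL) {
  if (any(records$actual <= 0))
    stop("evaluate_predictions: every tree must have a positive true count")
  e1 <- abs(records$actual - records$detect)
  e2 <- abs(records$actual - records$predicted)
  rate <- trunc_dec(100 * e2 / records$actual, 1L)
  tab <- cbind(records, E1 = e1, E2 = e2, error_rate = rate)
  use <- if (is.null(rates)) rate else rates
  list(table = tab, mean_error_rate = trunc_dec(mean(use), 2L))
}

#' Published tree-count tables
#'
#' The four embedded field-count tables: ten (detect, actual) fitting pairs
#' for each of the green-fruit and ripening stages, and six validation
#' records per stage (with the published predicted counts and the published
#' per-tree error-rate column).
#'
#' @return named list `green_fit`, `ripe_fit`, `green_valid`, `ripe_valid`.
#' @export
citrus_count_tables <- function() {
  rd <- function(f) read.csv(system.file("extdata", f, package = "citrusRL"))
  list(green_fit = rd("green_fit.csv"), ripe_fit = rd("ripe_fit.csv"),
       green_valid = rd("green_valid.csv"), ripe_valid = rd("ripe_valid.csv"))
}

#' Fit the stage yield model on the packaged tables
#'
#' Green-fruit stage: linear fit. Ripening stage: quadratic fit (the degree
#' choices that minimize residual error on the respective tables).
#'
#' @param stage `"green"` or `"ripe"`.
#' @return a `crl_fit`.
#' @export
stage_yield_fit <- function(stage = c("green", "ripe")) {
  stage <- match.arg(stage)
  tabs <- citrus_count_tables()
  if (stage == "green") fit_polynomial(tabs$green_fit, 1L)
  else fit_polynomial(tabs$ripe_fit, 2L)
}
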