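#' Coefficient of determination
#'
#' `R^2 = 1 - SSres / SStot`. Undefined (NA with a warning) when the
#' reference values have zero variance.
#'
#' @param y Reference values.
#' @param yhat Predicted values, same length, n >= 2.
#' @return Dimensionless R-squared (<= 1, can be negative).
#' @export
r2 <- function(y, yhat) {
  check_pairs(y, yhat)
  sstot <- sum((y - mean(y))^2)
  if (sstot == 0) {
    warning("zero variance in reference values: R^2 undefined")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / sstot
}

#' Mean absolute error
#' @inheritParams r2
#' @return MAE in the units of `y` (samples, typically).
#' @export
mae <- function(y, yhat) {
  check_pairs(y, yhat)
  mean(abs(y - yhat))
}

#' Root mean square error
#' @inheritParams r2
#' @return RMSE in the units of `y`; always `>= mae(y, yhat)`.
#' @export
rmse <- function(y, yhat) {
  check_pairs(y, yhat)
  sqrt(mean((y - yhat)^2))
}

check_pairs <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2) stop("need at least 2 paired values")
  invisible(TRUE)
}

#' Convert sample counts to milliseconds
#'
#' @param value Value in samples.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @return `value / sampling_rate * 1000`, in ms.
#' @export
samples_to_ms <- function(value, sampling_rate) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  value / sampling_rate * 1000
}

#' Mean and sample standard deviation of run values
#'
#' The SD uses the n-1 denominator; this convention reproduces the
#' published cross-validation summary columns exactly and is asserted in
#' the test suite.
#'
#' @param values Numeric vector, n >= 2.
#' @return List with `mean` and `sample_sd`.
#' @export
summarize_runs <- function(values) {
  if (length(values) < 2) stop("need at least 2 values (SD undefined)")
  list(mean = mean(values), sample_sd = stats::sd(values))
}

#' Aggregate a per-feature metric across features
#'
#' Arithmetic mean over the non-excluded features at full precision;
#' rounding to the display precision of published tables is the caller's
#' choice. The default exclusion drops the rapid-ejection and
#' rapid-filling peaks (RE, RF), the two hard, low-curvature targets.
#'
#' @param per_feature_values Named numeric vector keyed by feature.
#' @param exclude Features to drop (default `c("RE", "RF")`).
#' @return Mean over the remaining features.
#' @export
aggregate_features <- function(per_feature_values, exclude = c("RE", "RF")) {
  if (is.null(names(per_feature_values)))
    stop("per_feature_values must be named by feature")
  keep <- setdiff(names(per_feature_values), exclude)
  if (length(keep) == 0) stop("no features left after exclusion")
  mean(per_feature_values[keep])
}

#' Build a per-feature metric report row
#'
#' @param feature Feature name.
#' @param split Split name (`"train"` / `"test"` / fold id).
#' @param y,yhat Paired label/prediction vectors in samples.
#' @param sampling_rate Sampling rate in Hz.
#' @return One-row data.frame: `feature`, `split`, `r2`, `mae_samples`,
#'   `mae_ms`, `rmse_samples`, `rmse_ms`, `n`.
#' @export
metric_report <- function(feature, split, y, yhat, sampling_rate) {
  m <- mae(y, yhat); r <- rmse(y, yhat)
  data.frame(feature = feature, split = split, r2 = r2(y, yhat),
             mae_samples = m, mae_ms = samples_to_ms(m, sampling_rate),
             rmse_samples = r, rmse_ms = samples_to_ms(r, sampling_rate),
             n = length(y), stringsAsFactors = FALSE)
}
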