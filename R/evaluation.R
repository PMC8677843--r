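#' Prediction-error metrics
#'
#' `mae(y, yhat) = mean(|y - yhat|)` and
#' `rmse(y, yhat) = sqrt(mean((y - yhat)^2))`, in response units (rate
#' per 100,000 for mortality applications). By the power-mean
#' inequality `rmse >= mae` always.
#'
#' @param observed,predicted Numeric vectors of equal positive length.
#' @return A single number.
#' @export
mae <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  mean(abs(observed - predicted))
}

#' @rdname mae
#' @export
rmse <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

check_obs_pred <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted differ in length")
  if (length(observed) < 1) stop("empty vectors")
  invisible(NULL)
}

#' Observed-versus-predicted goodness of fit
#'
#' The R-squared of the simple linear regression of observed on
#' predicted values, i.e. the squared Pearson correlation; invariant to
#' affine transformations of the predictions.
#'
#' @param observed,predicted Numeric vectors (n >= 3).
#' @return R-squared in [0, 1].
#' @export
goodness_of_fit <- function(observed, predicted) {
  check_obs_pred(observed, predicted)
  if (length(observed) < 3) stop("need at least 3 observations")
  if (stats::sd(predicted) == 0)
    stop("r2 undefined: predictions are constant")
  stats::cor(observed, predicted)^2
}

#' Per-partition evaluation report
#'
#' @param observed,predicted Numeric vectors.
#' @return An `eval_report` list: `mae`, `rmse`, `r2`, `n`.
#' @export
eval_report <- function(observed, predicted) {
  structure(list(mae = mae(observed, predicted),
                 rmse = rmse(observed, predicted),
                 r2 = if (stats::sd(predicted) > 0 && length(observed) >= 3)
                        goodness_of_fit(observed, predicted) else NA_real_,
                 n = length(observed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d  MAE = %.3f  RMSE = %.3f  R2 = %.3f\n",
              x$n, x$mae, x$rmse, x$r2))
  invisible(x)
}

#' Bootstrap bias-variance decomposition
#'
#' Repeats the model-building process on `n_resamples` bootstrap draws
#' of the training pool and decomposes the prediction error at each test
#' point into squared bias `(E[fhat(x)] - f(x))^2` and variance
#' `E[fhat(x)^2] - E[fhat(x)]^2`, expectations taken over resamples.
#' When the true surface `f` is unknown (real data), bias is measured
#' against the observed test responses and therefore also absorbs the
#' irreducible noise; on synthetic data pass `truth` to separate the
#' two, and the mean squared test error then closes approximately as
#' `bias_sq + variance + noise_sd^2`.
#'
#' @param model_factory Function `f(data)` returning either a fitted
#'   object with a `predict(object, newdata)` method or a prediction
#'   function `g(newdata)`.
#' @param training_pool Data frame to resample (must contain the
#'   response used by `model_factory`).
#' @param test Data frame of evaluation points.
#' @param test_response Observed responses at the test points.
#' @param truth Optional true (noiseless) surface at the test points —
#'   numeric vector or function of `test`.
#' @param n_resamples Number of bootstrap model rebuilds (default 10,
#'   the conventional protocol).
#' @param seed Optional integer seed.
#' @return A `bias_variance_report` list with aggregate `bias_sq`,
#'   `variance`, `total_err`, `n_resamples`, the per-point vectors, and
#'   `bias_target` (`"truth"` or `"observed"`).
#' @export
bias_variance <- function(model_factory, training_pool, test, test_response,
                          truth = NULL, n_resamples = 10, seed = NULL) {
  if (n_resamples < 2) stop("n_resamples must be >= 2")
  n <- nrow(training_pool)
  f_target <- if (is.null(truth)) test_response
              else if (is.function(truth)) truth(test) else truth
  run <- function() {
    P <- matrix(NA_real_, n_resamples, nrow(test))
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- model_factory(training_pool[idx, , drop = FALSE])
      P[r, ] <- if (is.function(m)) m(test) else stats::predict(m, test)
    }
    P
  }
  P <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mbar <- colMeans(P)
  bias_sq <- (mbar - f_target)^2
  variance <- colMeans(P^2) - mbar^2
  total_err <- mean(sweep(P, 2, test_response)^2)
  structure(list(bias_sq = mean(bias_sq), variance = mean(variance),
                 total_err = total_err,
                 pointwise = data.frame(bias_sq = bias_sq,
                                        variance = variance),
                 n_resamples = n_resamples,
                 bias_target = if (is.null(truth)) "observed" else "truth"),
            class = "bias_variance_report")
}

#' @export
print.bias_variance_report <- function(x, ...) {
  cat(sprintf(
    "bias^2 = %.4f  variance = %.4f  total err = %.4f  (%d resamples, bias vs %s)\n",
    x$bias_sq, x$variance, x$total_err, x$n_resamples, x$bias_target))
  invisible(x)
}
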