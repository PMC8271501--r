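#' Fit the hybrid LSTM-TCN yield forecaster to a greenhouse series
#'
#' One-call interface over the full pipeline: leakage-aware min-max
#' normalisation, sliding-window supervision, 70/30 train/test split,
#' and mini-batch Adam training of the hybrid network on the MSE loss.
#'
#' @param series a `greenhouse_series` (see [read_greenhouse_csv()],
#'   [simulate_greenhouse()]).
#' @param window a [window_config()]; defaults to one week in, one week
#'   ahead.
#' @param model a [model_config()].
#' @param training a [training_config()].
#' @param ratio train fraction (default 0.7).
#' @param mode `"chronological"` (default) or `"random"` split.
#' @param normalize_on `"train"` (default, leakage-free) or `"all"`.
#' @return A `hybrid_fit` object with components `model` (trained
#'   `hybrid_model`), `record` (loss history), `split`, `params`
#'   (normalisation), `test_rmse` and `naive_rmse` (both g/m2).
#' @seealso [predict.hybrid_fit()], [evaluate_repeated()]
#' @export
#' @examples
#' \donttest{
#' gs <- simulate_greenhouse(n_days = 120, seed = 7)
#' fit <- fit_hybrid(gs, model = model_config(lstm_units = 8, tcn_filters = 8),
#'                   training = training_config(epochs = 5))
#' fit
#' }
fit_hybrid <- function(series, window = window_config(),
                       model = model_config(), training = training_config(),
                       ratio = 0.7, mode = c("chronological", "random"),
                       normalize_on = c("train", "all")) {
  mode <- match.arg(mode)
  normalize_on <- match.arg(normalize_on)
  split <- prepare_split(series, window, ratio = ratio, mode = mode,
                         seed = training$seed, normalize_on = normalize_on)
  record <- train_model(split, model, training)
  structure(list(model = record$model, record = record, split = split,
                 params = split$params, window = window,
                 test_rmse = test_rmse(record$model, split),
                 naive_rmse = naive_rmse(split),
                 call = match.call()),
            class = "hybrid_fit")
}

#' Predict from a fitted hybrid model
#'
#' With `newdata` a `greenhouse_series`, windows are cut with the fit's
#' configuration and normalisation before prediction; a
#' `windowed_samples` object is used as is. Without `newdata` the fit's
#' test windows are predicted.
#'
#' @param object a `hybrid_fit`.
#' @param newdata optional `greenhouse_series` or `windowed_samples`.
#' @param units `"gm2"` (default; denormalised accumulated yield) or
#'   `"normalized"`.
#' @param ... unused.
#' @return Numeric vector of predicted accumulated yield, one per window.
#' @export
predict.hybrid_fit <- function(object, newdata = NULL,
                               units = c("gm2", "normalized"), ...) {
  units <- match.arg(units)
  ws <- if (is.null(newdata)) {
    object$split$test
  } else if (inherits(newdata, "windowed_samples")) {
    newdata
  } else {
    make_windows(newdata, object$window, object$params)
  }
  pred <- predict_windows(object$model, ws)
  if (units == "gm2") denormalize_value(pred, object$params, "yield") else pred
}

#' @export
fitted.hybrid_fit <- function(object, ...) {
  denormalize_value(predict_windows(object$model, object$split$train),
                    object$params, "yield")
}

#' @export
residuals.hybrid_fit <- function(object, ...) {
  truth <- denormalize_value(object$split$test$target, object$params, "yield")
  truth - predict(object)
}

#' @export
coef.hybrid_fit <- function(object, ...) flatten_params(object$model$params)

#' @export
print.hybrid_fit <- function(x, ...) {
  cat("Hybrid LSTM-TCN yield forecaster\n")
  print(x$model)
  cat(sprintf("  split: %s, %d train / %d test windows\n", x$split$mode,
              n_samples(x$split$train), n_samples(x$split$test)))
  cat(sprintf("  test RMSE %.2f g/m2 (persistence baseline %.2f g/m2)\n",
              x$test_rmse, x$naive_rmse))
  invisible(x)
}

#' @export
summary.hybrid_fit <- function(object, ...) {
  h <- object$record$loss_history
  res <- residuals(object)
  out <- list(config = object$model$config,
              n_train = n_samples(object$split$train),
              n_test = n_samples(object$split$test),
              mode = object$split$mode,
              epochs = length(h), first_loss = h[1], final_loss = h[length(h)],
              test_rmse = object$test_rmse, naive_rmse = object$naive_rmse,
              resid_summary = summary(res))
  class(out) <- "summary.hybrid_fit"
  out
}

#' @export
print.summary.hybrid_fit <- function(x, ...) {
  cat("Hybrid LSTM-TCN yield forecaster: summary\n")
  print(x$config)
  cat(sprintf("  windows: %d train / %d test (%s split)\n", x$n_train,
              x$n_test, x$mode))
  cat(sprintf("  training MSE (normalised): %.4g -> %.4g over %d epochs\n",
              x$first_loss, x$final_loss, x$epochs))
  cat(sprintf("  test RMSE: %.2f g/m2; persistence baseline: %.2f g/m2\n",
              x$test_rmse, x$naive_rmse))
  cat("  test residuals (g/m2):\n")
  print(x$resid_summary)
  invisible(x)
}

#' Plot a fitted hybrid model
#'
#' Two base-graphics panels: the training loss curve and predicted vs
#' observed accumulated yield on the test windows.
#'
#' @param x a `hybrid_fit`.
#' @param ... passed to [plot.default()].
#' @return `x`, invisibly.
#' @export
plot.hybrid_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::plot(x$record$loss_history, type = "l", xlab = "epoch",
                 ylab = "training MSE (normalised)", main = "Convergence", ...)
  truth <- denormalize_value(x$split$test$target, x$params, "yield")
  pred <- predict(x)
  graphics::plot(x$split$test$anchor_day, truth, type = "l",
                 xlab = "anchor day", ylab = "accumulated yield (g/m2)",
                 main = "Test predictions", ...)
  graphics::lines(x$split$test$anchor_day, pred, lty = 2)
  graphics::legend("topleft", legend = c("observed", "predicted"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}
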