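# Training: mini-batch Adam on the mean-squared-error loss over the
# normalised training targets. Evaluation: RMSE on the test set, reported
# in g/m2 by rescaling with the fitted yield extrema (RMSE is invariant
# to the additive part of the affine denormalisation, so
# RMSE_gm2 = RMSE_normalised * (yield_max - yield_min)).

#' Mean squared error
#'
#' @param predictions,truths equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse_loss <- function(predictions, truths) {
  if (length(predictions) != length(truths) || length(truths) < 1L)
    stop("predictions and truths must be equal-length, non-empty", call. = FALSE)
  mean((predictions - truths)^2)
}

#' Root mean squared error
#'
#' @inheritParams mse_loss
#' @return Square root of [mse_loss()].
#' @export
rmse <- function(predictions, truths) sqrt(mse_loss(predictions, truths))

#' Training configuration
#'
#' Adam is the (only) optimiser; 0.001 is the default learning rate, the
#' fastest-converging of the rates studied for this architecture.
#'
#' @param learning_rate Adam step size, default 0.001.
#' @param epochs full passes over the training set, default 100.
#' @param batch_size mini-batch size, default 16.
#' @param seed integer seed controlling parameter initialisation, batch
#'   shuffling and dropout.
#' @return A `training_config` object.
#' @export
training_config <- function(learning_rate = 0.001, epochs = 100L,
                            batch_size = 16L, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 optimizer = "adam"),
            class = "training_config")
}

#' Train a model on a prepared split
#'
#' Runs mini-batch Adam for the configured number of epochs, recording
#' the full-training-set MSE (evaluation mode, normalised scale) after
#' every epoch. Fully reproducible: the same split, configurations and
#' seed give a bit-identical model and loss history.
#'
#' @param split a `dataset_split` (see [prepare_split()]).
#' @param model_cfg a [model_config()].
#' @param train_cfg a [training_config()].
#' @return A `train_record`: `model` (trained `hybrid_model`),
#'   `loss_history` (length `epochs`), `seed`, and the configurations.
#' @export
train_model <- function(split, model_cfg = model_config(),
                        train_cfg = training_config()) {
  stopifnot(inherits(split, "dataset_split"))
  ws <- split$train
  n <- n_samples(ws)
  if (n < 1L) stop("training set is empty", call. = FALSE)
  X <- ws$inputs; y <- ws$target
  N <- dim(X)[2]; D <- dim(X)[3]
  seeds <- derive_seeds(train_cfg$seed, 2L)
  model <- init_model(model_cfg, window_length = N, n_factors = D,
                      seed = seeds[1])
  flat <- flatten_params(model$params)
  m <- numeric(length(flat)); v <- numeric(length(flat))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_history <- numeric(train_cfg$epochs)
  drop_on <- use_tcn(model_cfg) && model_cfg$dropout_rate > 0
  with_seed(seeds[2], {
    for (epoch in seq_len(train_cfg$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = train_cfg$batch_size)) {
        idx <- ord[start:min(start + train_cfg$batch_size - 1L, n)]
        Xb <- X[idx, , , drop = FALSE]
        masks <- if (drop_on)
          lapply(model$params$tcn, function(p)
            block_dropout_masks(list(layers = p$layers), model_cfg$dropout_rate))
        lg <- model_loss_grad(model, Xb, y[idx], training = TRUE, masks = masks)
        if (!is.finite(lg$loss))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        g <- flatten_params(lg$grads)
        step <- step + 1L
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mhat <- m / (1 - beta1^step)
        vhat <- v / (1 - beta2^step)
        flat <- flat - train_cfg$learning_rate * mhat / (sqrt(vhat) + eps)
        model$params <- unflatten_params(flat, model$params)
      }
      loss_history[epoch] <- mse_loss(hybrid_forward(model, X)$pred, y)
      if (!is.finite(loss_history[epoch]))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             call. = FALSE)
    }
  })
  structure(list(model = model, loss_history = loss_history,
                 seed = train_cfg$seed, model_cfg = model_cfg,
                 train_cfg = train_cfg),
            class = "train_record")
}

# Normalised-scale predictions for every sample of a windowed set.
predict_windows <- function(model, ws) {
  hybrid_forward(model, ws$inputs)$pred
}

# Test RMSE in g/m2 for a trained model on a split with fitted params.
test_rmse <- function(model, split, params = split$params) {
  yr <- norm_factor(params, "yield")
  span <- yr[["max"]] - yr[["min"]]
  rmse(predict_windows(model, split$test), split$test$target) * span
}

# RMSE (g/m2) of the persistence baseline: predict the last observed
# accumulated yield of the input window.
naive_rmse <- function(split, params = split$params) {
  yr <- norm_factor(params, "yield")
  N <- split$test$window$window_length
  pred <- split$test$inputs[, N, "yield"]
  rmse(pred, split$test$target) * (yr[["max"]] - yr[["min"]])
}

#' Repeated train/test evaluation
#'
#' Repeats training `n_runs` times with distinct derived seeds and
#' reports the per-run test RMSE (g/m2), their mean and their population
#' standard deviation. By default the chronological split is held fixed
#' so that run-to-run variation is attributable to parameter
#' initialisation alone; `reseed_split = TRUE` additionally re-randomises
#' a random-mode split each run.
#'
#' @param series a `greenhouse_series`.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [training_config()]; its seed is the master seed.
#' @param n_runs repetitions, default 5.
#' @param window a [window_config()].
#' @param ratio,mode,normalize_on passed to [prepare_split()].
#' @param reseed_split draw a new random split per run (random mode only).
#' @param split_seed seed for the (random-mode) split draw; defaults to
#'   the training master seed. Experiment runners pass their master seed
#'   here so every cell of a table shares one split.
#' @param exclude optional factor name to drop from the input channels
#'   (factor ablation; the target stays the accumulated yield).
#' @return An `eval_report`: `rmse` (per run), `mean`, `sd` (population),
#'   `n_runs`, `mode`, `excluded`, `split_checksum`.
#' @export
evaluate_repeated <- function(series, model_cfg = model_config(),
                              train_cfg = training_config(), n_runs = 5L,
                              window = window_config(), ratio = 0.7,
                              mode = "chronological",
                              normalize_on = "train",
                              reseed_split = FALSE, split_seed = NULL,
                              exclude = NULL) {
  if (n_runs < 1L) stop("n_runs must be >= 1", call. = FALSE)
  seeds <- derive_seeds(train_cfg$seed, n_runs)
  if (is.null(split_seed)) split_seed <- train_cfg$seed
  base_split <- prepare_split(series, window, ratio = ratio, mode = mode,
                              seed = split_seed, normalize_on = normalize_on)
  vals <- vapply(seq_len(n_runs), function(r) {
    split <- if (reseed_split && mode == "random")
      prepare_split(series, window, ratio = ratio, mode = mode,
                    seed = seeds[r], normalize_on = normalize_on)
    else base_split
    if (!is.null(exclude)) {
      split$train <- drop_factor(split$train, exclude)
      split$test <- drop_factor(split$test, exclude)
    }
    cfg_r <- train_cfg; cfg_r$seed <- seeds[r]
    rec <- train_model(split, model_cfg, cfg_r)
    test_rmse(rec$model, split, base_split$params)
  }, numeric(1))
  eval_report(vals, mode = mode, excluded = exclude,
              split_checksum = split_checksum(base_split))
}

# Population-sd convention: the handful of repeated runs is treated as
# the full set of runs performed, not a sample from a larger population.
eval_report <- function(rmse_values, mode = NA_character_, excluded = NULL,
                        split_checksum = NA_character_) {
  m <- mean(rmse_values)
  s <- sqrt(mean((rmse_values - m)^2))
  structure(list(rmse = rmse_values, mean = m, sd = s,
                 n_runs = length(rmse_values), mode = mode,
                 excluded = if (is.null(excluded)) NA_character_ else excluded,
                 split_checksum = split_checksum),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> RMSE %.2f +/- %.2f g/m2 over %d run(s)",
              x$mean, x$sd, x$n_runs))
  if (!is.na(x$mode)) cat(sprintf(" [%s split]", x$mode))
  if (!is.na(x$excluded)) cat(sprintf(" [excluding %s]", x$excluded))
  cat("\n")
  invisible(x)
}

#' @export
print.train_record <- function(x, ...) {
  h <- x$loss_history
  cat(sprintf("<train_record> %d epochs, train MSE %.3g -> %.3g (seed %d)\n",
              length(h), h[1], h[length(h)], x$seed))
  invisible(x)
}

# JSON serialisation of reports and records ----------------------------

#' Write an evaluation report or training record as JSON
#'
#' @param x an `eval_report` or `train_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  out <- if (inherits(x, "eval_report")) {
    unclass(x)
  } else if (inherits(x, "train_record")) {
    list(loss_history = x$loss_history, seed = x$seed,
         model_cfg = unclass(x$model_cfg), train_cfg = unclass(x$train_cfg))
  } else stop("cannot serialise object of class ", class(x)[1], call. = FALSE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a loss curve as CSV (`epoch,loss`)
#'
#' @param record a `train_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loss_csv <- function(record, path) {
  utils::write.csv(data.frame(epoch = seq_along(record$loss_history),
                              loss = record$loss_history),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
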