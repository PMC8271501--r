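# Sliding-window supervision: each sample pairs an N-day block of the six
# normalised factors with the normalised accumulated yield H days after the
# block ends. With step 1 this is the standard one-week-ahead setup
# (N = 7 days in, yield at day t + 7 out).

#' Sliding-window configuration
#'
#' @param window_length N, days of input context (default 7: one week).
#' @param horizon H, days ahead of the window end at which the target is
#'   read (default 7).
#' @param step stride of the window start between consecutive samples
#'   (default 1).
#' @return A `window_config` object.
#' @export
window_config <- function(window_length = 7L, horizon = 7L, step = 1L) {
  cfg <- list(window_length = as.integer(window_length),
              horizon = as.integer(horizon), step = as.integer(step))
  if (cfg$window_length < 1L || cfg$horizon < 1L || cfg$step < 1L)
    stop("window_length, horizon and step must all be >= 1", call. = FALSE)
  structure(cfg, class = "window_config")
}

#' Cut a series into supervised sliding-window samples
#'
#' Normalises the series with `params`, then slides a window of
#' `window_length` days with the configured step. Sample k (0-based)
#' covers series rows `k*step .. k*step + N - 1` and its target is the
#' normalised yield `horizon` days after the last input day. The number
#' of samples is exactly `floor((L - N - H) / step) + 1`.
#'
#' @param series a `greenhouse_series` of length L >= N + H.
#' @param cfg a [window_config()].
#' @param params a [fit_normalization()] result.
#' @return A `windowed_samples` object: `inputs` (n x N x 6 array),
#'   `target` (length n), `anchor_day` (day of the last input row of each
#'   sample), plus the configuration used.
#' @export
#' @examples
#' gs <- simulate_greenhouse(n_days = 60, seed = 1)
#' ws <- make_windows(gs, window_config(), fit_normalization(gs))
#' length(ws$target)
make_windows <- function(series, cfg = window_config(), params) {
  validate_series(series)
  stopifnot(inherits(cfg, "window_config"))
  L <- nrow(series)
  N <- cfg$window_length; H <- cfg$horizon; s <- cfg$step
  if (L < N + H)
    stop("series too short: ", L, " days but window_length + horizon = ",
         N + H, call. = FALSE)
  n <- (L - N - H) %/% s + 1L
  norm <- normalize_matrix(series, params)
  yidx <- match("yield", colnames(norm))
  inputs <- array(NA_real_, dim = c(n, N, length(FACTOR_NAMES)),
                  dimnames = list(NULL, NULL, FACTOR_NAMES))
  target <- numeric(n)
  anchor <- integer(n)
  for (k in seq_len(n)) {
    start <- (k - 1L) * s + 1L
    rows <- start:(start + N - 1L)
    inputs[k, , ] <- norm[rows, ]
    target[k] <- norm[rows[N] + H, yidx]
    anchor[k] <- series$day[rows[N]]
  }
  structure(list(inputs = inputs, target = target, anchor_day = anchor,
                 window = cfg, factors = FACTOR_NAMES),
            class = "windowed_samples")
}

n_samples <- function(ws) length(ws$target)

subset_windows <- function(ws, idx) {
  structure(list(inputs = ws$inputs[idx, , , drop = FALSE],
                 target = ws$target[idx], anchor_day = ws$anchor_day[idx],
                 window = ws$window, factors = ws$factors),
            class = "windowed_samples")
}

# Drop one input channel (factor ablation); targets are untouched.
drop_factor <- function(ws, factor) {
  keep <- setdiff(ws$factors, factor)
  if (length(keep) == length(ws$factors))
    stop("unknown factor '", factor, "'", call. = FALSE)
  structure(list(inputs = ws$inputs[, , keep, drop = FALSE],
                 target = ws$target, anchor_day = ws$anchor_day,
                 window = ws$window, factors = keep),
            class = "windowed_samples")
}

#' Split windowed samples into train and test sets
#'
#' The train size is `round(ratio * n)`. Chronological mode (the default)
#' sends the earliest anchors to the train set, so every train anchor day
#' precedes every test anchor day; random mode draws the train set
#' uniformly, reproducibly under `seed`. Random splitting leaks
#' overlapping days across the boundary and is kept only for fidelity
#' experiments; reports flag the mode used.
#'
#' @param samples a `windowed_samples` object.
#' @param ratio train fraction, strictly between 0 and 1 (default 0.7).
#' @param mode `"chronological"` or `"random"`.
#' @param seed integer seed used in random mode.
#' @return A `dataset_split`: `train` and `test` (both `windowed_samples`),
#'   `ratio`, `mode`.
#' @export
split_samples <- function(samples, ratio = 0.7, mode = c("chronological", "random"),
                          seed = 1L) {
  mode <- match.arg(mode)
  n <- n_samples(samples)
  if (n == 0L) stop("no samples to split", call. = FALSE)
  if (!(ratio > 0 && ratio < 1)) stop("ratio must lie in (0, 1)", call. = FALSE)
  n_train <- round(ratio * n)
  if (n_train < 1L || n_train >= n)
    stop("split leaves an empty train or test set (n = ", n, ", ratio = ",
         ratio, ")", call. = FALSE)
  ord <- order(samples$anchor_day)
  if (mode == "chronological") {
    train_idx <- ord[seq_len(n_train)]
    test_idx <- ord[(n_train + 1L):n]
  } else {
    train_idx <- sort(with_seed(as.integer(seed), sample.int(n, n_train)))
    test_idx <- setdiff(seq_len(n), train_idx)
  }
  structure(list(train = subset_windows(samples, train_idx),
                 test = subset_windows(samples, test_idx),
                 ratio = ratio, mode = mode),
            class = "dataset_split")
}

#' Normalise, window and split a series in one leakage-aware step
#'
#' Fits the min-max scaling on the training period only (the default):
#' for a chronological split the extrema are taken over the days a train
#' sample can touch (inputs and targets), and the fixed scaling is then
#' applied to the test windows, which may therefore fall slightly outside
#' \[0, 1\] and are deliberately not clipped. With `normalize_on = "all"`
#' (always the case in random mode, where a temporal boundary does not
#' exist) the extrema come from the full series.
#'
#' @inheritParams split_samples
#' @param series a `greenhouse_series`.
#' @param cfg a [window_config()].
#' @param normalize_on `"train"` (default) or `"all"`.
#' @return A `dataset_split` with the fitted `norm_params` attached as
#'   `$params`.
#' @export
prepare_split <- function(series, cfg = window_config(), ratio = 0.7,
                          mode = c("chronological", "random"), seed = 1L,
                          normalize_on = c("train", "all")) {
  mode <- match.arg(mode)
  normalize_on <- match.arg(normalize_on)
  validate_series(series)
  L <- nrow(series)
  N <- cfg$window_length; H <- cfg$horizon; s <- cfg$step
  if (L < N + H)
    stop("series too short: ", L, " days but window_length + horizon = ",
         N + H, call. = FALSE)
  n <- (L - N - H) %/% s + 1L
  if (mode == "chronological" && normalize_on == "train") {
    n_train <- round(ratio * n)
    # last day a train sample touches: target of the n_train-th window
    last_train_row <- (n_train - 1L) * s + N + H
    params <- fit_normalization(series, days = series$day[seq_len(last_train_row)])
  } else {
    params <- fit_normalization(series)
  }
  split <- split_samples(make_windows(series, cfg, params), ratio = ratio,
                         mode = mode, seed = seed)
  split$params <- params
  split
}

#' @export
print.windowed_samples <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("<windowed_samples> %d samples, window %d x %d factors, horizon %d\n",
              d[1], d[2], d[3], x$window$horizon))
  invisible(x)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train / %d test (%s, ratio %.2f)\n",
              n_samples(x$train), n_samples(x$test), x$mode, x$ratio))
  invisible(x)
}
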