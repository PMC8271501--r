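# The hybrid architecture: LSTM layer(s) -> TCN residual block(s) ->
# flatten -> fully connected head with one output and ReLU activation.
# The LSTM passes its FULL hidden-state sequence (N x units) to the TCN,
# and the head consumes the whole flattened N x filters map of the last
# block, so predictions use features from every time step.
#
# `variant` selects ablated architectures for the comparison study:
# "lstm" skips the TCN (hidden states go straight to the head), "tcn"
# convolves the raw normalised window directly.

#' Architecture configuration
#'
#' Defaults follow the grid-search optimum for this architecture family:
#' 200 LSTM units, 250 filters, one LSTM layer and one residual block,
#' kernel size 2 with dilation 1 in each of the block's three layers.
#' `dilations = "doubling"` selects the conventional 1, 2, 4 schedule
#' instead.
#'
#' @param lstm_units LSTM unit count (LN), default 200.
#' @param lstm_layers stacked LSTM layers, default 1.
#' @param tcn_filters convolutional filter count (FN), default 250.
#' @param tcn_blocks residual block count, default 1.
#' @param dilations per-layer dilation within a block: a length-3 integer
#'   vector, or `"doubling"` for `c(1, 2, 4)`; default `c(1, 1, 1)`.
#' @param dropout_rate fraction of dilated-layer weights dropped during
#'   training, default 0.1.
#' @param weight_norm apply weight normalisation to dilated layers,
#'   default TRUE.
#' @param variant `"hybrid"` (default), `"lstm"` (no TCN) or `"tcn"`
#'   (no LSTM).
#' @return A `model_config` object (kernel size is fixed at 2).
#' @export
model_config <- function(lstm_units = 200L, lstm_layers = 1L,
                         tcn_filters = 250L, tcn_blocks = 1L,
                         dilations = c(1L, 1L, 1L), dropout_rate = 0.1,
                         weight_norm = TRUE,
                         variant = c("hybrid", "lstm", "tcn")) {
  variant <- match.arg(variant)
  if (identical(dilations, "doubling")) dilations <- c(1L, 2L, 4L)
  dilations <- as.integer(dilations)
  if (length(dilations) != 3L || any(dilations < 1L))
    stop("dilations must be 3 positive integers (one per layer)", call. = FALSE)
  cfg <- list(lstm_units = as.integer(lstm_units),
              lstm_layers = as.integer(lstm_layers),
              tcn_filters = as.integer(tcn_filters),
              tcn_blocks = as.integer(tcn_blocks),
              kernel_size = 2L, dilations = dilations,
              dropout_rate = dropout_rate, weight_norm = weight_norm,
              variant = variant)
  if (cfg$lstm_units < 1L || cfg$tcn_filters < 1L ||
      cfg$lstm_layers < 1L || cfg$tcn_blocks < 1L)
    stop("unit, filter, layer and block counts must all be >= 1", call. = FALSE)
  if (!(dropout_rate >= 0 && dropout_rate < 1))
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "model_config")
}

use_lstm <- function(cfg) cfg$variant %in% c("hybrid", "lstm")
use_tcn <- function(cfg) cfg$variant %in% c("hybrid", "tcn")

#' Initialise a hybrid model
#'
#' Glorot-uniform weights, zero biases, drawn reproducibly from `seed`.
#'
#' @param config a [model_config()].
#' @param window_length N, input days per sample.
#' @param n_factors input channels (6, or 5 under factor ablation).
#' @param seed integer seed for the parameter draw.
#' @return A `hybrid_model`: `config`, `window_length`, `n_factors` and
#'   the parameter tree `params` (`lstm`, `tcn`, `head`).
#' @export
init_model <- function(config = model_config(), window_length = 7L,
                       n_factors = 6L, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  N <- as.integer(window_length); D <- as.integer(n_factors)
  with_seed(seed, {
    params <- list()
    d_in <- D
    if (use_lstm(config)) {
      params$lstm <- lapply(seq_len(config$lstm_layers), function(l) {
        p <- lstm_params(if (l == 1L) D else config$lstm_units, config$lstm_units)
        unclass(p)
      })
      d_in <- config$lstm_units
    }
    if (use_tcn(config)) {
      params$tcn <- lapply(seq_len(config$tcn_blocks), function(j) {
        p <- tcn_block_params(if (j == 1L) d_in else config$tcn_filters,
                              config$tcn_filters, config$dilations,
                              config$weight_norm)
        attr(p, "dilations") <- NULL
        unclass(p)
      })
      d_in <- config$tcn_filters
    }
    # head bias starts mid-range: a zero start can leave the ReLU output
    # dead (all pre-activations negative => zero gradient forever)
    params$head <- list(w = glorot(N * d_in, 1L), b = 0.5)
    structure(list(config = config, window_length = N, n_factors = D,
                   params = params),
              class = "hybrid_model")
  })
}

# ---- parameter tree <-> flat vector ----------------------------------

flatten_params <- function(params) as.numeric(unlist(params, use.names = FALSE))

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  fill <- function(x) {
    if (is.list(x)) return(lapply(x, fill))
    n <- length(x)
    out <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (is.matrix(x)) dim(out) <- dim(x)
    out
  }
  out <- fill(params_strip(skeleton))
  if (pos != length(flat))
    stop("flat parameter vector has wrong length", call. = FALSE)
  out
}

params_strip <- function(x) {
  if (is.list(x)) {
    attributes(x) <- list(names = names(x))
    lapply(x, params_strip)
  } else x
}

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

add_trees <- function(a, b) {
  if (is.list(a)) Map(add_trees, a, b) else a + b
}

# ---- forward / backward ----------------------------------------------

# X: B x N x D array. Returns prediction vector plus caches for backprop.
hybrid_forward <- function(model, X, training = FALSE, masks = NULL,
                           keep_cache = FALSE) {
  cfg <- model$config
  B <- dim(X)[1]; N <- dim(X)[2]; D <- dim(X)[3]
  if (N != model$window_length || D != model$n_factors)
    stop("input is ", N, " x ", D, " but model expects ",
         model$window_length, " x ", model$n_factors, call. = FALSE)
  rate <- if (training) cfg$dropout_rate else 0
  lstm_fwd <- NULL
  if (use_lstm(cfg)) {
    lstm_fwd <- vector("list", cfg$lstm_layers)
    Xin <- X
    for (l in seq_len(cfg$lstm_layers)) {
      lstm_fwd[[l]] <- lstm_layer_forward(Xin, model$params$lstm[[l]],
                                          keep_cache = keep_cache)
      if (l < cfg$lstm_layers)
        Xin <- stack_to_array(lstm_fwd[[l]]$H_stack, B, N)
    }
    S <- lstm_fwd[[cfg$lstm_layers]]$H_stack
  } else {
    S <- array_to_stack(X)
  }
  tcn_fwd <- NULL
  if (use_tcn(cfg)) {
    tcn_fwd <- vector("list", cfg$tcn_blocks)
    for (j in seq_len(cfg$tcn_blocks)) {
      tcn_fwd[[j]] <- block_forward(S, model$params$tcn[[j]], cfg$dilations,
                                    B, N, masks[[j]], rate,
                                    keep_cache = keep_cache)
      S <- tcn_fwd[[j]]$out
    }
  }
  V <- stack_to_flat(S, B, N)
  zhat <- as.numeric(V %*% model$params$head$w) + model$params$head$b
  pred <- pmax(zhat, 0)
  list(pred = pred, zhat = zhat, V = V, lstm = lstm_fwd, tcn = tcn_fwd,
       B = B, N = N)
}

# dpred: gradient of the loss wrt each prediction. Returns the gradient
# tree (same shape as model$params).
hybrid_backward <- function(model, fwd, dpred, masks = NULL, training = FALSE) {
  cfg <- model$config
  B <- fwd$B; N <- fwd$N
  rate <- if (training) cfg$dropout_rate else 0
  gr <- list()
  dz <- dpred * (fwd$zhat > 0)
  gr$head <- list(w = t(fwd$V) %*% dz, b = sum(dz))
  dV <- matrix(dz, ncol = 1L) %*% t(model$params$head$w)
  dS <- flat_to_stack(dV, B, N)
  if (use_tcn(cfg)) {
    gr$tcn <- vector("list", cfg$tcn_blocks)
    for (j in rev(seq_len(cfg$tcn_blocks))) {
      bk <- block_backward(fwd$tcn[[j]], model$params$tcn[[j]], cfg$dilations,
                           B, N, dS, masks[[j]], rate)
      gr$tcn[[j]] <- bk$grads
      dS <- bk$dS0
    }
  }
  if (use_lstm(cfg)) {
    gr$lstm <- vector("list", cfg$lstm_layers)
    for (l in rev(seq_len(cfg$lstm_layers))) {
      lb <- lstm_layer_backward(fwd$lstm[[l]], model$params$lstm[[l]], dS)
      gr$lstm[[l]] <- lb$grads
      if (l > 1L) dS <- array_to_stack(lb$dX)
    }
  }
  gr[names(model$params)]
}

# B x N x D array -> stacked (B*N) x D matrix, rows sample-major.
array_to_stack <- function(X) {
  d <- dim(X)
  matrix(aperm(X, c(2L, 1L, 3L)), d[1] * d[2], d[3])
}

stack_to_array <- function(S, B, N) {
  aperm(array(S, c(N, B, ncol(S))), c(2L, 1L, 3L))
}

# Flatten each sample's N x F map column-major (channel-major): sample b's
# feature vector is c(S[time 1..N, filter 1], S[time 1..N, filter 2], ...).
stack_to_flat <- function(S, B, N) {
  Fc <- ncol(S)
  t(matrix(aperm(array(S, c(N, B, Fc)), c(1L, 3L, 2L)), N * Fc, B))
}

flat_to_stack <- function(V, B, N) {
  Fc <- ncol(V) / N
  matrix(aperm(array(t(V), c(N, Fc, B)), c(1L, 3L, 2L)), N * B, Fc)
}

#' Model forward pass
#'
#' Predicts the normalised yield for one window (N x factors matrix) or a
#' batch (B x N x factors array). Output is non-negative by the ReLU
#' head. In training mode weight dropout is sampled from the current RNG;
#' in evaluation mode the pass is deterministic.
#'
#' @param x input window(s).
#' @param model a `hybrid_model` from [init_model()] or a fit's `$model`.
#' @param training logical, enables dropout.
#' @return Numeric vector of predictions (length B).
#' @export
model_forward <- function(x, model, training = FALSE) {
  if (is.matrix(x)) x <- array(x, c(1L, nrow(x), ncol(x)))
  cfg <- model$config
  masks <- if (training && use_tcn(cfg) && cfg$dropout_rate > 0)
    lapply(model$params$tcn, function(p)
      block_dropout_masks(list(layers = p$layers), cfg$dropout_rate))
  hybrid_forward(model, x, training = training, masks = masks)$pred
}

# Mean-squared-error loss and its gradient tree for one batch.
model_loss_grad <- function(model, X, y, training = FALSE, masks = NULL) {
  fwd <- hybrid_forward(model, X, training = training, masks = masks,
                        keep_cache = TRUE)
  err <- fwd$pred - y
  loss <- mean(err^2)
  dpred <- 2 * err / length(y)
  grads <- hybrid_backward(model, fwd, dpred, masks = masks,
                           training = training)
  list(loss = loss, grads = grads, pred = fwd$pred)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON checkpoint (format version 1): architecture
#' configuration, input geometry and the flattened parameter vector at
#' full precision. `load_model()` restores a bit-identical model.
#'
#' @param model a `hybrid_model`.
#' @param path checkpoint path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored `hybrid_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hybrid_model"))
  cfg <- unclass(model$config)
  # parameters stored as %.17g strings: decimal shortest-exact round trip
  out <- list(format = "yieldnet-checkpoint", version = 1L, config = cfg,
              window_length = model$window_length,
              n_factors = model$n_factors,
              params = sprintf("%.17g", flatten_params(model$params)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "yieldnet-checkpoint"))
    stop("not a yieldnet checkpoint: ", path, call. = FALSE)
  cfg <- do.call(model_config, raw$config[setdiff(names(raw$config), "kernel_size")])
  model <- init_model(cfg, raw$window_length, raw$n_factors, seed = 0L)
  model$params <- unflatten_params(as.numeric(raw$params), model$params)
  model
}

#' @export
print.hybrid_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<hybrid_model> variant '%s': ", cfg$variant))
  parts <- c(
    if (use_lstm(cfg)) sprintf("%d LSTM layer(s) x %d units", cfg$lstm_layers, cfg$lstm_units),
    if (use_tcn(cfg)) sprintf("%d TCN block(s) x %d filters (dilations %s)",
                              cfg$tcn_blocks, cfg$tcn_filters,
                              paste(cfg$dilations, collapse = ",")),
    "ReLU head")
  cat(paste(parts, collapse = " -> "), "\n")
  cat(sprintf("  window %d x %d factors, %d parameters\n", x$window_length,
              x$n_factors, length(flatten_params(x$params))))
  invisible(x)
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s: LN=%d x %d layer(s), FN=%d x %d block(s), kernel 2, dilations %s, dropout %.2f, weight_norm %s\n",
              x$variant, x$lstm_units, x$lstm_layers, x$tcn_filters,
              x$tcn_blocks, paste(x$dilations, collapse = ","),
              x$dropout_rate, x$weight_norm))
  invisible(x)
}
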