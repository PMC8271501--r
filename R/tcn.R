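# Temporal convolutional network pieces. A dilated causal convolution
# with kernel size 2 computes, per output channel,
#
#   S_t = f(w1 . S_{t-s} + w2 . S_t + b)
#
# where s is the dilation: the two taps read the current step and the
# step s back, never the future. Left zero-padding of s positions keeps
# the output length equal to the input length. A residual block stacks
# three such layers (ReLU activations) and adds a 1x1-convolution
# projection of the block input so channel counts match.
#
# Weight normalisation reparameterises each filter's kernel as
# w = g * v / ||v|| (magnitude g, direction v); it applies to the dilated
# layers only. Dropout, when training, removes a fraction of the dilated
# layers' *weights* (not activations), with inverted scaling 1/(1-rate).

#' Initialise one dilated convolutional layer
#'
#' @param in_channels input channel count.
#' @param filters output channel (filter) count.
#' @param weight_norm store the kernel as direction + magnitude
#'   (`v1`, `v2`, `g`) instead of plain `w1`, `w2`. The magnitude is
#'   initialised to the direction's norm, so the initial effective
#'   weights equal the raw Glorot draw.
#' @return A `conv_layer_params` list with bias `b` (length filters).
#' @export
conv_layer_params <- function(in_channels, filters, weight_norm = TRUE) {
  C <- as.integer(in_channels); Fn <- as.integer(filters)
  stopifnot(C >= 1L, Fn >= 1L)
  w1 <- glorot(C, Fn); w2 <- glorot(C, Fn)
  p <- if (weight_norm) {
    list(v1 = w1, v2 = w2, g = sqrt(colSums(w1^2) + colSums(w2^2)),
         b = numeric(Fn))
  } else {
    list(w1 = w1, w2 = w2, b = numeric(Fn))
  }
  structure(p, class = "conv_layer_params")
}

layer_has_wnorm <- function(p) !is.null(p$g)

# Effective kernel of a layer after weight normalisation and (optionally)
# a weight-dropout mask. mask is list(m1, m2) of 0/1 matrices; rate is the
# dropout fraction used for inverted scaling.
effective_weights <- function(p, mask = NULL, rate = 0) {
  if (layer_has_wnorm(p)) {
    nrm <- sqrt(colSums(p$v1^2) + colSums(p$v2^2))
    scl <- p$g / nrm
    W1 <- sweep(p$v1, 2L, scl, "*"); W2 <- sweep(p$v2, 2L, scl, "*")
  } else {
    W1 <- p$w1; W2 <- p$w2
  }
  if (!is.null(mask)) {
    keep <- 1 / (1 - rate)
    W1 <- W1 * mask$m1 * keep
    W2 <- W2 * mask$m2 * keep
  }
  list(W1 = W1, W2 = W2)
}

# Backward through dropout + weight normalisation: maps gradients wrt the
# effective kernel onto the stored parameterisation.
effective_weights_backward <- function(p, dW1e, dW2e, mask = NULL, rate = 0) {
  if (!is.null(mask)) {
    keep <- 1 / (1 - rate)
    dW1e <- dW1e * mask$m1 * keep
    dW2e <- dW2e * mask$m2 * keep
  }
  if (layer_has_wnorm(p)) {
    nrm <- sqrt(colSums(p$v1^2) + colSums(p$v2^2))
    dg <- (colSums(dW1e * p$v1) + colSums(dW2e * p$v2)) / nrm
    scl <- p$g / nrm
    corr <- p$g * dg / nrm^2
    dv1 <- sweep(dW1e, 2L, scl, "*") - sweep(p$v1, 2L, corr, "*")
    dv2 <- sweep(dW2e, 2L, scl, "*") - sweep(p$v2, 2L, corr, "*")
    list(v1 = dv1, v2 = dv2, g = dg)
  } else {
    list(w1 = dW1e, w2 = dW2e)
  }
}

# Causal shift by s steps inside each of B stacked length-N sequences
# (rows sample-major, (b-1)*N + t); vacated positions are zero.
shift_stack <- function(S, B, N, s) {
  out <- S * 0
  if (s < N) {
    t_pos <- rep(seq_len(N), B)
    valid <- t_pos > s
    out[valid, ] <- S[which(valid) - s, , drop = FALSE]
  }
  out
}

# Adjoint of shift_stack: scatter dZ rows back to the positions they read.
unshift_stack <- function(dZ, B, N, s) {
  out <- dZ * 0
  if (s < N) {
    t_pos <- rep(seq_len(N), B)
    valid <- t_pos > s
    out[which(valid) - s, ] <- dZ[valid, , drop = FALSE]
  }
  out
}

#' Dilated causal convolution (kernel size 2)
#'
#' Computes `f(w1 . S_{t-s} + w2 . S_t + b)` per output channel over a
#' single sequence, with causal left zero-padding so the output has the
#' input's length and output `t` depends only on inputs at or before `t`.
#'
#' @param x a T x C input matrix (rows are time steps).
#' @param w1,w2 C x F kernel matrices (tap at `t - s`, tap at `t`).
#' @param b bias, length F.
#' @param dilation s >= 1, spacing between the two taps.
#' @param activation `"relu"` (default) or `"identity"`.
#' @return A T x F matrix.
#' @export
#' @examples
#' dilated_causal_conv(matrix(1:3), w1 = matrix(1), w2 = matrix(1), b = 0)
dilated_causal_conv <- function(x, w1, w2, b, dilation = 1L,
                                activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  x <- as.matrix(x); w1 <- as.matrix(w1); w2 <- as.matrix(w2)
  s <- as.integer(dilation)
  if (s < 1L) stop("dilation must be >= 1", call. = FALSE)
  if (nrow(w1) != ncol(x) || nrow(w2) != ncol(x) ||
      ncol(w1) != ncol(w2) || length(b) != ncol(w1))
    stop("kernel shapes inconsistent with ", ncol(x), " input channels",
         call. = FALSE)
  Z <- shift_stack(x, 1L, nrow(x), s) %*% w1 + x %*% w2 +
    rep_row(b, nrow(x))
  if (activation == "relu") relu(Z) else Z
}

#' Initialise one residual block
#'
#' Three dilated causal convolutional layers (the first maps
#' `in_channels -> filters`, the rest `filters -> filters`) plus a 1x1
#' skip convolution projecting the block input to `filters` channels.
#'
#' @param in_channels channels of the block input.
#' @param filters filter count of every dilated layer.
#' @param dilations integer vector of length 3, dilation per layer
#'   (default `c(1, 1, 1)`).
#' @param weight_norm use weight normalisation on the dilated layers.
#' @return A `tcn_block_params` list: `layers` (list of 3
#'   [conv_layer_params()]) and `skip` (`W`, `b`); the dilation schedule
#'   is kept as the attribute `"dilations"` so the parameter tree holds
#'   trainable weights only.
#' @export
tcn_block_params <- function(in_channels, filters, dilations = c(1L, 1L, 1L),
                             weight_norm = TRUE) {
  if (length(dilations) != 3L)
    stop("a residual block has exactly 3 dilated layers", call. = FALSE)
  C <- as.integer(in_channels); Fn <- as.integer(filters)
  layers <- list(conv_layer_params(C, Fn, weight_norm),
                 conv_layer_params(Fn, Fn, weight_norm),
                 conv_layer_params(Fn, Fn, weight_norm))
  structure(list(layers = layers,
                 skip = list(W = glorot(C, Fn), b = numeric(Fn))),
            class = "tcn_block_params", dilations = as.integer(dilations))
}

block_dilations <- function(params) attr(params, "dilations")

# Draw fresh weight-dropout masks for the three dilated layers.
block_dropout_masks <- function(params, rate) {
  if (rate <= 0) return(NULL)
  lapply(params$layers, function(p) {
    W <- if (layer_has_wnorm(p)) p$v1 else p$w1
    list(m1 = matrix(stats::rbinom(length(W), 1L, 1 - rate), nrow(W), ncol(W)),
         m2 = matrix(stats::rbinom(length(W), 1L, 1 - rate), nrow(W), ncol(W)))
  })
}

# Batched block forward on a stacked matrix S0 ((B*N) x C).
block_forward <- function(S0, params, dilations, B, N, masks = NULL, rate = 0,
                          keep_cache = FALSE) {
  S <- S0
  cache <- if (keep_cache) vector("list", 3L)
  for (l in 1:3) {
    p <- params$layers[[l]]
    s <- dilations[l]
    eff <- effective_weights(p, masks[[l]], rate)
    Ssh <- shift_stack(S, B, N, s)
    Z <- Ssh %*% eff$W1 + S %*% eff$W2 + rep_row(p$b, nrow(S))
    if (keep_cache) cache[[l]] <- list(S_in = S, Ssh = Ssh, Z = Z, eff = eff)
    S <- relu(Z)
  }
  out <- S + S0 %*% params$skip$W + rep_row(params$skip$b, nrow(S0))
  list(out = out, cache = cache, S0 = S0)
}

block_backward <- function(fwd, params, dilations, B, N, dOut, masks = NULL,
                           rate = 0) {
  gr <- list(layers = vector("list", 3L),
             skip = list(W = t(fwd$S0) %*% dOut, b = colSums(dOut)))
  dS0 <- dOut %*% t(params$skip$W)
  dS <- dOut
  for (l in 3:1) {
    cc <- fwd$cache[[l]]
    p <- params$layers[[l]]
    s <- dilations[l]
    dZ <- dS * (cc$Z > 0)
    dW1e <- t(cc$Ssh) %*% dZ
    dW2e <- t(cc$S_in) %*% dZ
    gw <- effective_weights_backward(p, dW1e, dW2e, masks[[l]], rate)
    gw$b <- colSums(dZ)
    gr$layers[[l]] <- gw[names(p)]
    dS <- dZ %*% t(cc$eff$W2) + unshift_stack(dZ %*% t(cc$eff$W1), B, N, s)
  }
  list(grads = gr, dS0 = dS + dS0)
}

#' Residual block forward pass
#'
#' Applies the three dilated causal layers (ReLU) to `x` and adds the 1x1
#' skip projection of `x`. No activation follows the addition. In
#' training mode a fresh weight-dropout mask is drawn from the current
#' RNG; in evaluation mode the block is deterministic.
#'
#' @param x a T x C matrix.
#' @param params a [tcn_block_params()] object.
#' @param training logical; enables weight dropout.
#' @param dropout_rate fraction of dilated-layer weights dropped when
#'   training (default 0.1).
#' @return A T x F matrix.
#' @export
residual_block <- function(x, params, training = FALSE, dropout_rate = 0.1) {
  x <- as.matrix(x)
  if (ncol(x) != nrow(params$skip$W))
    stop("input has ", ncol(x), " channels but block expects ",
         nrow(params$skip$W), call. = FALSE)
  masks <- if (training && dropout_rate > 0)
    block_dropout_masks(params, dropout_rate)
  rate <- if (training) dropout_rate else 0
  block_forward(x, params, block_dilations(params), 1L, nrow(x), masks, rate)$out
}
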