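# Peephole LSTM implemented directly from its defining recurrences:
#
#   i_t = sigmoid(Wxi x_t + Whi h_{t-1} + wci * c_{t-1} + bi)
#   f_t = sigmoid(Wxf x_t + Whf h_{t-1} + wcf * c_{t-1} + bf)
#   c_t = f_t * c_{t-1} + i_t * tanh(Wxc x_t + Whc h_{t-1} + bc)
#   o_t = sigmoid(Wxo x_t + Who h_{t-1} + wco * c_{t-1} + bo)
#   h_t = o_t * tanh(c_t)
#
# Note the peephole into the output gate reads c_{t-1}, not c_t: the cell
# state feeds all three gates before it is updated. Stock framework LSTMs
# drop the peepholes entirely, which is why this cell is hand-built and
# oracle-tested rather than delegated.
#
# Peepholes are diagonal: wci, wcf, wco are per-unit vectors.

glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise peephole-LSTM parameters
#'
#' Weight matrices are Glorot-uniform, biases zero, drawn from the
#' current RNG state (seed with [set.seed()] or wrap the call).
#'
#' @param input_dim dimension of x_t.
#' @param units number of LSTM units.
#' @return An `lstm_params` list: `Wx*` (input_dim x units), `Wh*`
#'   (units x units), peephole vectors `wci`, `wcf`, `wco` and biases
#'   `bi`, `bf`, `bc`, `bo` (length units).
#' @export
lstm_params <- function(input_dim, units) {
  U <- as.integer(units); D <- as.integer(input_dim)
  stopifnot(U >= 1L, D >= 1L)
  peep <- function() stats::runif(U, -sqrt(6 / (2 * U)), sqrt(6 / (2 * U)))
  structure(list(
    Wxi = glorot(D, U), Wxf = glorot(D, U), Wxc = glorot(D, U), Wxo = glorot(D, U),
    Whi = glorot(U, U), Whf = glorot(U, U), Whc = glorot(U, U), Who = glorot(U, U),
    wci = peep(), wcf = peep(), wco = peep(),
    bi = numeric(U), bf = numeric(U), bc = numeric(U), bo = numeric(U)),
    class = "lstm_params")
}

lstm_units_of <- function(params) length(params$bi)

check_lstm_shapes <- function(x_cols, params) {
  U <- lstm_units_of(params)
  if (nrow(params$Wxi) != x_cols)
    stop("LSTM input dimension mismatch: x has ", x_cols,
         " columns but Wxi expects ", nrow(params$Wxi), call. = FALSE)
  stopifnot(all(vapply(params[c("Wxi", "Wxf", "Wxc", "Wxo")], ncol, 1L) == U),
            all(vapply(params[c("Whi", "Whf", "Whc", "Who")], dim, integer(2)) == U))
  U
}

# Batched single step: X (B x D), H/C (B x U). Returns updated state plus
# the gate activations needed for backpropagation through time.
lstm_step_batch <- function(X, H, C, p) {
  ai <- X %*% p$Wxi + H %*% p$Whi + sweep_cols(C, p$wci) + rep_row(p$bi, nrow(X))
  af <- X %*% p$Wxf + H %*% p$Whf + sweep_cols(C, p$wcf) + rep_row(p$bf, nrow(X))
  i <- sigmoid(ai); f <- sigmoid(af)
  g <- tanh(X %*% p$Wxc + H %*% p$Whc + rep_row(p$bc, nrow(X)))
  Cn <- f * C + i * g
  ao <- X %*% p$Wxo + H %*% p$Who + sweep_cols(C, p$wco) + rep_row(p$bo, nrow(X))
  o <- sigmoid(ao)
  tc <- tanh(Cn)
  list(H = o * tc, C = Cn, i = i, f = f, g = g, o = o, tc = tc)
}

sweep_cols <- function(M, v) sweep(M, 2L, v, "*")
rep_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

#' One LSTM step
#'
#' Advances the cell by a single time step for one input vector.
#'
#' @param x input vector (length input_dim).
#' @param state list with `h` and `c` (length units); use zeros to start.
#' @param params an [lstm_params()] object.
#' @return List with updated `h` and `c`.
#' @export
lstm_step <- function(x, state, params) {
  U <- check_lstm_shapes(length(x), params)
  stopifnot(length(state$h) == U, length(state$c) == U)
  st <- lstm_step_batch(matrix(x, 1L), matrix(state$h, 1L), matrix(state$c, 1L),
                        params)
  list(h = as.numeric(st$H), c = as.numeric(st$C))
}

#' LSTM forward pass over a sequence
#'
#' Iterates [lstm_step()] from the zero state and returns the full hidden
#' state sequence `[h_1 ... h_N]` (every step, not only the last one):
#' the downstream temporal convolution consumes the whole feature
#' sequence.
#'
#' @param x an N x input_dim matrix, one row per time step.
#' @param params an [lstm_params()] object.
#' @return An N x units matrix of hidden states.
#' @export
lstm_forward <- function(x, params) {
  x <- as.matrix(x)
  U <- check_lstm_shapes(ncol(x), params)
  fwd <- lstm_layer_forward(array(x, c(1L, nrow(x), ncol(x))), params)
  matrix(fwd$H_stack, nrow(x), U)
}

# Batched layer forward: X is B x N x D. Returns the hidden states as a
# sample-major stacked matrix (row (b-1)*N + t) plus per-step caches.
lstm_layer_forward <- function(X, p, keep_cache = FALSE) {
  B <- dim(X)[1]; N <- dim(X)[2]; D <- dim(X)[3]
  U <- check_lstm_shapes(D, p)
  H <- matrix(0, B, U); C <- matrix(0, B, U)
  H_stack <- matrix(0, B * N, U)
  cache <- if (keep_cache) vector("list", N)
  for (t in seq_len(N)) {
    Xt <- matrix(X[, t, ], B, D)
    st <- lstm_step_batch(Xt, H, C, p)
    if (keep_cache)
      cache[[t]] <- list(X = Xt, H_prev = H, C_prev = C, i = st$i, f = st$f,
                         g = st$g, o = st$o, C = st$C, tc = st$tc)
    H <- st$H; C <- st$C
    H_stack[seq(t, by = N, length.out = B), ] <- H
  }
  list(H_stack = H_stack, cache = cache, B = B, N = N, D = D, U = U)
}

# Backpropagation through time. dH_stack matches H_stack's layout.
# Returns parameter gradients (same shapes as params) and the gradient
# with respect to the layer input (B x N x D array) for stacking layers.
lstm_layer_backward <- function(fwd, p, dH_stack) {
  B <- fwd$B; N <- fwd$N; D <- fwd$D; U <- fwd$U
  gr <- lapply(p, function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w)))
  dX <- array(0, c(B, N, D))
  dH_carry <- matrix(0, B, U)
  dC_next <- matrix(0, B, U)
  for (t in rev(seq_len(N))) {
    cc <- fwd$cache[[t]]
    dH <- matrix(dH_stack[seq(t, by = N, length.out = B), ], B, U) + dH_carry
    d_o <- dH * cc$tc
    dao <- d_o * cc$o * (1 - cc$o)
    dC <- dH * cc$o * (1 - cc$tc^2) + dC_next
    d_f <- dC * cc$C_prev
    d_i <- dC * cc$g
    d_g <- dC * cc$i
    daf <- d_f * cc$f * (1 - cc$f)
    dai <- d_i * cc$i * (1 - cc$i)
    dag <- d_g * (1 - cc$g^2)
    tX <- t(cc$X); tH <- t(cc$H_prev)
    gr$Wxi <- gr$Wxi + tX %*% dai; gr$Whi <- gr$Whi + tH %*% dai
    gr$Wxf <- gr$Wxf + tX %*% daf; gr$Whf <- gr$Whf + tH %*% daf
    gr$Wxc <- gr$Wxc + tX %*% dag; gr$Whc <- gr$Whc + tH %*% dag
    gr$Wxo <- gr$Wxo + tX %*% dao; gr$Who <- gr$Who + tH %*% dao
    gr$wci <- gr$wci + colSums(dai * cc$C_prev)
    gr$wcf <- gr$wcf + colSums(daf * cc$C_prev)
    gr$wco <- gr$wco + colSums(dao * cc$C_prev)
    gr$bi <- gr$bi + colSums(dai); gr$bf <- gr$bf + colSums(daf)
    gr$bc <- gr$bc + colSums(dag); gr$bo <- gr$bo + colSums(dao)
    dH_carry <- dai %*% t(p$Whi) + daf %*% t(p$Whf) +
      dag %*% t(p$Whc) + dao %*% t(p$Who)
    # c_{t-1} enters through the cell update and all three gate peepholes
    dC_next <- dC * cc$f + sweep_cols(dai, p$wci) + sweep_cols(daf, p$wcf) +
      sweep_cols(dao, p$wco)
    dX[, t, ] <- dai %*% t(p$Wxi) + daf %*% t(p$Wxf) +
      dag %*% t(p$Wxc) + dao %*% t(p$Wxo)
  }
  list(grads = gr, dX = dX)
}
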