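# Independent scalar re-implementations of the defining recurrences,
# written with plain loops so they share no code path with the package's
# vectorised forward passes. Used as oracles.

sig <- function(x) 1 / (1 + exp(-x))

# Peephole LSTM step, unit by unit.
oracle_lstm_step <- function(x, h_prev, c_prev, p) {
  U <- length(p$bi)
  h <- numeric(U); cn <- numeric(U)
  for (u in seq_len(U)) {
    ai <- sum(p$Wxi[, u] * x) + sum(p$Whi[, u] * h_prev) +
      p$wci[u] * c_prev[u] + p$bi[u]
    af <- sum(p$Wxf[, u] * x) + sum(p$Whf[, u] * h_prev) +
      p$wcf[u] * c_prev[u] + p$bf[u]
    ac <- sum(p$Wxc[, u] * x) + sum(p$Whc[, u] * h_prev) + p$bc[u]
    i <- sig(ai); f <- sig(af)
    cn[u] <- f * c_prev[u] + i * tanh(ac)
    ao <- sum(p$Wxo[, u] * x) + sum(p$Who[, u] * h_prev) +
      p$wco[u] * c_prev[u] + p$bo[u]
    h[u] <- sig(ao) * tanh(cn[u])
  }
  list(h = h, c = cn)
}

# Dilated causal convolution, element by element, explicit zero padding.
oracle_dilated_conv <- function(x, w1, w2, b, s, relu = TRUE) {
  T_ <- nrow(x); Fn <- ncol(w1)
  out <- matrix(0, T_, Fn)
  for (t in seq_len(T_)) {
    for (f in seq_len(Fn)) {
      acc <- b[f]
      for (c in seq_len(ncol(x))) {
        xlag <- if (t - s >= 1) x[t - s, c] else 0
        acc <- acc + w1[c, f] * xlag + w2[c, f] * x[t, c]
      }
      out[t, f] <- if (relu) max(acc, 0) else acc
    }
  }
  out
}

# Brute-force enumeration of valid sliding-window anchors.
oracle_window_count <- function(L, N, H, step) {
  count <- 0L
  for (start in seq_len(L)) {
    if ((start - 1L) %% step != 0L) next
    if (start + N - 1L + H <= L) count <- count + 1L
  }
  count
}

# Fixture series: short simulated runs with growth starting on day 1 so
# the yield factor is non-degenerate even for the smallest windows.
make_fixture_series <- function(seed = 101, n_days = 120) {
  simulate_greenhouse(growth = yield_spec(onset_day = 1L, saturation_day = 400L),
                      n_days = n_days, seed = seed)
}

tiny_model_cfg <- function(...) {
  model_config(lstm_units = 4L, tcn_filters = 4L, ...)
}

tiny_train_cfg <- function(epochs = 3L, seed = 1L) {
  training_config(epochs = epochs, batch_size = 16L, seed = seed)
}
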