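# Central finite-difference gradient, used to verify every analytic
# gradient in the package. fun maps a flat numeric vector to a scalar.
numeric_gradient <- function(fun, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (fun(xp) - fun(xm)) / (2 * eps)
  }, numeric(1))
}

# Relative agreement between analytic and numeric gradient vectors.
grad_rel_err <- function(analytic, numeric) {
  denom <- pmax(abs(analytic) + abs(numeric), 1e-8)
  max(abs(analytic - numeric) / denom)
}
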