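# Min-max normalisation of the six factors: each factor i is mapped by
# (x - min_i) / (max_i - min_i) so that values seen while fitting land in
# [0, 1]. Values outside the fitted range map outside [0, 1] by design and
# are never clipped: clipping would silently distort held-out data.

#' Fit per-factor min-max normalisation
#'
#' Records each factor's minimum and maximum over `series` (optionally over
#' `days` only, e.g. the training period so the test period never informs
#' the scaling).
#'
#' @param series a `greenhouse_series`.
#' @param days optional integer vector of day indices to fit on; defaults
#'   to the whole series.
#' @return An object of class `norm_params`: named list of `c(min, max)`
#'   per factor.
#' @export
#' @examples
#' gs <- simulate_greenhouse(n_days = 30, seed = 1)
#' np <- fit_normalization(gs)
#' np$co2
fit_normalization <- function(series, days = NULL) {
  validate_series(series)
  df <- as.data.frame(series)
  if (!is.null(days)) {
    df <- df[df$day %in% as.integer(days), , drop = FALSE]
    if (nrow(df) == 0L) stop("no rows left after restricting to 'days'", call. = FALSE)
  }
  params <- lapply(FACTOR_NAMES, function(f) {
    rng <- range(df[[f]])
    if (rng[2] <= rng[1])
      stop("degenerate factor '", f, "': max equals min (", rng[1],
           "), cannot normalise", call. = FALSE)
    c(min = rng[1], max = rng[2])
  })
  names(params) <- FACTOR_NAMES
  structure(params, class = "norm_params")
}

#' Normalise / denormalise a factor value
#'
#' `normalize_value()` maps a raw value to the unit interval with the
#' fitted extrema; `denormalize_value()` is the exact inverse.
#'
#' @param x numeric vector of raw (or normalised) values.
#' @param params a `norm_params` object.
#' @param factor factor name (one of [greenhouse_factors()]) or index 1-6.
#' @return Numeric vector.
#' @export
normalize_value <- function(x, params, factor) {
  p <- norm_factor(params, factor)
  (x - p[["min"]]) / (p[["max"]] - p[["min"]])
}

#' @rdname normalize_value
#' @export
denormalize_value <- function(x, params, factor) {
  p <- norm_factor(params, factor)
  x * (p[["max"]] - p[["min"]]) + p[["min"]]
}

norm_factor <- function(params, factor) {
  stopifnot(inherits(params, "norm_params"))
  if (is.numeric(factor)) factor <- names(params)[factor]
  p <- params[[factor]]
  if (is.null(p)) stop("unknown factor '", factor, "'", call. = FALSE)
  p
}

# L x 6 matrix of normalised factors for a whole series.
normalize_matrix <- function(series, params) {
  m <- series_matrix(series)
  mins <- vapply(params, `[[`, numeric(1), "min")[colnames(m)]
  maxs <- vapply(params, `[[`, numeric(1), "max")[colnames(m)]
  sweep(sweep(m, 2L, mins, "-"), 2L, maxs - mins, "/")
}

#' Serialise normalisation parameters as JSON
#'
#' Written as `{factor: {min, max}}` so fitted scalings can travel with a
#' model checkpoint.
#'
#' @param params a `norm_params` object.
#' @param path output path.
#' @return `path` invisibly; `read_norm_params()` returns a `norm_params`.
#' @export
write_norm_params <- function(params, path) {
  stopifnot(inherits(params, "norm_params"))
  out <- lapply(params, function(p) list(min = p[["min"]], max = p[["max"]]))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_norm_params
#' @export
read_norm_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(raw, function(p) c(min = p$min, max = p$max))
  structure(params[FACTOR_NAMES], class = "norm_params")
}

#' @export
print.norm_params <- function(x, ...) {
  cat("<norm_params>\n")
  for (f in names(x))
    cat(sprintf("  %-18s [%.4g, %.4g]\n", f, x[[f]][["min"]], x[[f]][["max"]]))
  invisible(x)
}
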