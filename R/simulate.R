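# Synthetic greenhouse generator. Real commercial tomato records are
# restricted, so experiments run on simulated series built to sit inside
# the published descriptive envelope of such data: each environmental
# factor is a seasonal sinusoid plus AR(1) noise clipped to hard bounds,
# and accumulated yield is a non-decreasing sigmoid-like curve driven
# mostly by elapsed growth with a weak climate response.

ENV_FACTORS <- c("co2", "temperature", "humidity_deficit",
                 "relative_humidity", "radiation")

#' Climate specification for one environmental factor
#'
#' @param min,max hard bounds in the factor's units; simulated values are
#'   clipped to this interval.
#' @param mean,sd target stationary mean and standard deviation.
#' @param amplitude seasonal (annual sinusoid) amplitude, same units.
#' @param phi AR(1) coefficient of the day-to-day noise, in \[0, 1).
#' @param noise_sd innovation standard deviation of the AR(1) term.
#' @param peak_day day of year at which the seasonal term peaks
#'   (default 181, mid-year: northern-hemisphere summer).
#' @return A `factor_spec` list.
#' @export
factor_spec <- function(min, max, mean, sd, amplitude = 0, phi = 0.7,
                        noise_sd = sd * 0.5, peak_day = 181) {
  if (!(min < max)) stop("factor spec requires min < max", call. = FALSE)
  if (!(mean > min && mean < max))
    stop("factor spec mean must lie strictly inside (min, max)", call. = FALSE)
  if (!(phi >= 0 && phi < 1)) stop("phi must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0 || amplitude < 0)
    stop("amplitude and noise_sd must be non-negative", call. = FALSE)
  structure(list(min = min, max = max, mean = mean, sd = sd,
                 amplitude = amplitude, phi = phi, noise_sd = noise_sd,
                 peak_day = peak_day),
            class = "factor_spec")
}

#' Climate specification for all five environmental factors
#'
#' @param co2,temperature,humidity_deficit,relative_humidity,radiation
#'   [factor_spec()] objects.
#' @return A `climate_spec` list.
#' @seealso [climate_preset()] for ready-made specifications.
#' @export
climate_spec <- function(co2, temperature, humidity_deficit,
                         relative_humidity, radiation) {
  spec <- list(co2 = co2, temperature = temperature,
               humidity_deficit = humidity_deficit,
               relative_humidity = relative_humidity, radiation = radiation)
  for (f in ENV_FACTORS)
    if (!inherits(spec[[f]], "factor_spec"))
      stop("'", f, "' must be a factor_spec", call. = FALSE)
  structure(spec, class = "climate_spec")
}

# Seasonal + AR(1) split of the target sd: temperature and radiation are
# dominated by the annual cycle, CO2 / humidity factors are kept flat in
# season (enrichment and vent control decouple them from the calendar).
seasonal_factor_spec <- function(min, max, mean, sd, seasonal = FALSE,
                                 phi = 0.7) {
  if (seasonal) {
    amplitude <- 1.2 * sd
    resid_sd <- sd * sqrt(max(1 - 1.2^2 / 2, 0.05))
  } else {
    amplitude <- 0
    resid_sd <- sd
  }
  factor_spec(min = min, max = max, mean = mean, sd = sd,
              amplitude = amplitude, phi = phi,
              noise_sd = resid_sd * sqrt(1 - phi^2))
}

#' Preset climate specifications
#'
#' Three ready-made specifications whose bounds, means and standard
#' deviations follow the published descriptive statistics of one year of
#' daily records from two UK commercial tomato greenhouses (CO2 in ppm,
#' temperature in deg C, humidity deficit in g/kg, relative humidity in
#' %, radiation in W/m2). `dataset2` has the distinctly lowest CO2 level
#' of the three, as in the source records.
#'
#' @param name `"dataset1"`, `"dataset2"` or `"dataset3"`.
#' @return A `climate_spec`.
#' @export
#' @examples
#' climate_preset("dataset2")$co2$mean
climate_preset <- function(name = c("dataset1", "dataset2", "dataset3")) {
  name <- match.arg(name)
  tab <- switch(name,
    dataset1 = list(
      co2               = c(535.97, 1634.10, 785.95, 152.52),
      temperature       = c(4.73, 23.73, 17.25, 3.97),
      humidity_deficit  = c(0.33, 6.70, 2.91, 1.40),
      relative_humidity = c(63.04, 96.24, 82.49, 6.57),
      radiation         = c(0.59, 82.91, 42.17, 19.37)),
    dataset2 = list(
      co2               = c(370.94, 967.40, 624.19, 129.58),
      temperature       = c(3.68, 23.89, 17.01, 4.25),
      humidity_deficit  = c(0.13, 7.27, 2.91, 1.29),
      relative_humidity = c(65.31, 98.50, 82.19, 5.88),
      radiation         = c(0.58, 83.02, 42.19, 18.92)),
    dataset3 = list(
      co2               = c(478.05, 1691.43, 770.37, 175.61),
      temperature       = c(4.72, 23.69, 17.18, 3.94),
      humidity_deficit  = c(0.00, 6.08, 2.65, 1.33),
      relative_humidity = c(65.09, 100.00, 83.99, 6.72),
      radiation         = c(0.59, 82.91, 42.17, 19.37)))
  specs <- lapply(ENV_FACTORS, function(f) {
    v <- tab[[f]]
    seasonal_factor_spec(v[1], v[2], v[3], v[4],
                         seasonal = f %in% c("temperature", "radiation"))
  })
  names(specs) <- ENV_FACTORS
  do.call(climate_spec, specs)
}

#' Simulate daily environmental factors
#'
#' Each factor is generated independently as
#' `mean + amplitude * cos(2*pi*(d - peak_day)/365) + e_d` with
#' `e_d = phi * e_{d-1} + N(0, noise_sd)`, then clipped to its bounds.
#'
#' @param spec a [climate_spec()].
#' @param n_days number of days to simulate.
#' @param seed integer seed; identical seed and spec give a bit-identical
#'   matrix.
#' @return An `n_days` x 5 matrix with the environmental factors as
#'   columns.
#' @export
simulate_environment <- function(spec, n_days, seed = 1L) {
  stopifnot(inherits(spec, "climate_spec"))
  n_days <- as.integer(n_days)
  if (n_days < 1L) stop("n_days must be >= 1", call. = FALSE)
  with_seed(seed, {
    out <- vapply(ENV_FACTORS, function(f) {
      p <- spec[[f]]
      d <- seq_len(n_days) - 1L
      seasonal <- p$mean + p$amplitude * cos(2 * pi * (d - p$peak_day) / 365)
      e <- numeric(n_days)
      innov <- stats::rnorm(n_days, 0, p$noise_sd)
      # stationary start so short series are not initial-condition biased
      e[1] <- if (p$phi > 0 && p$noise_sd > 0)
        stats::rnorm(1, 0, p$noise_sd / sqrt(1 - p$phi^2)) else innov[1]
      if (n_days > 1L)
        for (t in 2:n_days) e[t] <- p$phi * e[t - 1] + innov[t]
      pmin(pmax(seasonal + e, p$min), p$max)
    }, numeric(n_days))
    matrix(out, nrow = n_days, dimnames = list(NULL, ENV_FACTORS))
  })
}

#' Yield specification
#'
#' Accumulated yield starts at zero, begins to grow at `onset_day`,
#' plateaus at `saturation_day`, and between the two accrues a daily
#' increment `max(0, base + beta . z + noise)` where `z` are the
#' standardized climate drivers. The flooring at zero makes the
#' accumulated curve non-decreasing by construction. The climate
#' response is deliberately weak relative to `base`: an accumulated
#' total is dominated by its own history, which is exactly the property
#' the factor-ablation experiment probes.
#'
#' @param onset_day first day with non-zero growth (default 60).
#' @param saturation_day day growth stops (default 330).
#' @param base base daily increment, g/m2/day (default 10).
#' @param beta named numeric vector of unit-free response weights on
#'   standardized drivers; default `c(radiation = 0.5, co2 = 0.3,
#'   temperature = 0.2)`.
#' @param noise_sd increment noise standard deviation, g/m2/day
#'   (default 2).
#' @return A `yield_spec` list.
#' @export
yield_spec <- function(onset_day = 60L, saturation_day = 330L, base = 10,
                       beta = c(radiation = 0.5, co2 = 0.3, temperature = 0.2),
                       noise_sd = 2) {
  if (!(onset_day < saturation_day))
    stop("onset_day must precede saturation_day", call. = FALSE)
  if (base < 0 || noise_sd < 0)
    stop("base increment and noise_sd must be non-negative", call. = FALSE)
  if (length(beta) && is.null(names(beta)))
    stop("beta must be a named vector of climate factors", call. = FALSE)
  unknown <- setdiff(names(beta), ENV_FACTORS)
  if (length(unknown))
    stop("unknown beta driver(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(onset_day = as.integer(onset_day),
                 saturation_day = as.integer(saturation_day),
                 base = base, beta = beta, noise_sd = noise_sd),
            class = "yield_spec")
}

#' Simulate accumulated yield from a climate matrix
#'
#' @param climate matrix from [simulate_environment()] (columns named by
#'   factor).
#' @param spec a [yield_spec()].
#' @param seed integer seed for the increment noise.
#' @return Numeric vector of accumulated yield (g/m2), non-decreasing,
#'   zero before `onset_day`, flat after `saturation_day`.
#' @export
simulate_yield <- function(climate, spec = yield_spec(), seed = 1L) {
  stopifnot(inherits(spec, "yield_spec"))
  n <- nrow(climate)
  if (is.null(n) || n < 1L) stop("climate matrix is empty", call. = FALSE)
  drivers <- names(spec$beta)
  if (!all(drivers %in% colnames(climate)))
    stop("climate matrix is missing driver column(s): ",
         paste(setdiff(drivers, colnames(climate)), collapse = ", "),
         call. = FALSE)
  signal <- if (length(drivers)) {
    z <- scale(climate[, drivers, drop = FALSE])
    z[!is.finite(z)] <- 0  # constant driver => no contribution
    as.numeric(z %*% spec$beta)
  } else rep(0, n)
  noise <- with_seed(seed, stats::rnorm(n, 0, spec$noise_sd))
  day <- seq_len(n) - 1L
  growing <- day >= spec$onset_day & day < spec$saturation_day
  inc <- pmax(spec$base + signal + noise, 0) * growing
  cumsum(inc)
}

#' Simulate a complete greenhouse dataset
#'
#' Assembles climate and yield into a [greenhouse_series()] matching the
#' daily CSV schema. Defaults give one simulated year from the
#' `dataset1` climate preset.
#'
#' @param climate a [climate_spec()] (default `climate_preset("dataset1")`).
#' @param growth a [yield_spec()].
#' @param n_days days to simulate (default 365).
#' @param seed master seed; climate and yield noise both derive from it.
#' @return A `greenhouse_series`.
#' @export
#' @examples
#' gs <- simulate_greenhouse(n_days = 60, seed = 42)
#' head(gs)
simulate_greenhouse <- function(climate = climate_preset("dataset1"),
                                growth = yield_spec(),
                                n_days = 365L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L)
  climate <- simulate_environment(climate, n_days, seed = seeds[1])
  y <- simulate_yield(climate, growth, seed = seeds[2])
  greenhouse_series(day = seq_len(nrow(climate)) - 1L, yield = y,
                    co2 = climate[, "co2"],
                    temperature = climate[, "temperature"],
                    humidity_deficit = climate[, "humidity_deficit"],
                    relative_humidity = climate[, "relative_humidity"],
                    radiation = climate[, "radiation"])
}

#' Read simulator specifications from a YAML config
#'
#' The `simulator` section may give `preset: dataset1|2|3` or a full
#' per-factor table, plus a `yield:` block with [yield_spec()] fields.
#'
#' @param cfg parsed config list (see [read_config()]).
#' @return List with elements `climate` and `yield`.
#' @export
simulator_from_config <- function(cfg) {
  sim <- cfg$simulator
  climate <- if (!is.null(sim$preset)) {
    climate_preset(sim$preset)
  } else if (!is.null(sim$climate)) {
    specs <- lapply(ENV_FACTORS, function(f)
      do.call(factor_spec, sim$climate[[f]]))
    names(specs) <- ENV_FACTORS
    do.call(climate_spec, specs)
  } else climate_preset("dataset1")
  yld <- if (!is.null(sim$yield)) {
    args <- sim$yield
    if (!is.null(args$beta)) args$beta <- unlist(args$beta)
    do.call(yield_spec, args)
  } else yield_spec()
  list(climate = climate, yield = yld)
}
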