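#' @keywords internal
"_PACKAGE"

# Canonical factor order used throughout: the per-day feature vector is
# (yield, co2, temperature, humidity_deficit, relative_humidity, radiation).
FACTOR_NAMES <- c("yield", "co2", "temperature", "humidity_deficit",
                  "relative_humidity", "radiation")

FACTOR_LABELS <- c(
  yield             = "historical yield information",
  co2               = "CO2 concentration",
  temperature       = "temperature",
  humidity_deficit  = "humidity deficit",
  relative_humidity = "relative humidity",
  radiation         = "radiation"
)

#' Factor names of a greenhouse series
#'
#' The fixed order of the six daily factors: accumulated yield (g/m2),
#' CO2 concentration (ppm), temperature (degrees C), humidity deficit
#' (g/kg), relative humidity (%), radiation (W/m2).
#'
#' @return Character vector of length six.
#' @export
greenhouse_factors <- function() FACTOR_NAMES

#' Construct a daily greenhouse series
#'
#' Bundles one growing period of daily records into a validated data frame
#' of class `greenhouse_series`: an accumulated yield track plus the five
#' environmental factors, one row per day.
#'
#' @param day integer vector of 0-based, consecutive day indices.
#' @param yield accumulated yield, g/m2; non-negative.
#' @param co2 CO2 concentration, ppm.
#' @param temperature air temperature, degrees C.
#' @param humidity_deficit humidity deficit, g water / kg air.
#' @param relative_humidity relative humidity, percent (0-100).
#' @param radiation radiation, W/m2.
#'
#' @return A `greenhouse_series` data frame with columns `day` and the six
#'   factors in canonical order.
#' @export
#' @examples
#' gs <- greenhouse_series(day = 0:2, yield = c(0, 1, 3), co2 = c(600, 700, 650),
#'                         temperature = c(17, 18, 16), humidity_deficit = c(2, 3, 2.5),
#'                         relative_humidity = c(80, 82, 81), radiation = c(40, 45, 42))
#' nrow(gs)
greenhouse_series <- function(day, yield, co2, temperature, humidity_deficit,
                              relative_humidity, radiation) {
  df <- data.frame(day = as.integer(day), yield = as.numeric(yield),
                   co2 = as.numeric(co2), temperature = as.numeric(temperature),
                   humidity_deficit = as.numeric(humidity_deficit),
                   relative_humidity = as.numeric(relative_humidity),
                   radiation = as.numeric(radiation))
  validate_series(df)
  class(df) <- c("greenhouse_series", "data.frame")
  df
}

validate_series <- function(df) {
  need <- c("day", FACTOR_NAMES)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("greenhouse series is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) < 1L) stop("greenhouse series is empty", call. = FALSE)
  for (f in FACTOR_NAMES)
    if (!all(is.finite(df[[f]])))
      stop("non-finite values in factor '", f, "'", call. = FALSE)
  d <- as.integer(df$day)
  if (any(diff(d) != 1L))
    stop("day index must increase by exactly 1 (missing days are an error, ",
         "no imputation is performed)", call. = FALSE)
  if (any(df$yield < 0)) stop("accumulated yield must be non-negative", call. = FALSE)
  if (any(df$relative_humidity < 0 | df$relative_humidity > 100))
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  invisible(df)
}

#' Read a daily greenhouse series from CSV
#'
#' Expects the header `day,yield,co2,temperature,humidity_deficit,
#' relative_humidity,radiation`, one row per day, dot decimal separator.
#' Gaps in the day index are a hard error: the pipeline assumes complete
#' daily recordings and performs no imputation.
#'
#' @param path path to a CSV file.
#' @return A `greenhouse_series`.
#' @export
read_greenhouse_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  do.call(greenhouse_series, df[c("day", FACTOR_NAMES)])
}

#' Write a greenhouse series to CSV
#'
#' @param series a `greenhouse_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_greenhouse_csv <- function(series, path) {
  validate_series(series)
  utils::write.csv(as.data.frame(series)[c("day", FACTOR_NAMES)], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Numeric day-by-factor matrix (L x 6) in canonical factor order.
series_matrix <- function(series) {
  as.matrix(as.data.frame(series)[FACTOR_NAMES])
}

#' @export
print.greenhouse_series <- function(x, ...) {
  cat(sprintf("<greenhouse_series> %d days (day %d..%d), final yield %.1f g/m2\n",
              nrow(x), x$day[1], x$day[nrow(x)], x$yield[nrow(x)]))
  print(utils::head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat("...\n")
  invisible(x)
}
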