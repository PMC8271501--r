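# YAML configuration: one file can carry `window`, `model`, `training`,
# `grid` and `simulator` sections; each maps 1:1 onto the corresponding
# constructor, so a config round-trips exactly.

#' Read a YAML configuration file
#'
#' Recognised sections: `window` ([window_config()] fields), `model`
#' ([model_config()] fields), `training` ([training_config()] fields),
#' `grid` ([grid_spec()] fields), `simulator` (`preset` or per-factor
#' `climate` table plus `yield`).
#'
#' @param path path to a YAML file.
#' @return Parsed list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' Build configuration objects from a parsed config
#'
#' Missing sections or fields fall back to the package defaults.
#'
#' @param cfg parsed list from [read_config()] (or `NULL`).
#' @return The corresponding configuration object.
#' @export
window_from_config <- function(cfg) {
  do.call(window_config, cfg$window %||% list())
}

#' @rdname window_from_config
#' @export
model_from_config <- function(cfg) {
  args <- cfg$model %||% list()
  if (!is.null(args$dilations)) args$dilations <- unlist(args$dilations)
  args$kernel_size <- NULL  # fixed at 2; tolerated in round-tripped configs
  do.call(model_config, args)
}

#' @rdname window_from_config
#' @export
training_from_config <- function(cfg) {
  args <- cfg$training %||% list()
  args$optimizer <- NULL  # fixed to Adam
  do.call(training_config, args)
}

#' @rdname window_from_config
#' @export
grid_from_config <- function(cfg) {
  args <- cfg$grid %||% list()
  args <- lapply(args, unlist)
  do.call(grid_spec, args)
}

#' Write configuration objects back to YAML
#'
#' @param window,model,training,grid configuration objects (any may be
#'   omitted).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(path, window = NULL, model = NULL, training = NULL,
                         grid = NULL) {
  out <- list()
  if (!is.null(window)) out$window <- unclass(window)
  if (!is.null(model)) out$model <- unclass(model)
  if (!is.null(training)) out$training <- unclass(training)
  if (!is.null(grid)) out$grid <- unclass(grid)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
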