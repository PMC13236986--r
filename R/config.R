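#' Build and validate a run configuration
#'
#' Collects the knobs of the pipeline in one validated list: file paths and
#' variable names, the vertical level, the season, the sector scheme, the
#' structuring-element size, the axis-smoothing window, statistics flags and
#' epochs, and seeds. A serialised copy should be written next to any run's
#' outputs with [write_run_config()] so results are reproducible from the
#' config alone.
#'
#' @param ... fields overriding the defaults; unknown fields are rejected.
#' @return an object of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    input = NULL, variable = "u", level = 200,
    season = c(6L, 7L, 8L),
    element = c(lat_cells = 5L, lon_cells = 5L), element_shape = "rectangle",
    window_km = 1000,
    sectors = sector_scheme(),
    detrend = FALSE, ar1_adjust = FALSE, fdr = FALSE,
    epochs = list(c(1979, 1999), c(2000, 2023)),
    change_mode = "trend_change", n_boot = 2000L,
    seed = 1L, out_dir = ".", log_level = "info")
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  if (!is.null(over$sectors) && !inherits(over$sectors, "sector_scheme"))
    over$sectors <- do.call(sector_scheme, as.list(over$sectors))
  cfg <- defaults
  cfg[names(over)] <- over
  stopifnot(cfg$window_km > 0, cfg$n_boot >= 100,
            all(cfg$element >= 1), all(cfg$element %% 2 == 1),
            cfg$change_mode %in% c("trend_change", "epoch_diff"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Sector schemes are given as a mapping `sectors: {name: [...], west: [...],
#' east: [...]}`; all other fields are plain key-value pairs. The result is
#' validated by [run_config()] before anything is computed.
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sectors) && !inherits(raw$sectors, "sector_scheme"))
    raw$sectors <- do.call(sector_scheme, raw$sectors)
  if (!is.null(raw$epochs)) raw$epochs <- lapply(raw$epochs, unlist)
  do.call(run_config, raw)
}

#' Serialise a run configuration to YAML
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- unclass(cfg)
  out$sectors <- list(name = cfg$sectors$name, west = cfg$sectors$west,
                      east = cfg$sectors$east)
  yaml::write_yaml(out, path)
  invisible(path)
}
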