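#' Gridded lat-lon(-time) field
#'
#' The common container for all gridded inputs and outputs: a numeric array on
#' a regular latitude-longitude grid, optionally with a time axis. Latitudes
#' must be strictly increasing; longitudes strictly increasing on a regular
#' step and treated as periodic (covering `[0, 360)` after normalisation).
#'
#' @param values numeric array of dim `c(n_lat, n_lon)` or
#'   `c(n_lat, n_lon, n_time)`.
#' @param lat strictly increasing latitudes in degrees.
#' @param lon strictly increasing longitudes in degrees.
#' @param time optional time coordinate (integer index or `Date` vector).
#' @param units units string stored as metadata.
#' @return an object of class `gridded_field`.
#' @export
gridded_field <- function(values, lat, lon, time = NULL, units = "") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  stopifnot(is.array(values), length(dim(values)) == 3L)
  if (dim(values)[1] != length(lat) || dim(values)[2] != length(lon))
    stop("values must have dim [n_lat, n_lon(, n_time)]")
  .check_regular(lat, "latitude")
  .check_regular(lon, "longitude")
  if (is.null(time)) time <- seq_len(dim(values)[3])
  if (length(time) != dim(values)[3]) stop("time length does not match values")
  structure(list(values = values, lat = lat, lon = lon, time = time,
                 units = units),
            class = "gridded_field")
}

.check_regular <- function(x, what) {
  if (length(x) < 2) stop(what, " axis needs at least 2 points")
  d <- diff(x)
  if (any(d <= 0)) stop(what, " must be strictly increasing")
  if (diff(range(d)) > 1e-6 * mean(d))
    stop("irregular ", what, " spacing: grid must be regular")
  invisible(mean(d))
}

#' @export
print.gridded_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<gridded_field> %d lat x %d lon x %d time [%s]\n",
              d[1], d[2], d[3], x$units))
  cat(sprintf("  lat %g..%g step %g | lon %g..%g step %g\n",
              min(x$lat), max(x$lat), diff(x$lat)[1],
              min(x$lon), max(x$lon), diff(x$lon)[1]))
  invisible(x)
}

#' Grid steps of a gridded field
#' @param field a `gridded_field`.
#' @return named numeric `c(lat =, lon =)` in degrees.
#' @keywords internal
grid_step <- function(field) {
  c(lat = diff(field$lat)[1], lon = diff(field$lon)[1])
}

#' Extract one time slice as a lat x lon matrix
#' @param field a `gridded_field`.
#' @param t time index.
#' @keywords internal
field_slice <- function(field, t = 1L) {
  field$values[, , t, drop = TRUE]
}

#' Jet axis polyline
#'
#' Per time step, the detected (or prescribed) jet axis: one latitude per
#' longitude grid column, covering the full longitude circle.
#'
#' @param lon longitudes in degrees, regular and increasing.
#' @param lat matrix `[n_time, n_lon]` (or vector for one time step) of axis
#'   latitudes in degrees North.
#' @param time optional time coordinate.
#' @return an object of class `jet_axis`.
#' @export
jet_axis <- function(lon, lat, time = NULL) {
  if (is.vector(lat)) lat <- matrix(lat, nrow = 1L)
  if (ncol(lat) != length(lon)) stop("one axis latitude per longitude required")
  .check_regular(lon, "longitude")
  if (any(!is.finite(lat)) || any(lat < 0) || any(lat > 90))
    stop("axis latitudes must be finite and within [0, 90] degrees North")
  if (is.null(time)) time <- seq_len(nrow(lat))
  structure(list(lon = lon, lat = lat, time = time), class = "jet_axis")
}

#' @export
print.jet_axis <- function(x, ...) {
  cat(sprintf("<jet_axis> %d time step(s) x %d longitudes, lat %0.1f..%0.1fN\n",
              nrow(x$lat), length(x$lon), min(x$lat), max(x$lat)))
  invisible(x)
}
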