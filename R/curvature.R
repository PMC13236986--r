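#' Pointwise streamline curvature of a jet axis
#'
#' Computes the signed curvature of the axis polyline `y(x)` (latitude as a
#' function of longitude, both in degrees) at every longitude:
#'
#' `kappa(x) = y'' / (1 + y'^2)^(3/2)`
#'
#' with first and second derivatives by central differences on the periodic
#' longitude circle (one grid step; endpoints wrap). Under the default
#' `"ridge_positive"` convention the result is negated so that a northward
#' crest (anticyclonic ridge, `y'' < 0`) has positive curvature and a
#' southward trough negative curvature; `"raw"` returns the bare formula.
#' Coordinates are planar longitude-latitude degrees with no cos-latitude
#' metric scaling.
#'
#' The axis should be smoothed (see [smooth_axis()]) before curvature is
#' computed; the curvature itself is not re-smoothed.
#'
#' @param axis a [jet_axis()] on a regular longitude grid.
#' @param convention `"ridge_positive"` (default) or `"raw"`.
#' @return an object of class `curvature_profile`: list with `lon`, `kappa`
#'   and `abs_kappa` matrices `[n_time, n_lon]` (degrees^-1), `time`, and the
#'   convention used.
#' @export
pointwise_curvature <- function(axis,
                                convention = c("ridge_positive", "raw")) {
  convention <- match.arg(convention)
  stopifnot(inherits(axis, "jet_axis"))
  h <- diff(axis$lon)
  if (diff(range(h)) > 1e-9 * mean(h))
    stop("non-uniform longitude spacing")
  h <- h[1]
  y <- axis$lat
  n <- ncol(y)
  ip <- c(2:n, 1L)           # wrap: the hemisphere is zonally periodic
  im <- c(n, 1:(n - 1L))
  yp <- (y[, ip, drop = FALSE] - y[, im, drop = FALSE]) / (2 * h)
  ypp <- (y[, ip, drop = FALSE] - 2 * y + y[, im, drop = FALSE]) / h^2
  kappa <- ypp / (1 + yp^2)^(3 / 2)
  if (convention == "ridge_positive") kappa <- -kappa
  structure(list(lon = axis$lon, kappa = kappa, abs_kappa = abs(kappa),
                 time = axis$time, convention = convention),
            class = "curvature_profile")
}

#' @export
print.curvature_profile <- function(x, ...) {
  cat(sprintf("<curvature_profile> %d time step(s) x %d longitudes (%s)\n",
              nrow(x$kappa), length(x$lon), x$convention))
  invisible(x)
}

#' Absolute curvature
#'
#' Elementwise magnitude of the signed curvature: the degree of bending of
#' the westerlies regardless of direction.
#'
#' @param profile a `curvature_profile`.
#' @return matrix `[n_time, n_lon]` of `|kappa|` in degrees^-1.
#' @export
absolute_curvature <- function(profile) {
  stopifnot(inherits(profile, "curvature_profile"))
  abs(profile$kappa)
}

#' Overall (hemispheric RMS) curvature
#'
#' The waviness index of the whole jet: per time step, the root mean square
#' of the signed curvature across all longitudes,
#' `sqrt(sum(kappa_i^2) / N)`. A smaller value indicates a more zonal, less
#' meandering jet. Anomalies are taken against the mean over a base period
#' (default: the full record).
#'
#' @param profile a `curvature_profile` with at least 2 longitude points.
#' @param baseline indices (into the time axis) of the base period used for
#'   the anomaly; default all time steps.
#' @return data.frame with columns `time`, `value` (degrees^-1, >= 0) and
#'   `anomaly`.
#' @export
overall_curvature <- function(profile, baseline = NULL) {
  stopifnot(inherits(profile, "curvature_profile"))
  if (ncol(profile$kappa) < 2) stop("need at least 2 longitude points")
  v <- sqrt(rowMeans(profile$kappa^2))
  if (is.null(baseline)) baseline <- seq_along(v)
  data.frame(time = profile$time, value = v,
             anomaly = v - mean(v[baseline]))
}

#' Seasonal (default JJA) means of a daily series or profile
#'
#' Averages daily values over June 1 - August 31 of each year (92 days every
#' year, leap or not). Years covering less than `min_coverage` of the season
#' are set to `NA` and flagged. Apply it to daily signed curvature and to
#' daily absolute curvature separately: the order of averaging and absolute
#' value matters (direction cancels in the mean of `kappa`, bending does
#' not in the mean of `|kappa|`).
#'
#' @param x numeric vector (daily series) or matrix `[n_days, p]` (e.g. daily
#'   curvature profiles, one column per longitude).
#' @param dates `Date` vector matching the rows of `x`.
#' @param season months included; default `c(6, 7, 8)` (JJA).
#' @param min_coverage minimum fraction of season days required per year.
#' @return data.frame (vector input) with `year`, `value`, `n_days`,
#'   `complete`; or a list with `year`, `value` matrix `[n_years, p]`,
#'   `n_days`, `complete` for matrix input.
#' @export
seasonal_mean <- function(x, dates, season = c(6L, 7L, 8L),
                          min_coverage = 0.8) {
  stopifnot(inherits(dates, "Date"))
  is_mat <- is.matrix(x)
  if (!is_mat) x <- matrix(x, ncol = 1L)
  if (nrow(x) != length(dates)) stop("dates must match rows of x")
  mo <- as.integer(format(dates, "%m"))
  yr <- as.integer(format(dates, "%Y"))
  in_season <- mo %in% season
  if (!any(in_season)) stop("no days in the requested season")
  # non-leap month lengths; JJA is 92 days in every year
  season_len <- sum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[season])
  years <- sort(unique(yr[in_season]))
  val <- matrix(NA_real_, length(years), ncol(x))
  nd <- integer(length(years))
  for (k in seq_along(years)) {
    sel <- in_season & yr == years[k]
    nd[k] <- sum(sel)
    if (nd[k] >= min_coverage * season_len)
      val[k, ] <- colMeans(x[sel, , drop = FALSE])
  }
  complete <- nd >= min_coverage * season_len
  if (!is_mat)
    return(data.frame(year = years, value = val[, 1], n_days = nd,
                      complete = complete))
  list(year = years, value = val, n_days = nd, complete = complete)
}

#' Longitudinal sector scheme
#'
#' Named longitudinal sectors tiling the full circle, used for regional
#' aggregation of curvature. The default is the eight-sector division of the
#' Northern Hemisphere: Western Europe (WE, 35W-16.5E), Eastern Europe
#' (EE, 16.5E-47E), Central Asia (CA, 47E-80.25E), Eastern Asia
#' (EA, 80.25E-120.5E), Pacific (PA, 120.5E-141.75W), Western North America
#' (WN, 141.75W-106.75W), Central North America (CN, 106.75W-71.75W) and
#' Eastern North America (EN, 71.75W-35W). Bounds are half-open `[west,
#' east)` on the normalised `[0, 360)` circle; a sector with `west > east`
#' wraps across 0.
#'
#' @param name sector names.
#' @param west,east bounds in degrees on `[0, 360)`.
#' @return data.frame of class `sector_scheme`.
#' @export
sector_scheme <- function(name = c("WE", "EE", "CA", "EA",
                                   "PA", "WN", "CN", "EN"),
                          west = c(325, 16.5, 47, 80.25,
                                   120.5, 218.25, 253.25, 288.25),
                          east = c(16.5, 47, 80.25, 120.5,
                                   218.25, 253.25, 288.25, 325)) {
  stopifnot(length(name) == length(west), length(west) == length(east))
  west <- west %% 360; east <- east %% 360
  width <- (east - west) %% 360
  # a proper tiling: widths sum to 360 and every east is some sector's west
  if (abs(sum(width) - 360) > 1e-9 ||
      any(abs(sort(west) - sort(east)) > 1e-9))
    stop("sectors must tile the full circle without overlap")
  structure(data.frame(name = name, west = west, east = east,
                       stringsAsFactors = FALSE),
            class = c("sector_scheme", "data.frame"))
}

#' Per-sector means of a curvature profile (or any per-longitude values)
#'
#' Averages values over the longitudes falling in each sector's half-open
#' `[west, east)` interval, handling sectors that wrap across 0 longitude.
#'
#' @param profile a `curvature_profile`, or a matrix `[n_time, n_lon]`, or a
#'   numeric vector over longitudes.
#' @param scheme a [sector_scheme()].
#' @param lon longitudes (required when `profile` is a bare matrix/vector).
#' @param what for a `curvature_profile`: `"kappa"` (default) or
#'   `"abs_kappa"`.
#' @return matrix `[n_time, n_sector]` with sector names as columns.
#' @export
sector_mean <- function(profile, scheme = sector_scheme(), lon = NULL,
                        what = c("kappa", "abs_kappa")) {
  what <- match.arg(what)
  if (inherits(profile, "curvature_profile")) {
    lon <- profile$lon
    m <- profile[[what]]
  } else {
    if (is.null(lon)) stop("lon required for matrix/vector input")
    m <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1L)
  }
  lon <- lon %% 360
  out <- matrix(NA_real_, nrow(m), nrow(scheme),
                dimnames = list(NULL, scheme$name))
  for (s in seq_len(nrow(scheme))) {
    width <- (scheme$east[s] - scheme$west[s]) %% 360
    inside <- ((lon - scheme$west[s]) %% 360) < width
    if (!any(inside)) stop("empty sector: ", scheme$name[s])
    out[, s] <- rowMeans(m[, inside, drop = FALSE])
  }
  out
}
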