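#' Extract the westerly jet axis from a filtered wind field
#'
#' Per longitude column, the axis latitude is the latitude of maximum zonal
#' wind within 0-90N. The field should already be morphologically filtered
#' (closing then opening, in that order); see [detect_axis()] for the full
#' chain.
#'
#' Values within `tie_tol` of the column maximum count as candidate maxima:
#' filtering flattens the jet core into plateaus of exactly equal values, and
#' wind differences below observational noise do not distinguish latitudes.
#' Among the candidates, continuity with the previous column's axis selects
#' the contiguous candidate run (westernmost column: the run nearest 45N),
#' and the run's central latitude is returned, so a flat plateau does not
#' drag the axis toward its equatorward or poleward edge. A column in which
#' more than half of all latitudes tie with the maximum has no distinct jet
#' and raises an error.
#'
#' @param field a filtered [gridded_field()].
#' @param tie_tol absolute tolerance (field units) within which values count
#'   as tied with the column maximum; the default of 2 suits 200 hPa zonal
#'   wind in m s^-1 (about 8% of a typical jet peak).
#' @return a [jet_axis()].
#' @export
extract_axis <- function(field, tie_tol = 2) {
  stopifnot(inherits(field, "gridded_field"))
  keep <- field$lat >= 0 & field$lat <= 90
  if (!any(keep)) stop("no latitudes in 0-90N: detection is Northern-Hemisphere only")
  lat <- field$lat[keep]
  nt <- dim(field$values)[3]
  nlon <- length(field$lon)
  out <- matrix(NA_real_, nt, nlon)
  for (t in seq_len(nt)) {
    m <- field$values[keep, , t, drop = FALSE]
    ref <- 45
    for (j in seq_len(nlon)) {
      v <- m[, j, 1]
      mx <- max(v)
      tied <- which(v >= mx - tie_tol)
      if (length(tied) > 0.5 * length(v))
        stop(sprintf("no distinct jet at time step %d: >50%% of latitudes tie with the column maximum", t))
      pick <- tied[which.min(abs(lat[tied] - ref))]
      run <- pick                      # contiguous tied run containing pick
      while ((run[1] - 1L) %in% tied) run <- c(run[1] - 1L, run)
      while ((run[length(run)] + 1L) %in% tied) run <- c(run, run[length(run)] + 1L)
      y <- mean(lat[run])
      out[t, j] <- y
      ref <- y
    }
  }
  jet_axis(field$lon, out, field$time)
}

#' Smooth a jet axis with a longitude-periodic moving average
#'
#' The axis is smoothed over a window of approximately `window_km`
#' (default 1000 km) to remove mesoscale disturbances before curvature is
#' computed. The window is converted to grid columns at the 45N reference
#' latitude -- `w = ` nearest odd integer to
#' `window_km / (111.32 * cos(45 deg) * grid_step)` -- giving one
#' deterministic window for all longitudes. The moving average is circular
#' (longitude-periodic).
#'
#' @param axis a [jet_axis()].
#' @param window_km smoothing window length in kilometres (> 0).
#' @return the smoothed [jet_axis()]; the window size in columns is stored in
#'   the `"window_cells"` attribute.
#' @export
smooth_axis <- function(axis, window_km = 1000) {
  stopifnot(inherits(axis, "jet_axis"), window_km > 0)
  step <- diff(axis$lon)[1]
  w0 <- window_km / (111.32 * cos(pi / 4) * step)
  w <- 2L * as.integer(round((w0 - 1) / 2)) + 1L   # nearest odd, >= 1
  if (w < 1L) w <- 1L
  if (w * step > 180)
    stop("smoothing window wider than 180 degrees of longitude")
  sm <- axis
  if (w > 1L) {
    for (t in seq_len(nrow(axis$lat))) {
      sm$lat[t, ] <- as.numeric(
        stats::filter(axis$lat[t, ], rep(1 / w, w), circular = TRUE))
    }
  }
  attr(sm, "window_cells") <- w
  sm
}

#' Full jet-axis detection chain
#'
#' Convenience wrapper running the published sequence: morphological closing,
#' then opening, then per-column argmax axis extraction, then ~1000 km
#' smoothing.
#'
#' @param field a [gridded_field()] of zonal wind.
#' @param elem a [structuring_element()].
#' @param window_km smoothing window (km); `NULL` or `0` to skip smoothing.
#' @param tie_tol tie tolerance passed to [extract_axis()].
#' @return a smoothed [jet_axis()].
#' @export
detect_axis <- function(field, elem = structuring_element(),
                        window_km = 1000, tie_tol = 2) {
  filt <- morph_open(morph_close(field, elem), elem)
  ax <- extract_axis(filt, tie_tol = tie_tol)
  if (!is.null(window_km) && window_km > 0) ax <- smooth_axis(ax, window_km)
  ax
}
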