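#' Specification of a meandering jet axis
#'
#' Describes a zonally periodic jet axis as a base latitude plus a sum of
#' harmonics, optionally drifting in amplitude or phase over time. This is the
#' ground truth that synthetic wind fields are built around and that axis
#' detection and curvature estimates are checked against.
#'
#' @param base_latitude central latitude of the jet, degrees North.
#' @param harmonics list of numeric triples `c(amplitude, wavenumber, phase)`:
#'   amplitude in degrees latitude (>= 0), integer zonal wavenumber in cycles
#'   per 360 degrees longitude (> 0, so the axis is periodic), phase in
#'   radians.
#' @param amplitude_drift degrees per time step added to every amplitude.
#' @param phase_drift radians per time step added to every phase.
#' @return an object of class `jet_axis_spec`.
#' @export
jet_axis_spec <- function(base_latitude = 45,
                          harmonics = list(c(8, 5, 0)),
                          amplitude_drift = 0, phase_drift = 0) {
  stopifnot(length(harmonics) >= 0)
  for (h in harmonics) {
    if (length(h) != 3) stop("each harmonic is c(amplitude, wavenumber, phase)")
    if (h[1] < 0) stop("harmonic amplitude must be >= 0")
    if (h[2] <= 0 || h[2] != round(h[2]))
      stop("wavenumber must be a positive integer (zonal periodicity)")
  }
  amp_sum <- sum(vapply(harmonics, `[`, 0, 1))
  if (base_latitude - amp_sum <= 5 || base_latitude + amp_sum >= 85)
    stop("axis must stay within (5, 85) degrees North for all longitudes")
  structure(list(base_latitude = base_latitude, harmonics = harmonics,
                 amplitude_drift = amplitude_drift, phase_drift = phase_drift),
            class = "jet_axis_spec")
}

#' True axis latitude of a harmonic jet
#'
#' @param spec a [jet_axis_spec()].
#' @param lon longitudes in degrees.
#' @param t time step (1-based; drift accrues as `t - 1`).
#' @return axis latitude in degrees North at each longitude.
#' @export
axis_latitude <- function(spec, lon, t = 1L) {
  y <- rep(spec$base_latitude, length(lon))
  for (h in spec$harmonics) {
    a <- h[1] + spec$amplitude_drift * (t - 1)
    ph <- h[3] + spec$phase_drift * (t - 1)
    y <- y + a * sin(2 * pi * h[2] * lon / 360 + ph)
  }
  y
}

#' Closed-form streamline curvature of a harmonic axis
#'
#' Exact counterpart of the central-difference curvature estimator: for an
#' axis `y(x)` that is a sum of harmonics, the first and second derivatives
#' with respect to longitude are available in closed form, giving
#' `kappa = y'' / (1 + y'^2)^(3/2)` exactly. Under the default ridge-positive
#' convention the sign is flipped so that a northward crest has positive
#' curvature.
#'
#' @inheritParams axis_latitude
#' @param convention `"ridge_positive"` (default; northward bulge positive) or
#'   `"raw"` (the bare differential-geometry formula).
#' @return curvature in degrees^-1 at each longitude.
#' @export
analytic_curvature <- function(spec, lon, t = 1L,
                               convention = c("ridge_positive", "raw")) {
  convention <- match.arg(convention)
  yp <- ypp <- numeric(length(lon))
  for (h in spec$harmonics) {
    a <- h[1] + spec$amplitude_drift * (t - 1)
    ph <- h[3] + spec$phase_drift * (t - 1)
    w <- 2 * pi * h[2] / 360                  # radians per degree longitude
    th <- 2 * pi * h[2] * lon / 360 + ph
    yp <- yp + a * w * cos(th)
    ypp <- ypp - a * w^2 * sin(th)
  }
  kappa <- ypp / (1 + yp^2)^(3 / 2)
  if (convention == "ridge_positive") kappa <- -kappa
  kappa
}

#' Specification of a synthetic zonal-wind field
#'
#' @param jet_peak_speed peak zonal wind at the jet core, m s^-1 (> 0);
#'   default 25, typical of the boreal-summer 200 hPa jet.
#' @param jet_width Gaussian sigma of the meridional jet profile, degrees
#'   latitude (> 0); default 4 (FWHM about 9.4 degrees, a daily jet core).
#' @param noise_sd i.i.d. Gaussian noise per grid cell, m s^-1.
#' @param spurious_patch_rate expected number of spurious high-wind patches
#'   per field (Poisson).
#' @param spurious_patch_speed wind speed assigned inside a patch, m s^-1.
#' @param patch_sides candidate square patch side lengths in cells, sampled
#'   uniformly per patch (default 2 or 3 cells, i.e. 4-9 grid cells).
#' @param grid_step grid spacing in degrees; must divide 360 (and 90);
#'   default 2.5 (the coarsest reanalysis grid in common use).
#' @param n_time number of time steps.
#' @param seed integer seed; fixes the output bit-for-bit.
#' @return an object of class `wind_field_spec`.
#' @export
wind_field_spec <- function(jet_peak_speed = 25, jet_width = 4, noise_sd = 0,
                            spurious_patch_rate = 0, spurious_patch_speed = 35,
                            patch_sides = c(2L, 3L),
                            grid_step = 2.5, n_time = 1L, seed = 1L) {
  stopifnot(jet_peak_speed > 0, jet_width > 0, noise_sd >= 0,
            spurious_patch_rate >= 0, n_time >= 1, all(patch_sides >= 1))
  if (abs(360 / grid_step - round(360 / grid_step)) > 1e-9 ||
      abs(90 / grid_step - round(90 / grid_step)) > 1e-9)
    stop("grid_step must divide both 360 and 90 degrees")
  structure(list(jet_peak_speed = jet_peak_speed, jet_width = jet_width,
                 noise_sd = noise_sd, spurious_patch_rate = spurious_patch_rate,
                 spurious_patch_speed = spurious_patch_speed,
                 patch_sides = as.integer(patch_sides),
                 grid_step = grid_step, n_time = as.integer(n_time),
                 seed = as.integer(seed)),
            class = "wind_field_spec")
}

#' Generate a synthetic zonal-wind field around a known jet axis
#'
#' Builds `u(lat, lon, t) = peak * exp(-(lat - y0(lon, t))^2 / (2 sigma^2))`
#' plus i.i.d. Gaussian noise and, optionally, spurious high-wind patches:
#' square blocks of a few cells placed uniformly at random at off-axis
#' locations (more than 3 sigma from the true axis and within 5-85N, away
#' from the domain's latitude edges where boundary replication would
#' artificially extend them), emulating isolated high-wind turbulence
#' anomalies that morphological opening should remove. The true axis is
#' recorded in the `"true_axis"` attribute; patch locations in `"patches"`.
#'
#' @param axis a [jet_axis_spec()].
#' @param spec a [wind_field_spec()].
#' @return a [gridded_field()] (units m s^-1) with attributes `true_axis`
#'   (matrix `[n_time, n_lon]`) and `patches` (data.frame).
#' @export
generate_wind_field <- function(axis, spec) {
  stopifnot(inherits(axis, "jet_axis_spec"), inherits(spec, "wind_field_spec"))
  lat <- seq(0, 90, by = spec$grid_step)
  lon <- seq(0, 360 - spec$grid_step, by = spec$grid_step)
  nlat <- length(lat); nlon <- length(lon)
  set.seed(spec$seed)
  vals <- array(0, dim = c(nlat, nlon, spec$n_time))
  truth <- matrix(0, spec$n_time, nlon)
  patches <- list()
  for (t in seq_len(spec$n_time)) {
    y0 <- axis_latitude(axis, lon, t)
    if (any(y0 <= 0) || any(y0 >= 90))
      stop("axis leaves (0, 90) degrees North; refusing to generate")
    truth[t, ] <- y0
    u <- spec$jet_peak_speed *
      exp(-outer(lat, y0, function(a, b) (a - b)^2) / (2 * spec$jet_width^2))
    if (spec$noise_sd > 0)
      u <- u + matrix(stats::rnorm(nlat * nlon, sd = spec$noise_sd), nlat, nlon)
    n_patch <- if (spec$spurious_patch_rate > 0)
      stats::rpois(1, spec$spurious_patch_rate) else 0L
    # patches model *isolated* turbulence anomalies: enforce a 5-cell
    # separation so no pair can be bridged by a closing with elements up to
    # 5x5 into a compound larger than the opening element
    occupied <- matrix(FALSE, nlat, nlon)
    for (p in seq_len(n_patch)) {
      for (try in 1:50) {
        side <- if (length(spec$patch_sides) > 1)
          sample(spec$patch_sides, 1) else spec$patch_sides
        j <- sample.int(nlon, 1)
        # turbulence anomalies sit outside the primary westerly belt:
        # exclude 4.5 sigma around the axis so a patch cannot chain to the
        # jet flank through noise under closing
        off_axis <- which(abs(lat - y0[j]) > 4.5 * spec$jet_width &
                            lat >= 5 & lat + (side - 1) * spec$grid_step <= 85)
        if (!length(off_axis)) break
        i <- off_axis[sample.int(length(off_axis), 1)]
        ii <- pmax(1L, pmin(nlat, i + 0:(side - 1L)))
        jj <- ((j + 0:(side - 1L) - 1L) %% nlon) + 1L     # wrap in longitude
        margin <- 5L
        mi <- pmax(1L, min(ii) - margin):pmin(nlat, max(ii) + margin)
        mj <- ((j - margin - 1L + 0:(side - 1L + 2L * margin)) %% nlon) + 1L
        if (any(occupied[mi, mj])) next
        u[ii, jj] <- spec$spurious_patch_speed
        occupied[ii, jj] <- TRUE
        patches[[length(patches) + 1L]] <-
          data.frame(time = t, lat = lat[i], lon = lon[j], side = side)
        break
      }
    }
    vals[, , t] <- u
  }
  out <- gridded_field(vals, lat, lon, units = "m s-1")
  attr(out, "true_axis") <- truth
  attr(out, "patches") <- if (length(patches))
    do.call(rbind, patches) else data.frame()
  out
}

#' Specification of a curvature-productivity coupling
#'
#' @param coefficient productivity units per degree^-1 of curvature.
#' @param noise_sd Gaussian noise sd in productivity units (>= 0).
#' @param plateau_threshold optional driver value above which the coupled
#'   response flattens (piecewise-linear hinge); `NULL` for purely linear.
#' @param fraction_coupled share of grid cells coupled to the index, in
#'   `[0, 1]`.
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(coefficient = 50, noise_sd = 10,
                          plateau_threshold = NULL, fraction_coupled = 1) {
  stopifnot(noise_sd >= 0, fraction_coupled >= 0, fraction_coupled <= 1)
  structure(list(coefficient = coefficient, noise_sd = noise_sd,
                 plateau_threshold = plateau_threshold,
                 fraction_coupled = fraction_coupled),
            class = "coupling_spec")
}

#' Generate a synthetic productivity field coupled to a curvature index
#'
#' A random subset of cells (share `fraction_coupled`) responds linearly to
#' the index -- `coefficient * index + noise`, optionally flattened above
#' `plateau_threshold` -- while the remaining cells are pure noise. The truth
#' mask of coupled cells is recorded in the `"coupled_mask"` attribute.
#'
#' @param index numeric time series driving the coupled cells.
#' @param coupling a [coupling_spec()].
#' @param lat,lon grid coordinates for the output field.
#' @param seed integer seed.
#' @return a [gridded_field()] with attribute `coupled_mask`
#'   (logical `[n_lat, n_lon]`).
#' @export
generate_gpp_field <- function(index, coupling,
                               lat = seq(30, 70, by = 2),
                               lon = seq(0, 358, by = 2), seed = 1L) {
  stopifnot(inherits(coupling, "coupling_spec"))
  nlat <- length(lat); nlon <- length(lon); nt <- length(index)
  set.seed(as.integer(seed))
  ncell <- nlat * nlon
  mask <- matrix(FALSE, nlat, nlon)
  n_coupled <- round(coupling$fraction_coupled * ncell)
  if (n_coupled > 0) mask[sample.int(ncell, n_coupled)] <- TRUE
  drive <- if (!is.null(coupling$plateau_threshold))
    pmin(index, coupling$plateau_threshold) else index
  vals <- array(stats::rnorm(ncell * nt, sd = coupling$noise_sd),
                dim = c(nlat, nlon, nt))
  sig <- coupling$coefficient * drive
  for (t in seq_len(nt)) {
    sl <- vals[, , t]
    sl[mask] <- sl[mask] + sig[t]
    vals[, , t] <- sl
  }
  out <- gridded_field(vals, lat, lon, units = "gC m-2 yr-1")
  attr(out, "coupled_mask") <- mask
  out
}

#' Specification of additive single-forcing ensembles
#'
#' The generator's defining assumption is additivity: the all-forcing
#' response is the sum of the three single-forcing responses, and each
#' fixed-forcing scenario (`XGHG`, `XAER`, `XBMB`) omits exactly one of them.
#' Members add independent Gaussian internal variability.
#'
#' @param response_ghg,response_aer,response_bmb forced-response time series
#'   (curvature units), equal length.
#' @param internal_sd internal-variability sd per member-year.
#' @param members named counts, default `c(ALL = 40, XGHG = 20, XAER = 20,
#'   XBMB = 15)`; each >= 2.
#' @param years year axis (defaults to an index).
#' @param seed integer seed.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(response_ghg, response_aer, response_bmb,
                          internal_sd = 1,
                          members = c(ALL = 40, XGHG = 20, XAER = 20, XBMB = 15),
                          years = NULL, seed = 1L) {
  nt <- length(response_ghg)
  stopifnot(length(response_aer) == nt, length(response_bmb) == nt,
            internal_sd >= 0, all(members >= 2),
            all(c("ALL", "XGHG", "XAER", "XBMB") %in% names(members)))
  if (is.null(years)) years <- seq_len(nt)
  structure(list(response_ghg = response_ghg, response_aer = response_aer,
                 response_bmb = response_bmb, internal_sd = internal_sd,
                 members = members, years = years, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate additive forcing ensembles (ALL, XGHG, XAER, XBMB)
#'
#' @param spec an [ensemble_spec()].
#' @return named list of four [forcing_ensemble()] objects, with the forced
#'   responses recorded in the `"truth"` attribute.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  nt <- length(spec$years)
  forced <- list(
    ALL  = spec$response_ghg + spec$response_aer + spec$response_bmb,
    XGHG = spec$response_aer + spec$response_bmb,   # GHG held fixed
    XAER = spec$response_ghg + spec$response_bmb,
    XBMB = spec$response_ghg + spec$response_aer)
  out <- lapply(names(forced), function(sc) {
    m <- spec$members[[sc]]
    noise <- matrix(stats::rnorm(m * nt, sd = spec$internal_sd), m, nt)
    forcing_ensemble(sc, sweep(noise, 2, forced[[sc]], `+`), spec$years)
  })
  names(out) <- names(forced)
  attr(out, "truth") <- list(ghg = spec$response_ghg, aer = spec$response_aer,
                             bmb = spec$response_bmb, forced = forced)
  out
}
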