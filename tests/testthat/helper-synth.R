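# shared builders for synthetic fixtures (all generated in code, no files)

harmonic_axis_spec <- function(A = 5, k = 6, phase = 0, base = 45, ...) {
  jet_axis_spec(base, list(c(A, k, phase)), ...)
}

# axis object sampled from a spec on a regular longitude grid
sampled_axis <- function(spec, step = 0.25, t = 1L) {
  lon <- seq(0, 360 - step, by = step)
  jet_axis(lon, axis_latitude(spec, lon, t))
}

# minimal flat field with a single bright pixel, for opening tests
one_pixel_field <- function(nlat = 11, nlon = 20, bg = 10, hot = 30,
                            i = 6, j = 10) {
  m <- matrix(bg, nlat, nlon)
  m[i, j] <- hot
  gridded_field(m, lat = seq(0, 90, length.out = nlat),
                lon = seq(0, 360 - 360 / nlon, length.out = nlon),
                units = "m s-1")
}

random_field <- function(seed, nlat = 19, nlon = 36) {
  set.seed(seed)
  gridded_field(matrix(rnorm(nlat * nlon, 10, 4), nlat, nlon),
                lat = seq(0, 90, length.out = nlat),
                lon = seq(0, 360 - 360 / nlon, length.out = nlon),
                units = "m s-1")
}

# additive 51-year forcing ensembles with GHG:AER:BMB shares of total change
shares_ensemble_spec <- function(total = 2, shares = c(0.7, 0.2, 0.1),
                                 internal_sd = 0.2, seed = 1L,
                                 members = c(ALL = 40, XGHG = 20,
                                             XAER = 20, XBMB = 15)) {
  tt <- seq(0, 1, length.out = 51)
  ensemble_spec(response_ghg = total * shares[1] * tt,
                response_aer = total * shares[2] * tt,
                response_bmb = total * shares[3] * tt,
                internal_sd = internal_sd, members = members,
                years = 2030:2080, seed = seed)
}
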