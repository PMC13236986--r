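test_that("a zonal axis has exactly zero curvature", {
  lon <- seq(0, 359, 1)
  prof <- pointwise_curvature(jet_axis(lon, rep(45, length(lon))))
  expect_true(all(abs(prof$kappa) < 1e-12))
  expect_true(all(prof$abs_kappa == abs(prof$kappa)))
})

test_that("a circular-arc crest of radius 10 degrees has curvature +0.1", {
  step <- 0.25
  lon <- seq(0, 360 - step, step)
  R <- 10; x0 <- 180
  y <- rep(40, length(lon))
  arc <- abs(lon - x0) < R
  y[arc] <- 40 + sqrt(R^2 - (lon[arc] - x0)^2) - R + 10  # crest at 50N
  prof <- pointwise_curvature(jet_axis(lon, y))
  expect_equal(prof$kappa[1, lon == x0], 0.1, tolerance = 1e-3)
})

test_that("crests are positive and troughs negative under the ridge convention", {
  axs <- harmonic_axis_spec(A = 5, k = 6, phase = 0.7)
  a <- sampled_axis(axs, step = 0.5)
  prof <- pointwise_curvature(a)
  y <- a$lat[1, ]
  n <- length(y)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  crest <- y > y[ip] & y > y[im]
  trough <- y < y[ip] & y < y[im]
  expect_true(all(prof$kappa[1, crest] > 0))
  expect_true(all(prof$kappa[1, trough] < 0))
  # raw mode flips the sign
  expect_equal(pointwise_curvature(a, convention = "raw")$kappa, -prof$kappa)
})

test_that("central-difference curvature converges to the closed form", {
  axs <- harmonic_axis_spec(A = 5, k = 6)
  err <- sapply(c(1, 0.5, 0.25), function(h) {
    a <- sampled_axis(axs, step = h)
    k_hat <- pointwise_curvature(a)$kappa[1, ]
    k_true <- analytic_curvature(axs, a$lon)
    max(abs(k_hat - k_true))
  })
  peak <- 5 * (2 * pi / 60)^2
  expect_lt(err[3], 0.02 * peak)
  expect_true(all(diff(err) < 0))          # monotone under refinement
})

test_that("curvature commutes with rolling the axis", {
  axs <- harmonic_axis_spec(A = 4, k = 4, phase = 1.1)
  a <- sampled_axis(axs, step = 1)
  k0 <- pointwise_curvature(a)$kappa[1, ]
  idx <- ((seq_along(a$lon) - 1 + 50) %% length(a$lon)) + 1
  ar <- jet_axis(a$lon, a$lat[1, idx])
  expect_equal(pointwise_curvature(ar)$kappa[1, ], k0[idx], tolerance = 1e-12)
})

test_that("overall curvature is the RMS with its defining properties", {
  lon <- seq(0, 350, 10)
  mk_prof <- function(k) pointwise_curvature(jet_axis(lon, rep(45, 36)))
  prof <- mk_prof(0)
  # direct arithmetic cases
  prof$kappa <- matrix(3e-5, 1, 36)
  expect_equal(overall_curvature(prof)$value, 3e-5)
  prof$kappa <- matrix(rep(c(3e-5, 4e-5), 18), 1)
  expect_equal(overall_curvature(prof)$value, sqrt(12.5) * 1e-5)
  prof$kappa <- 2 * prof$kappa
  expect_equal(overall_curvature(prof)$value, 2 * sqrt(12.5) * 1e-5)

  # RMS >= |mean| for arbitrary profiles; equality iff constant
  set.seed(3)
  for (i in 1:5) {
    prof$kappa <- matrix(rnorm(36, sd = 1e-4), 1)
    oc <- overall_curvature(prof)
    expect_gte(oc$value, abs(mean(prof$kappa)))
  }

  # anomaly against a chosen baseline
  prof$kappa <- matrix(rnorm(36 * 4, sd = 1e-4), 4, 36)
  prof$time <- 1:4
  oc <- overall_curvature(prof, baseline = 1:2)
  expect_equal(mean(oc$anomaly[1:2]), 0)
})

test_that("seasonal means separate signed and absolute curvature correctly", {
  dates <- seq(as.Date("1979-01-01"), as.Date("1980-12-31"), by = "day")
  x <- rep(0, length(dates))
  jja <- as.integer(format(dates, "%m")) %in% 6:8
  # alternating +c/-c within the season: signed mean 0, absolute mean c
  x[jja] <- rep(c(2e-4, -2e-4), length.out = sum(jja))
  sm <- seasonal_mean(x, dates)
  expect_equal(sm$n_days, c(92L, 92L))       # 1980 is a leap year: still 92
  expect_equal(sm$value, c(0, 0))
  sm_abs <- seasonal_mean(abs(x), dates)
  expect_equal(sm_abs$value, c(2e-4, 2e-4))

  # constant series and coverage flagging
  sm_c <- seasonal_mean(rep(7, length(dates)), dates)
  expect_equal(sm_c$value, c(7, 7))
  short <- dates[dates <= as.Date("1979-07-10")]
  sm_s <- seasonal_mean(rep(1, length(short)), short)
  expect_false(sm_s$complete[1])
  expect_true(is.na(sm_s$value[1]))
})

test_that("sector means respect the eight-sector tiling and the 0-wrap", {
  sch <- sector_scheme()
  expect_equal(sum(((sch$east - sch$west) %% 360)), 360)
  lon <- seq(0, 359.75, 0.25)
  # piecewise-constant profile: each sector's constant is recovered exactly
  vals <- rep(NA_real_, length(lon))
  for (s in seq_len(nrow(sch))) {
    width <- (sch$east[s] - sch$west[s]) %% 360
    inside <- ((lon - sch$west[s]) %% 360) < width
    vals[inside] <- s * 1e-5
  }
  expect_false(anyNA(vals))                 # tiling covers every longitude
  sm <- sector_mean(vals, sch, lon = lon)
  expect_equal(as.numeric(sm), (1:8) * 1e-5)

  # uniform profile: every sector mean equals the constant, including the
  # WE sector that wraps across 0 longitude
  smu <- sector_mean(rep(3e-5, length(lon)), sch, lon = lon)
  expect_true(all(smu == 3e-5))

  expect_error(sector_scheme(c("A", "B"), c(0, 100), c(100, 250)), "tile")
})
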