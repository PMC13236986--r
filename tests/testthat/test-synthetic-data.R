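test_that("noise-free wind field peaks on the analytic axis and is seed-reproducible", {
  spec <- wind_field_spec(noise_sd = 0, grid_step = 2.5, seed = 11)
  axs <- harmonic_axis_spec()
  f1 <- generate_wind_field(axs, spec)
  f2 <- generate_wind_field(axs, spec)
  expect_identical(f1$values, f2$values)

  truth <- attr(f1, "true_axis")[1, ]
  argmax_lat <- f1$lat[apply(f1$values[, , 1], 2, which.max)]
  expect_true(all(abs(argmax_lat - truth) <= 2.5))
})

test_that("spurious patches displace the raw argmax but not the recorded truth", {
  axs <- harmonic_axis_spec()
  clean <- generate_wind_field(axs, wind_field_spec(noise_sd = 0, seed = 3))
  patchy <- generate_wind_field(axs, wind_field_spec(noise_sd = 0, seed = 3,
                                                     spurious_patch_rate = 6))
  expect_identical(attr(clean, "true_axis"), attr(patchy, "true_axis"))
  patches <- attr(patchy, "patches")
  expect_gt(nrow(patches), 0)
  # brute-force argmax on the raw array deviates at patched longitudes
  # (patch speed 35 exceeds the jet peak 25)
  am <- patchy$lat[apply(patchy$values[, , 1], 2, which.max)]
  truth <- attr(patchy, "true_axis")[1, ]
  jbad <- match(patches$lon, patchy$lon)
  expect_true(all(abs(am[jbad] - truth[jbad]) > 2.5))
  # patches sit inside 5-85N so boundary replication cannot extend them
  expect_true(all(patches$lat >= 5 & patches$lat <= 85))
})

test_that("axis generation rejects an axis leaving the hemisphere interior", {
  expect_error(jet_axis_spec(45, list(c(45, 3, 0))), "within \\(5, 85\\)")
  drifting <- jet_axis_spec(45, list(c(30, 3, 0)), amplitude_drift = 5)
  expect_error(
    generate_wind_field(drifting, wind_field_spec(noise_sd = 0, n_time = 5)),
    "leaves")
})

test_that("closed-form curvature matches its oracle and scales with amplitude", {
  lon <- seq(0, 359.99, by = 0.01)
  # zero harmonics: straight zonal axis
  flat <- jet_axis_spec(45, list())
  expect_true(all(analytic_curvature(flat, lon) == 0))

  axs <- harmonic_axis_spec(A = 5, k = 6)   # wavelength 60 degrees
  k <- analytic_curvature(axs, lon)
  # crest value A (2 pi / L)^2, ridge-positive
  expect_equal(max(k), 5 * (2 * pi / 60)^2, tolerance = 1e-6)

  # dense central differences on the sampled axis agree to < 0.1% of peak
  y <- axis_latitude(axs, lon)
  h <- 0.01
  n <- length(y)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  yp <- (y[ip] - y[im]) / (2 * h)
  ypp <- (y[ip] - 2 * y + y[im]) / h^2
  k_fd <- -ypp / (1 + yp^2)^(3 / 2)
  expect_lt(max(abs(k_fd - k)), 1e-3 * max(abs(k)))

  # halving the amplitude halves the crest curvature (small-slope regime)
  half <- harmonic_axis_spec(A = 2.5, k = 6)
  expect_equal(max(analytic_curvature(half, lon)) / max(k), 0.5,
               tolerance = 0.02)

  # raw mode is the exact negative of ridge-positive
  expect_equal(analytic_curvature(axs, lon, convention = "raw"), -k)
})

test_that("coupled productivity cells correlate with the index as prescribed", {
  idx <- as.numeric(scale(sin(1:37) + cos(3 * (1:37))))
  # noise-free coupled cell: perfect correlation
  f0 <- generate_gpp_field(idx, coupling_spec(coefficient = 10, noise_sd = 0,
                                              fraction_coupled = 1), seed = 2)
  mask <- attr(f0, "coupled_mask")
  expect_true(all(mask))
  cell <- f0$values[1, 1, ]
  expect_equal(cor(cell, idx), 1)

  # plateau flattening weakens the simple linear correlation
  set.seed(9)
  fp <- generate_gpp_field(idx, coupling_spec(coefficient = 10, noise_sd = 5,
                                              plateau_threshold = 0.3),
                           seed = 31)
  fl <- generate_gpp_field(idx, coupling_spec(coefficient = 10, noise_sd = 5),
                           seed = 31)
  r_plateau <- mean(abs(apply(matrix(fp$values, ncol = 37), 1, cor, y = idx)))
  r_linear <- mean(abs(apply(matrix(fl$values, ncol = 37), 1, cor, y = idx)))
  expect_lt(r_plateau, r_linear)
})

test_that("uncoupled fields yield ~5% nominally significant cells", {
  idx <- rnorm(40)
  f <- generate_gpp_field(rnorm(40), coupling_spec(fraction_coupled = 0,
                                                   noise_sd = 1),
                          lat = seq(30, 69, 1), lon = seq(0, 359, 1.5),
                          seed = 77)
  cm <- correlate_index_field(f, idx)
  expect_lt(abs(mean(cm$sig) - 0.05), 0.015)
})

test_that("forcing ensembles are additive with the target forcing removed", {
  # zero internal variability: members identical, spread zero
  spec0 <- shares_ensemble_spec(internal_sd = 0, seed = 5)
  ens0 <- generate_ensemble(spec0)
  ms <- ensemble_mean_spread(ens0$ALL)
  expect_true(all(ms$sd == 0))
  expect_equal(ens0$ALL$members[1, ], ens0$ALL$members[40, ])
  truth <- attr(ens0, "truth")
  expect_equal(unname(ens0$ALL$members[1, ]),
               truth$ghg + truth$aer + truth$bmb)
  expect_equal(unname(ens0$XGHG$members[1, ]), truth$aer + truth$bmb)

  # noisy case: ALL minus XGHG ensemble means recover the GHG response
  spec1 <- shares_ensemble_spec(internal_sd = 0.2, seed = 6)
  ens1 <- generate_ensemble(spec1)
  diffm <- colMeans(ens1$ALL$members) - colMeans(ens1$XGHG$members)
  se <- 0.2 * sqrt(1 / 40 + 1 / 20)
  truth1 <- attr(ens1, "truth")
  expect_lt(mean(abs(diffm - truth1$ghg)), 3 * se)
})
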