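test_that("linear_trend matches lm and recovers exact lines", {
  tr <- linear_trend(2 * (1:20) + 5)
  expect_equal(tr$slope, 2)
  expect_lt(tr$p, 1e-12)

  set.seed(1)
  y <- 0.3 * (1:30) + rnorm(30)
  fit <- summary(lm(y ~ x, data = data.frame(x = 1:30)))
  tr <- linear_trend(y)
  expect_equal(tr$slope, fit$coefficients[2, 1])
  expect_equal(tr$se, fit$coefficients[2, 2])
  expect_equal(tr$p, fit$coefficients[2, 4])
  ci <- confint(lm(y ~ x, data = data.frame(x = 1:30)))[2, ]
  expect_equal(unname(tr$ci), unname(ci))

  # constant series: zero slope, undefined p, flagged
  trc <- linear_trend(rep(4, 10))
  expect_equal(trc$slope, 0)
  expect_true(trc$degenerate)
  expect_true(is.na(trc$p))

  # AR(1) adjustment widens the standard error for persistent residuals
  set.seed(2)
  e <- as.numeric(stats::filter(rnorm(200), 0.7, method = "recursive"))
  y <- 0.01 * (1:200) + e
  expect_gt(linear_trend(y, ar1_adjust = TRUE)$se, linear_trend(y)$se)
})

test_that("detrending zeroes lines, is idempotent and orthogonal to time", {
  expect_equal(detrend_series(3 * (1:15) - 2), rep(0, 15))
  set.seed(4)
  y <- rnorm(40) + 0.2 * (1:40)
  r <- detrend_series(y)
  expect_equal(mean(r), 0)
  expect_equal(sum(r * (1:40)), 0, tolerance = 1e-9)
  expect_equal(detrend_series(r), r)
})

test_that("epoch anomalies measure a step change against the baseline", {
  yrs <- 1979:2022
  expect_equal(epoch_anomalies(rep(5, 44), yrs)$anomaly, c(0, 0))

  a <- 1.5
  y <- ifelse(yrs < 2000, -a, a)           # 21 early, 23 late years
  base <- (21 * (-a) + 23 * a) / 44        # length-weighted baseline
  ea <- epoch_anomalies(y, yrs, epochs = list(c(1979, 1999), c(2000, 2022)))
  expect_equal(ea$anomaly, c(-a - base, a - base))

  whole <- epoch_anomalies(y, yrs, epochs = list(c(1979, 2022)))
  expect_equal(whole$anomaly, 0)
  expect_error(epoch_anomalies(y, yrs, epochs = list(c(1900, 1910))), "empty")
})

test_that("correlation maps separate real coupling from shared trends", {
  idx <- as.numeric(scale(rnorm(37) + 0.1 * (1:37)))
  lat <- seq(40, 48, 4); lon <- seq(0, 300, 60)
  # exact proportionality: r = 1
  vals <- array(0, c(3, 6, 37))
  for (t in 1:37) vals[, , t] <- 3 * idx[t]
  f <- gridded_field(vals, lat, lon)
  cm <- correlate_index_field(f, idx)
  expect_true(all(abs(cm$r - 1) < 1e-12))
  expect_true(all(cm$sig))

  # trend-only coupling: raw r large, detrended r near zero
  set.seed(6)
  tt <- 1:37
  idx2 <- tt + rnorm(37, sd = 1)
  vals2 <- array(rnorm(3 * 6 * 37, sd = 1), c(3, 6, 37))
  for (t in 1:37) vals2[, , t] <- vals2[, , t] + 2 * tt[t]
  f2 <- gridded_field(vals2, lat, lon)
  raw <- correlate_index_field(f2, idx2)
  det <- correlate_index_field(f2, idx2, detrend_first = TRUE)
  expect_gt(min(raw$r), 0.9)
  expect_lt(max(abs(det$r)), 0.6)
  # correlation is invariant to affine rescaling of the index
  resc <- correlate_index_field(f2, 10 * idx2 - 4)
  expect_equal(resc$r, raw$r, tolerance = 1e-12)
})

test_that("index regression returns exact coefficients and standardization", {
  idx <- rnorm(30)
  tgt <- cbind(2 * idx, -0.5 * idx + rnorm(30, sd = 1e-8))
  fit <- regress_index_field(tgt, idx, standardize = FALSE)
  expect_equal(fit$coef, c(2, -0.5), tolerance = 1e-6)
  # standardized mode invariant to index rescaling
  f1 <- regress_index_field(tgt, idx, standardize = TRUE)
  f2 <- regress_index_field(tgt, 10 * idx, standardize = TRUE)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_error(regress_index_field(tgt, rep(1, 30)), "zero-variance")
})

test_that("land-use stratification orders |r| by coupling strength", {
  set.seed(11)
  idx <- as.numeric(scale(rnorm(37)))
  lat <- seq(40, 59, 1); lon <- seq(0, 358, 2)
  managed <- matrix(rep(c(0.9, 0.1), length.out = 20 * 180), 20, 180)
  natural <- 1 - managed
  coefs <- ifelse(managed > 0.5, 2, 10)    # weaker coupling on managed land
  vals <- array(rnorm(20 * 180 * 37, sd = 10), c(20, 180, 37))
  for (t in 1:37) vals[, , t] <- vals[, , t] + coefs * idx[t]
  cm <- correlate_index_field(gridded_field(vals, lat, lon), idx)
  st <- stratify_by_landuse(cm, managed, natural)
  expect_lt(st$mean_abs_r[["managed"]], st$mean_abs_r[["natural"]])
  expect_lt(st$test$p.value, 0.05)
  # all cells managed: natural class empty
  expect_error(stratify_by_landuse(cm, matrix(1, 20, 180), matrix(0, 20, 180)),
               "natural class empty")
})

test_that("binned response finds a hinge and flags its absence", {
  set.seed(21)
  x <- runif(2000, 10, 28)
  # hinge at 19: rise then plateau
  y <- 5 * pmin(x, 19) + rnorm(2000, sd = 1)
  rc <- binned_response(y, x, n_bins = 18)
  expect_true(rc$identified)
  expect_lt(abs(rc$breakpoint - 19), 1 + 1e-9)
  expect_equal(rc$slope_low, 5, tolerance = 0.1)
  expect_equal(rc$slope_high, 0, tolerance = 0.1)

  # exact line: slopes equal, breakpoint unidentified
  rl <- binned_response(2 * x + 1, x, n_bins = 10)
  expect_false(rl$identified)
  expect_true(is.na(rl$breakpoint))
  expect_equal(rl$slope_low, rl$slope_high, tolerance = 1e-8)

  # constant response: both slopes zero
  rc0 <- binned_response(rep(3, 2000), x, n_bins = 10)
  expect_equal(rc0$slope_low, 0, tolerance = 1e-10)
  expect_equal(rc0$slope_high, 0, tolerance = 1e-10)
  expect_error(binned_response(y, rep(1, 2000)), "degenerate")
})
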