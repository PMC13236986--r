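# Closed-form simple OLS of y on x: returns slope, intercept, se, df.
# Used everywhere a plain linear fit is needed; cross-checked against lm()
# in the test suite.
.ols <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 finite points")
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("degenerate predictor (zero variance)")
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  df <- n - 2L
  s2 <- sum(res^2) / df
  list(slope = slope, intercept = intercept, se = sqrt(s2 / sxx),
       residuals = res, n = n, df = df, x = x)
}

#' Linear trend of an annual series
#'
#' Ordinary-least-squares slope against year with a two-sided t-test and 95%
#' confidence interval. With `ar1_adjust = TRUE` the standard error and
#' degrees of freedom are adjusted for lag-1 autocorrelation of the
#' residuals via the effective sample size `n_eff = n (1 - r1) / (1 + r1)`.
#'
#' @param y annual values (>= 3 finite points).
#' @param year time axis; defaults to `seq_along(y)`.
#' @param conf confidence level for the interval.
#' @param ar1_adjust adjust inference for AR(1) residual autocorrelation.
#' @return an object of class `trend_result`: list with `slope` (per year),
#'   `se`, `p` (two-sided; `NA` with `degenerate = TRUE` for a constant
#'   series), `ci`, `intercept`, `n`.
#' @export
linear_trend <- function(y, year = seq_along(y), conf = 0.95,
                         ar1_adjust = FALSE) {
  fit <- .ols(y, year)
  degenerate <- sum(fit$residuals^2) < 1e-24 * max(1, mean(y[is.finite(y)])^2) &&
    abs(fit$slope) < 1e-15
  se <- fit$se; df <- fit$df
  if (ar1_adjust && df > 2) {
    r <- fit$residuals
    r1 <- sum(r[-1] * r[-length(r)]) / sum(r^2)
    r1 <- max(min(r1, 0.99), -0.99)
    neff <- fit$n * (1 - r1) / (1 + r1)
    if (neff > 3) {
      se <- se * sqrt(df / (neff - 2))
      df <- neff - 2
    }
  }
  if (degenerate || se == 0) {
    p <- if (fit$slope == 0) NA_real_ else 0
    ci <- c(fit$slope, fit$slope)
  } else {
    tval <- fit$slope / se
    p <- 2 * stats::pt(-abs(tval), df)
    q <- stats::qt(1 - (1 - conf) / 2, df)
    ci <- fit$slope + c(-1, 1) * q * se
  }
  structure(list(slope = fit$slope, se = se, p = p, ci = ci,
                 intercept = fit$intercept, n = fit$n,
                 degenerate = isTRUE(degenerate)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result> slope %.4g / yr (se %.3g, p %.3g), 95%% CI [%.4g, %.4g], n=%d\n",
              x$slope, x$se, x$p, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Remove the linear trend from a series
#'
#' Residuals of the OLS fit on time; mean zero and orthogonal to time.
#' `NA`s are preserved in place.
#'
#' @inheritParams linear_trend
#' @return numeric vector of residuals, same length as `y`.
#' @export
detrend_series <- function(y, year = seq_along(y)) {
  ok <- is.finite(y) & is.finite(year)
  fit <- .ols(y, year)
  out <- rep(NA_real_, length(y))
  out[ok] <- y[ok] - fit$intercept - fit$slope * year[ok]
  out
}

#' Epoch mean anomalies of an annual series
#'
#' Mean over each epoch minus the mean over a baseline period -- the
#' epoch-reversal diagnostic (e.g. 1979-1999 vs 2000-2023 anomalies relative
#' to the 1979-2023 mean).
#'
#' @param y annual values.
#' @param year years matching `y`.
#' @param epochs list of `c(first, last)` year pairs (inclusive).
#' @param baseline `c(first, last)` years of the baseline; default the full
#'   record.
#' @return data.frame with `first`, `last`, `mean`, `anomaly` per epoch.
#' @export
epoch_anomalies <- function(y, year = seq_along(y),
                            epochs = list(c(1979, 1999), c(2000, 2023)),
                            baseline = range(year)) {
  base <- y[year >= baseline[1] & year <= baseline[2]]
  if (!length(base)) stop("empty baseline period")
  b <- mean(base, na.rm = TRUE)
  res <- lapply(epochs, function(e) {
    v <- y[year >= e[1] & year <= e[2]]
    if (!length(v) || all(!is.finite(v))) stop("empty epoch ", e[1], "-", e[2])
    m <- mean(v, na.rm = TRUE)
    data.frame(first = e[1], last = e[2], mean = m, anomaly = m - b)
  })
  do.call(rbind, res)
}

#' Correlation map between a gridded field and an index series
#'
#' Per-cell Pearson correlation between the field's time series and the
#' index, with a two-sided t-test and a significance mask at `1 - conf`.
#' With `detrend_first = TRUE` both the cell series and the index are
#' linearly detrended before correlating, isolating interannual covariability
#' from shared trends. Cells with missing values are correlated on their
#' complete years (cellwise tolerance).
#'
#' @param field a [gridded_field()] with time as the third dimension.
#' @param index numeric series, one value per field time step.
#' @param detrend_first detrend both sides first.
#' @param conf confidence level for the mask (default 0.95).
#' @param fdr apply Benjamini-Hochberg adjustment to the p-values before
#'   masking (off by default: per-cell masking).
#' @return an object of class `correlation_map`: list with matrices `r`, `p`,
#'   `sig` (`[n_lat, n_lon]`), the coordinates, and `n` used per cell.
#' @export
correlate_index_field <- function(field, index, detrend_first = FALSE,
                                  conf = 0.95, fdr = FALSE) {
  stopifnot(inherits(field, "gridded_field"))
  nt <- dim(field$values)[3]
  if (length(index) != nt) stop("index length must match field time steps")
  if (nt < 3) stop("need at least 3 common time steps")
  d <- dim(field$values)
  cells <- matrix(aperm(field$values, c(3, 1, 2)), nrow = nt)  # time x cell
  idx <- index
  if (detrend_first) idx <- detrend_series(idx)
  r <- rep(NA_real_, ncol(cells)); nn <- rep(NA_integer_, ncol(cells))
  complete <- colSums(!is.finite(cells)) == 0 & all(is.finite(idx))
  if (any(complete)) {
    cc <- cells[, complete, drop = FALSE]
    if (detrend_first) {
      tt <- seq_len(nt)
      X <- cbind(1, tt)
      cc <- cc - X %*% qr.solve(X, cc)     # columnwise OLS detrend
    }
    r[complete] <- as.numeric(stats::cor(idx, cc))
    nn[complete] <- nt
  }
  for (j in which(!complete)) {
    ok <- is.finite(cells[, j]) & is.finite(idx)
    if (sum(ok) < 3) next
    yi <- cells[ok, j]; xi <- idx[ok]
    if (detrend_first) yi <- detrend_series(yi, which(ok))
    if (stats::sd(yi) == 0 || stats::sd(xi) == 0) next
    r[j] <- stats::cor(xi, yi)
    nn[j] <- sum(ok)
  }
  dfree <- nn - 2L
  tval <- r * sqrt(dfree / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), dfree)
  padj <- if (fdr) stats::p.adjust(p, method = "BH") else p
  alpha <- 1 - conf
  dim(r) <- dim(p) <- d[1:2]
  padj_m <- matrix(padj, d[1], d[2])
  structure(list(r = r, p = p, sig = !is.na(padj_m) & padj_m < alpha,
                 lat = field$lat, lon = field$lon,
                 n = matrix(nn, d[1], d[2]), conf = conf,
                 detrended = detrend_first, fdr = fdr),
            class = "correlation_map")
}

#' Regression of per-cell / per-longitude targets on an index
#'
#' OLS coefficient of each target series on the index, with a two-sided
#' t-test at `1 - conf`. With `standardize = TRUE` (default) the index is
#' z-scored first, so coefficients are the response per standard deviation
#' of the index and are invariant to affine rescaling of the index. Serves
#' both the local-curvature-onto-overall-curvature regression (targets =
#' columns of a curvature matrix) and index-onto-gridded-field regression.
#'
#' @param targets matrix `[n_time, p]`, a numeric vector, or a
#'   [gridded_field()].
#' @param index numeric series over the same time steps (non-zero variance).
#' @param standardize z-score the index before regressing.
#' @param conf confidence level for the significance mask.
#' @return list with `coef`, `se`, `p`, `sig` (length p, or matrices for a
#'   gridded field input).
#' @export
regress_index_field <- function(targets, index, standardize = TRUE,
                                conf = 0.95) {
  gridded <- inherits(targets, "gridded_field")
  if (gridded) {
    d <- dim(targets$values)
    m <- matrix(aperm(targets$values, c(3, 1, 2)), nrow = d[3])
  } else m <- if (is.matrix(targets)) targets else matrix(targets, ncol = 1)
  nt <- nrow(m)
  if (length(index) != nt) stop("index length must match target time steps")
  if (stats::sd(index) == 0) stop("zero-variance index")
  x <- if (standardize) as.numeric(scale(index)) else index
  mx <- mean(x); sxx <- sum((x - mx)^2)
  xc <- x - mx
  cf <- as.numeric(crossprod(xc, sweep(m, 2, colMeans(m))) / sxx)
  res <- m - outer(rep(1, nt), colMeans(m)) - outer(xc, cf)
  s2 <- colSums(res^2) / (nt - 2)
  se <- sqrt(s2 / sxx)
  tval <- cf / se
  p <- 2 * stats::pt(-abs(tval), nt - 2)
  sig <- p < (1 - conf)
  if (gridded) {
    shp <- d[1:2]
    list(coef = matrix(cf, shp[1], shp[2]), se = matrix(se, shp[1], shp[2]),
         p = matrix(p, shp[1], shp[2]), sig = matrix(sig, shp[1], shp[2]))
  } else list(coef = cf, se = se, p = p, sig = sig)
}

#' Stratify curvature-productivity correlations by land use
#'
#' Classifies each cell as managed (cropland + urban fraction exceeds the
#' natural fraction) or natural, then compares the mean absolute correlation
#' `|r|` between the classes with a two-sample Welch t-test. Used to ask
#' whether human land management buffers the circulation signal.
#'
#' @param corr_map a `correlation_map` from [correlate_index_field()].
#' @param managed_frac matrix of cropland + urban fractions in `[0, 1]`.
#' @param natural_frac matrix of primary + secondary forest fractions.
#' @param cells optional logical matrix restricting the comparison to a
#'   region of interest.
#' @return list with `mean_abs_r` (named: managed, natural), `n` per class,
#'   and `test` (the `htest` from [stats::t.test()]).
#' @export
stratify_by_landuse <- function(corr_map, managed_frac, natural_frac,
                                cells = NULL) {
  stopifnot(inherits(corr_map, "correlation_map"))
  if (any(managed_frac < 0 | managed_frac > 1, na.rm = TRUE) ||
      any(natural_frac < 0 | natural_frac > 1, na.rm = TRUE))
    stop("land-use fractions must lie in [0, 1]")
  use <- is.finite(corr_map$r)
  if (!is.null(cells)) use <- use & cells
  managed <- managed_frac > natural_frac
  a <- abs(corr_map$r)[use & managed]
  b <- abs(corr_map$r)[use & !managed]
  if (!length(a)) stop("managed class empty within the region")
  if (!length(b)) stop("natural class empty within the region")
  list(mean_abs_r = c(managed = mean(a), natural = mean(b)),
       n = c(managed = length(a), natural = length(b)),
       test = stats::t.test(a, b))
}

#' Binned response curve with a piecewise-linear (hinge) fit
#'
#' Bins the driver into `n_bins` equal-width bins, reports the bin-mean
#' response, and fits a continuous two-segment linear model
#' `y = a + b1 x + b2 max(x - c, 0)` by least squares, searching the
#' breakpoint `c` over the interior bin edges. Captures threshold behaviour
#' such as productivity increasing with maximum temperature up to an optimum
#' and then stabilising. The breakpoint is flagged unidentified when the
#' hinge term is not significant at 95% (e.g. for a purely linear response).
#'
#' @param response numeric response series.
#' @param driver numeric driver series, same length; needs at least
#'   `5 * n_bins` complete pairs and a non-degenerate range.
#' @param n_bins number of equal-width bins (default 20).
#' @return an object of class `response_curve`: list with `bin_center`,
#'   `bin_mean`, `bin_n`, `breakpoint`, `slope_low`, `slope_high`,
#'   `identified`, `p_hinge`.
#' @export
binned_response <- function(response, driver, n_bins = 20L) {
  ok <- is.finite(response) & is.finite(driver)
  y <- response[ok]; x <- driver[ok]
  if (length(y) < 5 * n_bins)
    stop("need at least 5 observations per bin")
  rng <- range(x)
  if (diff(rng) == 0) stop("degenerate driver range")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(x, edges, include.lowest = TRUE, labels = FALSE)
  bin_mean <- tapply(y, factor(bin, levels = seq_len(n_bins)), mean)
  bin_n <- tapply(y, factor(bin, levels = seq_len(n_bins)), length)
  bin_n[is.na(bin_n)] <- 0L
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  cand <- edges[2:n_bins]                       # interior edges only
  best <- NULL
  for (b in cand) {
    X <- cbind(1, x, pmax(x - b, 0))
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss)
      best <- list(b = b, rss = rss, coef = fit$coefficients, X = X,
                   res = fit$residuals)
  }
  cf <- best$coef
  df <- length(y) - 3L
  XtXinv <- tryCatch(solve(crossprod(best$X)), error = function(e) NULL)
  if (!is.null(XtXinv)) {
    se_h <- sqrt(best$rss / df * XtXinv[3, 3])
    p_hinge <- 2 * stats::pt(-abs(cf[3] / se_h), df)
  } else p_hinge <- NA_real_
  # a hinge term indistinguishable from zero slope change is unidentified,
  # whatever its nominal p (an exact line fits with rss ~ machine epsilon)
  negligible <- abs(cf[3]) < 1e-8 * max(abs(cf[2]), 1)
  identified <- is.finite(p_hinge) && p_hinge < 0.05 && !negligible
  structure(list(bin_center = centers, bin_mean = as.numeric(bin_mean),
                 bin_n = as.integer(bin_n),
                 breakpoint = if (identified) best$b else NA_real_,
                 slope_low = unname(cf[2]),
                 slope_high = unname(cf[2] + cf[3]),
                 identified = identified, p_hinge = p_hinge),
            class = "response_curve")
}
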