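#' Scenario-labelled forcing ensemble
#'
#' A members-by-years matrix of a scalar index (e.g. sector-mean or overall
#' curvature) for one scenario of a single-forcing large-ensemble design:
#' `ALL` (all forcings), or `XGHG`/`XAER`/`XBMB` (the named forcing held
#' fixed while all others evolve).
#'
#' @param scenario one of `"ALL"`, `"XGHG"`, `"XAER"`, `"XBMB"`.
#' @param members numeric matrix `[n_members, n_years]`, at least 2 members.
#' @param years common year axis.
#' @return an object of class `forcing_ensemble`.
#' @export
forcing_ensemble <- function(scenario, members, years = NULL) {
  scenario <- match.arg(scenario, c("ALL", "XGHG", "XAER", "XBMB"))
  members <- as.matrix(members)
  if (nrow(members) < 2) stop("an ensemble needs at least 2 members")
  if (is.null(years)) years <- seq_len(ncol(members))
  if (length(years) != ncol(members)) stop("years must match member columns")
  structure(list(scenario = scenario, members = members, years = years),
            class = "forcing_ensemble")
}

#' @export
print.forcing_ensemble <- function(x, ...) {
  cat(sprintf("<forcing_ensemble> %s: %d members x %d years (%s..%s)\n",
              x$scenario, nrow(x$members), ncol(x$members),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Ensemble mean and inter-member spread
#'
#' Per year, the cross-member mean (the forced response estimate) and the
#' inter-member standard deviation (sample sd, the internal-variability
#' spread drawn as a +/- 1 sd envelope).
#'
#' @param ens a [forcing_ensemble()] with >= 2 members.
#' @return data.frame with `year`, `mean`, `sd`.
#' @export
ensemble_mean_spread <- function(ens) {
  stopifnot(inherits(ens, "forcing_ensemble"))
  data.frame(year = ens$years,
             mean = colMeans(ens$members),
             sd = apply(ens$members, 2, stats::sd))
}

# Per-member change over a period. trend_change: member OLS slope x
# (last - first year of the period). epoch_diff: member mean over the late
# epoch minus mean over the early epoch. The scenario change C is the mean
# of these (exactly so for trend_change, since OLS is linear in y).
.member_changes <- function(ens, period, mode, epochs) {
  sel <- ens$years >= period[1] & ens$years <= period[2]
  if (sum(sel) < 3) stop("period too short: need at least 3 years")
  yrs <- ens$years[sel]
  m <- ens$members[, sel, drop = FALSE]
  if (mode == "trend_change") {
    span <- diff(range(yrs))
    xc <- yrs - mean(yrs)
    slopes <- as.numeric(m %*% xc) / sum(xc^2)
    slopes * span
  } else {
    if (is.null(epochs))
      epochs <- list(c(yrs[1], yrs[1]), c(yrs[length(yrs)], yrs[length(yrs)]))
    e1 <- yrs >= epochs[[1]][1] & yrs <= epochs[[1]][2]
    e2 <- yrs >= epochs[[2]][1] & yrs <= epochs[[2]][2]
    if (!any(e1) || !any(e2)) stop("empty epoch within the period")
    rowMeans(m[, e2, drop = FALSE]) - rowMeans(m[, e1, drop = FALSE])
  }
}

#' Scenario change metric C
#'
#' The scalar change in the index over a period for one scenario, feeding the
#' contribution ratios. Two estimators: `"trend_change"` (default) is the
#' ensemble-mean OLS slope over the period multiplied by the period span in
#' years (`last - first`); `"epoch_diff"` is the ensemble mean over a late
#' epoch minus an early epoch (default: the period's last and first single
#' years, which coincides with `trend_change` for an exactly linear series).
#'
#' @param ens a [forcing_ensemble()].
#' @param period `c(first, last)` years; default the full record.
#' @param mode `"trend_change"` or `"epoch_diff"`.
#' @param epochs for `"epoch_diff"`: list of two `c(first, last)` pairs.
#' @return scalar change C in index units.
#' @export
change_metric <- function(ens, period = range(ens$years),
                          mode = c("trend_change", "epoch_diff"),
                          epochs = NULL) {
  stopifnot(inherits(ens, "forcing_ensemble"))
  mode <- match.arg(mode)
  mean(.member_changes(ens, period, mode, epochs))
}

#' Single-forcing contribution percentages with bootstrap CIs
#'
#' For each forcing F, the contribution to the all-forcing change is
#' `(C_ALL - C_XF) / C_ALL x 100%`, where `C` is the [change_metric()] of the
#' scenario. Contributions are reported signed and unclamped: values below 0%
#' or above 100% indicate offsetting forcings or nonlinear interactions.
#' Confidence intervals are percentile bootstrap over ensemble members,
#' resampled with replacement independently within each scenario (only the
#' members carry sampling uncertainty).
#'
#' @param ensembles named list with elements `ALL`, `XGHG`, `XAER`, `XBMB`
#'   (any subset of the X scenarios), each a [forcing_ensemble()].
#' @param period,mode,epochs passed to [change_metric()].
#' @param n_boot bootstrap resamples (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @param eps threshold below which `|C_ALL|` makes the ratio undefined.
#' @return an object of class `attribution_result`: data.frame with
#'   `forcing`, `contribution` (percent), `lower`, `upper`, plus the scenario
#'   changes in the `"changes"` attribute.
#' @export
forcing_contribution <- function(ensembles, period = NULL,
                                 mode = c("trend_change", "epoch_diff"),
                                 epochs = NULL, n_boot = 2000L, conf = 0.95,
                                 seed = 1L, eps = 1e-12) {
  mode <- match.arg(mode)
  if (!"ALL" %in% names(ensembles)) stop("an ALL ensemble is required")
  xnames <- intersect(c("XGHG", "XAER", "XBMB"), names(ensembles))
  if (!length(xnames)) stop("at least one fixed-forcing ensemble is required")
  if (is.null(period)) period <- range(ensembles$ALL$years)
  changes <- lapply(ensembles[c("ALL", xnames)], .member_changes,
                    period = period, mode = mode, epochs = epochs)
  C <- vapply(changes, mean, 0)
  if (abs(C[["ALL"]]) <= eps)
    stop("attribution undefined: negligible all-forcing change")
  contrib <- (C[["ALL"]] - C[xnames]) / C[["ALL"]] * 100
  set.seed(as.integer(seed))
  nb <- as.integer(n_boot)
  boot_means <- lapply(changes, function(ci) {
    m <- length(ci)
    idx <- matrix(sample.int(m, m * nb, replace = TRUE), nb, m)
    rowMeans(matrix(ci[idx], nb, m))
  })
  ci <- t(vapply(xnames, function(f) {
    bc <- (boot_means$ALL - boot_means[[f]]) / boot_means$ALL * 100
    stats::quantile(bc, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  }, numeric(2)))
  out <- data.frame(forcing = sub("^X", "", xnames),
                    contribution = unname(contrib),
                    lower = ci[, 1], upper = ci[, 2])
  structure(out, class = c("attribution_result", "data.frame"),
            changes = C, period = period, mode = mode, conf = conf,
            n_boot = nb)
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution_result> %s over %d-%d (%d%% bootstrap CI)\n",
              attr(x, "mode"), attr(x, "period")[1], attr(x, "period")[2],
              round(100 * attr(x, "conf"))))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
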