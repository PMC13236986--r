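#' Read a gridded lat-lon(-time) field from NetCDF or CSV
#'
#' NetCDF input (via the ncdf4 package) follows CF conventions: latitude is
#' normalised to ascending order, longitude to `[0, 360)` (rows/columns are
#' permuted consistently), and units are taken from variable metadata. CSV
#' input uses the long format written by [write_gridded()]: comment header
#' lines `# key: value`, then columns `lat, lon, time, value`.
#'
#' @param path file path (`.nc` or `.csv`).
#' @param variable variable name (NetCDF only).
#' @param level optional level value to select along a vertical dimension
#'   (NetCDF only; nearest level is used).
#' @param time_range optional `c(first, last)` indices along time.
#' @return a [gridded_field()].
#' @export
read_gridded <- function(path, variable = NULL, level = NULL,
                         time_range = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    .read_gridded_nc(path, variable, level, time_range)
  } else {
    .read_gridded_csv(path, time_range)
  }
}

.require_ncdf4 <- function() {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF support needs the 'ncdf4' package; use the CSV format otherwise")
}

.read_gridded_nc <- function(path, variable, level, time_range) {
  .require_ncdf4()
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  if (is.null(variable) || !variable %in% names(nc$var))
    stop("variable not found; available: ",
         paste(names(nc$var), collapse = ", "))
  v <- nc$var[[variable]]
  dn <- vapply(v$dim, function(d) d$name, "")
  find_dim <- function(pats) which(grepl(pats, dn, ignore.case = TRUE))[1]
  ilat <- find_dim("^(lat|latitude|y)$")
  ilon <- find_dim("^(lon|longitude|x)$")
  itime <- find_dim("^(time|t|year)$")
  ilev <- find_dim("^(lev|level|plev|pressure)")
  if (is.na(ilat) || is.na(ilon)) stop("no latitude/longitude dimensions found")
  start <- rep(1L, length(dn)); count <- rep(-1L, length(dn))
  if (!is.na(ilev)) {
    levs <- v$dim[[ilev]]$vals
    k <- if (is.null(level)) 1L else which.min(abs(levs - level))
    start[ilev] <- k; count[ilev] <- 1L
  }
  if (!is.na(itime) && !is.null(time_range)) {
    start[itime] <- time_range[1]
    count[itime] <- time_range[2] - time_range[1] + 1L
  }
  vals <- ncdf4::ncvar_get(nc, variable, start = start, count = count,
                           collapse_degen = FALSE)
  perm <- c(ilat, ilon, if (!is.na(itime)) itime)
  vals <- aperm(vals, c(perm, setdiff(seq_along(dim(vals)), perm)))
  dim(vals) <- if (is.na(itime)) c(dim(vals)[1:2], 1L) else dim(vals)[1:3]
  lat <- as.numeric(v$dim[[ilat]]$vals)
  lon <- as.numeric(v$dim[[ilon]]$vals)
  tm <- if (!is.na(itime)) {
    tv <- as.numeric(v$dim[[itime]]$vals)
    if (!is.null(time_range)) tv[time_range[1]:time_range[2]] else tv
  } else NULL
  units <- tryCatch(ncdf4::ncatt_get(nc, variable, "units")$value,
                    error = function(e) "")
  if (!is.character(units)) units <- ""
  .normalise_grid(vals, lat, lon, tm, units)
}

# ascending latitude, [0,360) longitude, consistent value permutation
.normalise_grid <- function(vals, lat, lon, tm, units) {
  if (is.unsorted(lat)) {
    o <- order(lat); lat <- lat[o]; vals <- vals[o, , , drop = FALSE]
  }
  lon2 <- lon %% 360
  o <- order(lon2)
  if (any(o != seq_along(lon2)) || any(lon2 != lon)) {
    lon2 <- lon2[o]; vals <- vals[, o, , drop = FALSE]
  }
  gridded_field(vals, lat, lon2, time = tm, units = units)
}

#' Write a gridded field to NetCDF or CSV
#'
#' Extension selects the format. The CSV layout is long format with comment
#' header metadata (`# units:`, `# convention:`, `# package:`) followed by
#' `lat, lon, time, value` rows in deterministic (lat-major) order, and
#' round-trips exactly through [read_gridded()].
#'
#' @param field a [gridded_field()].
#' @param path output path (`.nc` or `.csv`).
#' @param varname variable name for NetCDF output.
#' @return the path, invisibly.
#' @export
write_gridded <- function(field, path, varname = "field") {
  stopifnot(inherits(field, "gridded_field"))
  if (grepl("\\.nc$", path, ignore.case = TRUE)) {
    .require_ncdf4()
    dlat <- ncdf4::ncdim_def("lat", "degrees_north", field$lat)
    dlon <- ncdf4::ncdim_def("lon", "degrees_east", field$lon)
    dtim <- ncdf4::ncdim_def("time", "index", as.numeric(field$time),
                             unlim = TRUE)
    v <- ncdf4::ncvar_def(varname, field$units, list(dlat, dlon, dtim),
                          missval = NA_real_, prec = "double")
    nc <- ncdf4::nc_create(path, v)
    on.exit(ncdf4::nc_close(nc))
    ncdf4::ncvar_put(nc, v, field$values)
  } else {
    d <- dim(field$values)
    df <- data.frame(
      lat = rep(field$lat, times = d[2] * d[3]),
      lon = rep(rep(field$lon, each = d[1]), times = d[3]),
      time = rep(as.numeric(field$time), each = d[1] * d[2]),
      value = as.numeric(field$values))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(paste0("# units: ", field$units),
                 "# convention: lat ascending, lon [0,360), half-open sectors [west,east)",
                 paste0("# package: jetcurve ",
                        as.character(utils::packageVersion("jetcurve")))),
               con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  invisible(path)
}

.read_gridded_csv <- function(path, time_range) {
  hdr <- readLines(path, n = 10L)
  units <- sub("^# units:\\s*", "", grep("^# units:", hdr, value = TRUE)[1])
  if (is.na(units)) units <- ""
  df <- utils::read.csv(path, comment.char = "#")
  stopifnot(all(c("lat", "lon", "time", "value") %in% names(df)))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  tm <- sort(unique(df$time))
  vals <- array(NA_real_, c(length(lat), length(lon), length(tm)))
  vals[cbind(match(df$lat, lat), match(df$lon, lon), match(df$time, tm))] <-
    df$value
  if (!is.null(time_range)) {
    keep <- seq(time_range[1], time_range[2])
    vals <- vals[, , keep, drop = FALSE]; tm <- tm[keep]
  }
  .normalise_grid(vals, lat, lon, tm, units)
}

#' Write a jet axis as CSV
#'
#' Long format `time, lon, lat` with comment-header metadata; deterministic
#' row order (time-major).
#'
#' @param axis a [jet_axis()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_axis_csv <- function(axis, path) {
  stopifnot(inherits(axis, "jet_axis"))
  df <- data.frame(
    time = rep(as.numeric(axis$time), each = length(axis$lon)),
    lon = rep(axis$lon, times = nrow(axis$lat)),
    lat = as.numeric(t(axis$lat)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# units: degrees",
               "# convention: axis latitude per longitude, 0-90N",
               paste0("# package: jetcurve ",
                      as.character(utils::packageVersion("jetcurve")))), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a jet axis written by [write_axis_csv()]
#' @param path CSV path.
#' @return a [jet_axis()].
#' @export
read_axis_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  tm <- sort(unique(df$time)); lon <- sort(unique(df$lon))
  lat <- matrix(NA_real_, length(tm), length(lon))
  lat[cbind(match(df$time, tm), match(df$lon, lon))] <- df$lat
  jet_axis(lon, lat, tm)
}

#' Write a series table as CSV with metadata header
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param meta named character vector written as `# key: value` header lines.
#' @return the path, invisibly.
#' @export
write_series_csv <- function(df, path, meta = c()) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(meta, package = paste("jetcurve",
            as.character(utils::packageVersion("jetcurve"))))
  writeLines(paste0("# ", names(meta), ": ", meta), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write an attribution result as JSON
#'
#' @param result an `attribution_result` from [forcing_contribution()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_attribution_json <- function(result, path) {
  stopifnot(inherits(result, "attribution_result"))
  obj <- list(
    period = attr(result, "period"),
    mode = attr(result, "mode"),
    conf = attr(result, "conf"),
    changes = as.list(attr(result, "changes")),
    contributions = lapply(seq_len(nrow(result)), function(i) list(
      forcing = result$forcing[i],
      contribution_pct = result$contribution[i],
      lower_pct = result$lower[i],
      upper_pct = result$upper[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
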