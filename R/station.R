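#' Monthly station climate series
#'
#' Container for one weather station's monthly mean temperature and monthly
#' precipitation records across a span of calendar years. Temperature and
#' precipitation are stored as year-by-12 matrices aligned on the same
#' strictly increasing year vector; missing observations are `NA`.
#'
#' @param station_id character scalar, station identifier.
#' @param longitude,latitude WGS84 coordinates in decimal degrees
#'   (longitude first everywhere in this package).
#' @param elevation station elevation in metres.
#' @param years integer vector of calendar years, strictly increasing.
#' @param temp numeric matrix `length(years) x 12` of monthly mean
#'   temperature (degrees C); `NA` allowed.
#' @param precip numeric matrix `length(years) x 12` of monthly
#'   precipitation totals (mm, non-negative); `NA` allowed.
#'
#' @return An object of class `station_series`.
#' @export
station_series <- function(station_id, longitude, latitude, elevation,
                           years, temp, precip) {
  temp <- as.matrix(temp)
  precip <- as.matrix(precip)
  years <- as.integer(years)
  if (ncol(temp) != 12L || ncol(precip) != 12L)
    stop("temp and precip must have 12 columns (months)")
  if (nrow(temp) != length(years) || nrow(precip) != length(years))
    stop("temp/precip rows must match length(years)")
  if (!identical(dim(temp), dim(precip)))
    stop("temp and precip must have identical shape")
  if (length(years) > 1L && any(diff(years) <= 0L))
    stop("years must be strictly increasing")
  if (any(precip < 0, na.rm = TRUE))
    stop("precipitation must be non-negative where present")
  dimnames(temp) <- dimnames(precip) <- list(years, month.abb)
  structure(
    list(station_id = as.character(station_id),
         longitude = as.numeric(longitude),
         latitude = as.numeric(latitude),
         elevation = as.numeric(elevation),
         years = years, temp = temp, precip = precip),
    class = "station_series")
}

#' @export
print.station_series <- function(x, ...) {
  miss <- sum(is.na(x$temp)) + sum(is.na(x$precip))
  cells <- 2L * length(x$temp)
  cat(sprintf(
    "<station_series> %s  (%.3f, %.3f)  %.0f m\n  years %d-%d, %d/%d cells missing (%.1f%%)\n",
    x$station_id, x$longitude, x$latitude, x$elevation,
    min(x$years), max(x$years), miss, cells, 100 * miss / cells))
  invisible(x)
}

#' Fraction of missing monthly cells for a station
#'
#' Missingness is pooled over the temperature and precipitation matrices:
#' one station-level gate, `NA` cells / total cells.
#'
#' @param station a [station_series()].
#' @return proportion in \[0, 1\].
#' @export
missing_fraction <- function(station) {
  stopifnot(inherits(station, "station_series"))
  (sum(is.na(station$temp)) + sum(is.na(station$precip))) /
    (2L * length(station$temp))
}

#' Twelve-month climatology (period normals)
#'
#' @param t numeric length-12, monthly mean temperature (degrees C),
#'   January first.
#' @param p numeric length-12, monthly precipitation (mm), non-negative.
#' @param hemisphere `"north"` or `"south"`; used only when a fixed
#'   calendar summer is requested instead of the warmest-quarter default.
#'
#' @return An object of class `monthly_climatology`.
#' @export
monthly_climatology <- function(t, p, hemisphere = c("north", "south")) {
  hemisphere <- match.arg(hemisphere)
  t <- as.numeric(t); p <- as.numeric(p)
  if (length(t) != 12L || length(p) != 12L)
    stop("t and p must each have exactly 12 values")
  if (any(!is.finite(t)) || any(!is.finite(p)))
    stop("climatology values must be finite")
  if (any(p < 0)) stop("precipitation must be non-negative")
  structure(list(t = t, p = p, hemisphere = hemisphere),
            class = "monthly_climatology")
}

#' @export
print.monthly_climatology <- function(x, ...) {
  m <- rbind(`T (degC)` = round(x$t, 2), `P (mm)` = round(x$p, 1))
  colnames(m) <- month.abb
  cat("<monthly_climatology> (", x$hemisphere, ")\n", sep = "")
  print(m)
  invisible(x)
}
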