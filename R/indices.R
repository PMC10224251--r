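# Rivas-Martinez bioclimatic parameters and indices from a 12-month
# climatology. All arithmetic is double precision; rounding happens only
# in report writers.

#' Period climatology of a station
#'
#' Month-by-month mean over the requested years of a complete (imputed)
#' station series.
#'
#' @param station complete [station_series()].
#' @param years year range to average over; default all station years.
#' @return [monthly_climatology()].
#' @export
climatology_of <- function(station, years = NULL) {
  stopifnot(inherits(station, "station_series"))
  if (is.null(years)) years <- station$years
  sel <- station$years %in% years
  if (!any(sel))
    stop("requested years are disjoint from station years (",
         station$station_id, ")")
  if (anyNA(station$temp[sel, ]) || anyNA(station$precip[sel, ]))
    stop("station must be complete (impute first): ", station$station_id)
  monthly_climatology(colMeans(station$temp[sel, , drop = FALSE]),
                      colMeans(station$precip[sel, , drop = FALSE]),
                      hemisphere = if (station$latitude >= 0) "north"
                                   else "south")
}

#' Positive temperature and precipitation
#'
#' Tp is ten times the sum of monthly mean temperatures over months whose
#' mean exceeds 0 degC (tenths of a degree); Pp is the precipitation sum
#' over those same months. Months at or below 0 degC contribute to
#' neither.
#'
#' @param clim [monthly_climatology()].
#' @return named numeric `c(Tp, Pp)`.
#' @export
positive_sums <- function(clim) {
  pos <- clim$t > 0
  c(Tp = 10 * sum(clim$t[pos]), Pp = sum(clim$p[pos]))
}

#' Warmest/coldest month means and simple continentality index
#'
#' @param clim [monthly_climatology()].
#' @return named numeric `c(Tmax, Tmin, Ic)` with `Ic = Tmax - Tmin`.
#' @export
thermal_extremes <- function(clim) {
  tmax <- max(clim$t); tmin <- min(clim$t)
  c(Tmax = tmax, Tmin = tmin, Ic = tmax - tmin)
}

#' Default continentality compensation for the thermicity index
#'
#' Piecewise-linear correction C(Ic) added to It to give Itc. No
#' correction for Ic in \[9, 18\]; hyperoceanic climates (Ic < 9) are
#' penalised at 10 units per degree; continental climates accumulate a
#' positive correction with progressively steeper slopes above Ic 18.
#'
#' @return list with `lower_knot`, `lower_slope`, and continental
#'   `breaks`/`slopes` (slope applying above each break).
#' @export
itc_compensation_default <- function() {
  list(lower_knot = 9, lower_slope = 10,
       breaks = c(18, 21, 28, 46), slopes = c(5, 10, 20, 30),
       cap = 65)
}

compensation_value <- function(ic, comp = itc_compensation_default()) {
  if (ic < comp$lower_knot)
    return(-comp$lower_slope * (comp$lower_knot - ic))
  b <- comp$breaks; s <- comp$slopes
  ic <- min(ic, comp$cap)
  if (ic <= b[1L]) return(0)
  segs <- pmax(pmin(ic, c(b[-1L], comp$cap)) - b, 0)
  sum(s * segs)
}

#' Thermicity and compensated thermicity indices
#'
#' `It = 10 (Tavg + 2 Tmin)`; `Itc = It + C(Ic)` with the piecewise
#' continentality compensation (identity for Ic in the no-compensation
#' band, boundaries included).
#'
#' @param clim [monthly_climatology()].
#' @param compensation compensation table, see
#'   [itc_compensation_default()].
#' @return named numeric `c(It, Itc)`.
#' @export
thermicity <- function(clim, compensation = itc_compensation_default()) {
  ex <- thermal_extremes(clim)
  it <- 10 * (mean(clim$t) + 2 * ex[["Tmin"]])
  c(It = it, Itc = it + compensation_value(ex[["Ic"]], compensation))
}

#' Annual ombrothermic index
#'
#' `Io = 10 Pp / Tp`. When no month is above 0 degC (`Tp = 0`) the index
#' is undefined and `NA` is returned (such a climate supports none of the
#' envelope species downstream).
#'
#' @param clim [monthly_climatology()].
#' @return numeric scalar, `NA` when undefined.
#' @export
ombrothermic <- function(clim) {
  ps <- positive_sums(clim)
  if (ps[["Tp"]] <= 0) return(NA_real_)
  10 * ps[["Pp"]] / ps[["Tp"]]
}

#' Summer quarter of a climatology
#'
#' The warmest three consecutive calendar months (default), wrapping
#' across the year boundary, or a fixed calendar summer (Jun-Aug north,
#' Dec-Feb south).
#'
#' @param clim [monthly_climatology()].
#' @param mode `"warmest"` (default) or `"fixed"`.
#' @return integer vector of three month numbers in consecutive order.
#' @export
summer_quarter <- function(clim, mode = c("warmest", "fixed")) {
  mode <- match.arg(mode)
  if (mode == "fixed")
    return(if (clim$hemisphere == "north") 6:8 else c(12L, 1L, 2L))
  sums <- vapply(1:12, function(m0) sum(clim$t[(m0 + 0:2 - 1L) %% 12L + 1L]),
                 numeric(1))
  m0 <- which.max(sums)  # earliest maximiser on ties
  (m0 + 0:2 - 1L) %% 12L + 1L
}

# Ombrothermic ratio sum(P)/sum(T) over a month set; NA when sum(T) <= 0.
ombro_ratio <- function(clim, months) {
  st <- sum(clim$t[months])
  if (st <= 0) return(NA_real_)
  sum(clim$p[months]) / st
}

#' Summer ombrothermic indices
#'
#' Ios1: warmest summer-quarter month; Ios2: two hottest summer-quarter
#' months (ties broken by calendar order); Ios3: the summer quarter;
#' Ios4: summer quarter plus the preceding month. Each is
#' `sum(P) / sum(T)` over its month set (the factor of ten in the
#' numerator and denominator of the monthly definition cancels).
#'
#' @param clim [monthly_climatology()].
#' @param summer optional integer vector of the three summer months;
#'   default [summer_quarter()].
#' @return named numeric `c(Ios1, Ios2, Ios3, Ios4)`; `NA` entries where
#'   the temperature sum is not positive.
#' @export
summer_ombrothermic <- function(clim, summer = summer_quarter(clim)) {
  stopifnot(length(summer) == 3L)
  ord <- summer[order(-clim$t[summer], seq_along(summer))]
  prev <- (summer[1L] - 2L) %% 12L + 1L
  c(Ios1 = ombro_ratio(clim, ord[1L]),
    Ios2 = ombro_ratio(clim, ord[1:2]),
    Ios3 = ombro_ratio(clim, summer),
    Ios4 = ombro_ratio(clim, c(prev, summer)))
}

#' All bioclimatic parameters and indices for one location
#'
#' Assembles the annual parameters (Tavg, Pavg, Tp, Pp, Tmax, Tmin), the
#' continentality, thermicity and ombrothermic indices, and the four
#' summer ombrothermic indices into one named vector, optionally carrying
#' elevation and a categorical soil order.
#'
#' @param clim [monthly_climatology()].
#' @param elevation optional elevation (m); `NA` when unknown.
#' @param soil_order optional categorical soil code; `NA` when unknown.
#' @param compensation see [thermicity()].
#' @param summer_mode see [summer_quarter()].
#' @return object of class `bioclim_vector`: named numeric vector with
#'   elements `Tavg, Pavg, Tp, Pp, Tmax, Tmin, Ic, It, Itc, Io,
#'   Ios1..Ios4, elevation` and attribute `soil_order`.
#' @export
bioclim_indices <- function(clim, elevation = NA_real_,
                            soil_order = NA,
                            compensation = itc_compensation_default(),
                            summer_mode = c("warmest", "fixed")) {
  summer_mode <- match.arg(summer_mode)
  ps <- positive_sums(clim)
  ex <- thermal_extremes(clim)
  th <- thermicity(clim, compensation)
  ios <- summer_ombrothermic(clim, summer_quarter(clim, summer_mode))
  v <- c(Tavg = mean(clim$t), Pavg = sum(clim$p), ps, ex, th,
         Io = ombrothermic(clim), ios,
         elevation = as.numeric(elevation))
  structure(v, soil_order = soil_order, class = "bioclim_vector")
}

#' @export
print.bioclim_vector <- function(x, digits = 1, ...) {
  cat("<bioclim_vector>\n")
  print(round(unclass(x), digits))
  if (!is.na(attr(x, "soil_order")))
    cat("soil order:", attr(x, "soil_order"), "\n")
  invisible(x)
}

#' Index table for a set of stations
#'
#' One row per station with its coordinates, elevation and full
#' [bioclim_indices()] vector; the standard input to surface
#' interpolation.
#'
#' @param stations list of complete [station_series()].
#' @param years optional year range passed to [climatology_of()].
#' @param ... passed to [bioclim_indices()].
#' @return data.frame.
#' @export
station_index_table <- function(stations, years = NULL, ...) {
  rows <- lapply(stations, function(s) {
    v <- bioclim_indices(climatology_of(s, years),
                         elevation = s$elevation, ...)
    data.frame(station_id = s$station_id, lon = s$longitude,
               lat = s$latitude, t(unclass(v)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
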