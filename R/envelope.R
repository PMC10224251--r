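# Rectilinear climate-envelope model: per-variable [min, max] suitability
# and [Q1, Q3] optimality intervals, conjunctive across variables, plus an
# admissible soil-order set; Boolean raster logic and change detection.

#' Default envelope variable set
#'
#' The thirteen annual/summer indices in report order, plus elevation;
#' soil order is handled as a categorical set. Ios1 is computed by
#' [bioclim_indices()] but excluded from the default envelope.
#' @export
ENVELOPE_VARS <- c("Tavg", "Tmin", "Tmax", "Pavg", "Pp", "It", "Itc",
                   "Tp", "Ic", "Io", "Ios2", "Ios3", "Ios4")

#' Fit a species climate envelope
#'
#' Builds the rectilinear envelope of a species from the variable values
#' observed at its occurrence points: per variable the minimum, first
#' quartile, third quartile and maximum (quantiles by linear
#' interpolation of order statistics, `type = 7`, by default), and the
#' set of soil-order codes observed at occurrences. Suitable conditions
#' are those inside every `[min, max]` interval; optimal conditions
#' inside every `[Q1, Q3]`.
#'
#' @param data data.frame, one row per occurrence, containing the
#'   envelope variables (and optionally `elevation` and a soil column).
#'   Rows with missing values in any used variable are dropped with a
#'   warning.
#' @param species species name (metadata).
#' @param vars continuous variables to use; default [ENVELOPE_VARS] plus
#'   `elevation` when present in `data`.
#' @param soil_col name of the categorical soil column, or `NULL` to
#'   ignore soils; ignored silently when absent from `data`.
#' @param quantile_type passed to [stats::quantile()] (default 7).
#' @return object of class `bioclim_envelope`.
#' @export
bioclim_envelope <- function(data, species = "species", vars = NULL,
                             soil_col = "soil", quantile_type = 7) {
  if (is.null(vars))
    vars <- intersect(c(ENVELOPE_VARS, "elevation"), names(data))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop("data lacks envelope variables: ",
         paste(missing_vars, collapse = ", "))
  use_soil <- !is.null(soil_col) && soil_col %in% names(data)
  x <- data[, vars, drop = FALSE]
  complete <- stats::complete.cases(x)
  if (use_soil) complete <- complete & !is.na(data[[soil_col]])
  if (any(!complete))
    warning(sum(!complete), " occurrence(s) with missing values dropped")
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 4L)
    stop("need at least 4 complete occurrence points, got ", nrow(x))
  stats_tab <- data.frame(
    variable = vars,
    min = vapply(x, min, numeric(1)),
    q1 = vapply(x, stats::quantile, numeric(1), probs = 0.25,
                type = quantile_type, names = FALSE),
    q3 = vapply(x, stats::quantile, numeric(1), probs = 0.75,
                type = quantile_type, names = FALSE),
    max = vapply(x, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  stopifnot(all(stats_tab$min <= stats_tab$q1),
            all(stats_tab$q1 <= stats_tab$q3),
            all(stats_tab$q3 <= stats_tab$max))
  structure(list(
    species = species, stats = stats_tab,
    soil_orders = if (use_soil) sort(unique(data[[soil_col]][complete]))
                  else NULL,
    n_occurrences = nrow(x), quantile_type = quantile_type),
    class = "bioclim_envelope")
}

#' @export
print.bioclim_envelope <- function(x, ...) {
  cat(sprintf("<bioclim_envelope> %s  (n = %d occurrences)\n",
              x$species, x$n_occurrences))
  if (!is.null(x$soil_orders))
    cat("  soil orders:", paste(x$soil_orders, collapse = ", "), "\n")
  cat("  ", format_characterisation(x), "\n", sep = "")
  invisible(x)
}

#' @export
summary.bioclim_envelope <- function(object, ...)
  summarize_envelope(object)

#' Characterisation table of an envelope
#'
#' Per-variable `min, Q1, Q3, max` rounded to one decimal, rows in the
#' standard report order (`Tavg, Tmin, Tmax, Pavg, Pp, It, Itc, Tp, Ic,
#' Io, Ios2, Ios3, Ios4`, then any extra variables such as elevation).
#'
#' @param envelope a [bioclim_envelope()].
#' @return data.frame.
#' @export
summarize_envelope <- function(envelope) {
  s <- envelope$stats
  ord <- order(match(s$variable, c(ENVELOPE_VARS, "elevation")))
  s <- s[ord, , drop = FALSE]
  s[, c("min", "q1", "q3", "max")] <-
    round(s[, c("min", "q1", "q3", "max")], 1)
  rownames(s) <- NULL
  s
}

#' Render a characterisation in the compact text layout
#'
#' `var: min (Q1-Q3) max` per variable, the interquartile range bracketed
#' and collapsed to a single value when Q1 and Q3 round to the same
#' number.
#'
#' @param envelope a [bioclim_envelope()].
#' @return character scalar.
#' @export
format_characterisation <- function(envelope) {
  s <- summarize_envelope(envelope)
  part <- vapply(seq_len(nrow(s)), function(i) {
    iqr <- if (s$q1[i] == s$q3[i]) sprintf("(%.1f)", s$q1[i])
           else sprintf("(%.1f-%.1f)", s$q1[i], s$q3[i])
    sprintf("%s: %.1f %s %.1f", s$variable[i], s$min[i], iqr, s$max[i])
  }, character(1))
  paste(part, collapse = "; ")
}

#' Conditional interval mask over a raster
#'
#' The CON operator: cell value 1 where `lo <= value <= hi` (both ends
#' inclusive), 0 elsewhere; nodata cells are 0 (absence).
#'
#' @param layer a continuous [raster_layer()].
#' @param lo,hi interval bounds, `lo <= hi`.
#' @return binary [raster_layer()].
#' @export
con_mask <- function(layer, lo, hi) {
  stopifnot(lo <= hi)
  v <- layer$values
  m <- ifelse(!is.na(v) & v >= lo & v <= hi, 1, 0)
  raster_layer(layer$grid, m, "continuous")
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$grid[c("xmin", "ymin", "cellsize", "ncol", "nrow")],
                   b$grid[c("xmin", "ymin", "cellsize", "ncol", "nrow")]))
}

#' Binary suitability or optimality map for an envelope
#'
#' Conjunction (AND) across all envelope variables: a cell is 1 iff
#' every continuous variable lies inside the envelope interval
#' (`[min, max]` for `"suitable"`, `[Q1, Q3]` for `"optimal"`) and, when
#' the envelope carries a soil set and a soil layer is supplied, the
#' cell's soil code is admissible.
#'
#' @param envelope a [bioclim_envelope()].
#' @param layers named list of continuous [raster_layer()]s covering
#'   every envelope variable, all on one grid.
#' @param level `"suitable"` or `"optimal"`.
#' @param soil optional categorical soil [raster_layer()].
#' @return binary [raster_layer()].
#' @export
suitability_map <- function(envelope, layers,
                            level = c("suitable", "optimal"),
                            soil = NULL) {
  level <- match.arg(level)
  s <- envelope$stats
  missing_layers <- setdiff(s$variable, names(layers))
  if (length(missing_layers))
    stop("layers missing for variables: ",
         paste(missing_layers, collapse = ", "))
  ref <- layers[[s$variable[1L]]]
  acc <- NULL
  for (i in seq_len(nrow(s))) {
    ly <- layers[[s$variable[i]]]
    if (!same_grid(ly, ref)) stop("layer grids do not match: ",
                                  s$variable[i])
    lo <- if (level == "suitable") s$min[i] else s$q1[i]
    hi <- if (level == "suitable") s$max[i] else s$q3[i]
    m <- con_mask(ly, lo, hi)$values
    acc <- if (is.null(acc)) m else acc * m
  }
  if (!is.null(envelope$soil_orders) && !is.null(soil)) {
    if (!same_grid(soil, ref)) stop("soil layer grid does not match")
    acc <- acc * ifelse(!is.na(soil$values) &
                          soil$values %in% envelope$soil_orders, 1, 0)
  }
  raster_layer(ref$grid, acc, "continuous")
}

#' @rdname suitability_map
#' @param object,... method arguments (`...` passed to
#'   [suitability_map()]).
#' @export
predict.bioclim_envelope <- function(object, layers, ...)
  suitability_map(object, layers, ...)

#' Change raster between a reference and a future binary map
#'
#' Per cell: never suitable (0/0), gain (0/1), unstable — currently
#' suitable but lost (1/0) — or stable (1/1).
#'
#' @param current,future binary [raster_layer()]s on one grid.
#' @return object of class `change_raster` (a categorical raster with
#'   codes never=0, gain=1, unstable=2, stable=3).
#' @export
change_map <- function(current, future) {
  if (!same_grid(current, future)) stop("grids do not match")
  cur <- current$values > 0 & !is.na(current$values)
  fut <- future$values > 0 & !is.na(future$values)
  code <- matrix(0L, nrow(cur), ncol(cur))
  code[!cur & fut] <- 1L
  code[cur & !fut] <- 2L
  code[cur & fut] <- 3L
  out <- raster_layer(current$grid, code, "categorical")
  class(out) <- c("change_raster", class(out))
  out
}

CHANGE_LEVELS <- c(never = 0L, gain = 1L, unstable = 2L, stable = 3L)

#' @export
print.change_raster <- function(x, ...) {
  tab <- table(factor(x$values, levels = CHANGE_LEVELS,
                      labels = names(CHANGE_LEVELS)))
  cat("<change_raster>", paste(names(tab), tab, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.change_raster <- function(x, main = "suitability change", ...) {
  cc <- cell_centres(x$grid)
  cols <- c("grey92", "royalblue3", "orangered3", "forestgreen")
  graphics::image(cc$x, rev(cc$y),
                  t(x$values[x$grid$nrow:1, , drop = FALSE]),
                  zlim = c(-0.5, 3.5), col = cols,
                  xlab = "lon", ylab = "lat", main = main,
                  useRaster = TRUE, ...)
  graphics::legend("topright", fill = cols, bty = "n",
                   legend = names(CHANGE_LEVELS))
  invisible(x)
}

#' Gain / unstable / stable percentages of a change raster
#'
#' All three percentages are expressed relative to the current
#' (reference-period) area, i.e. the unstable + stable cells: stable% and
#' unstable% partition the current area (sum 100), while gain% compares
#' newly suitable cells to the current area and may in principle exceed
#' 100. Cell areas are uniform on the grid, so counts stand in for areas.
#'
#' @param change a [change_map()] result.
#' @return named numeric `c(gain, unstable, stable)` in percent (`NA`
#'   with a warning when the current area is empty).
#' @export
summarize_change <- function(change) {
  n <- table(factor(change$values, levels = CHANGE_LEVELS))
  gain <- as.integer(n[["1"]]); unst <- as.integer(n[["2"]])
  stab <- as.integer(n[["3"]])
  current <- unst + stab
  if (current == 0L) {
    warning("no current area; percentages undefined")
    return(c(gain = NA_real_, unstable = NA_real_, stable = NA_real_))
  }
  100 * c(gain = gain, unstable = unst, stable = stab) / current
}
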