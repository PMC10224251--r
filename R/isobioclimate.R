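# Qualitative diagnosis: macrobioclimate, bioclimate, variant, thermotype,
# ombrotype and continentality, against configurable threshold tables.

#' Load bioclimatic threshold tables
#'
#' Reads an axis/class/horizon interval table (CSV with columns
#' `axis, class, horizon, lower, upper`) and validates that, within each
#' axis, horizon intervals are disjoint, contiguous and ordered. The
#' shipped default carries the worldwide bioclimatic classification
#' values for continentality, ombrotype, Mediterranean and Temperate
#' thermotypes (thermicity scale with a positive-temperature fallback
#' scale) and the Mediterranean bioclimate bands. Intervals are
#' lower-closed, upper-open everywhere.
#'
#' @param path CSV path; default the package's shipped table.
#' @return data.frame of class `threshold_tables`.
#' @export
load_threshold_tables <- function(path = system.file(
    "extdata", "rm_thresholds.csv", package = "bioclimenv")) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("axis", "class", "horizon", "lower", "upper")
  if (!all(need %in% names(tb)))
    stop("threshold table must have columns: ", paste(need, collapse = ", "))
  tb$lower <- as.numeric(tb$lower)
  tb$upper <- as.numeric(tb$upper)
  for (ax in unique(tb$axis)) {
    a <- tb[tb$axis == ax, ]
    a <- a[order(a$lower), ]
    if (any(a$upper <= a$lower))
      stop("degenerate interval in axis ", ax)
    if (nrow(a) > 1L && any(abs(a$lower[-1L] - a$upper[-nrow(a)]) > 1e-9))
      stop("intervals not contiguous in axis ", ax)
  }
  class(tb) <- c("threshold_tables", "data.frame")
  tb
}

#' Classify a value on one threshold axis
#'
#' Returns the class and horizon of the unique lower-closed, upper-open
#' interval containing `value`; a value exactly on an interior boundary
#' belongs to the upper interval. Values outside the axis span get the
#' explicit beyond-table marker (`"<beyond-table>"`), never silence.
#'
#' @param value finite numeric scalar.
#' @param axis axis name present in `tables`.
#' @param tables from [load_threshold_tables()].
#' @return named character `c(class=, horizon=)`.
#' @export
classify_axis <- function(value, axis, tables = load_threshold_tables()) {
  a <- tables[tables$axis == axis, ]
  if (nrow(a) == 0L) stop("unknown axis: ", axis)
  if (!is.finite(value) && !is.infinite(value))
    return(c(class = "<beyond-table>", horizon = "<beyond-table>"))
  hit <- which(a$lower <= value & value < a$upper)
  if (length(hit) != 1L)
    return(c(class = "<beyond-table>", horizon = "<beyond-table>"))
  c(class = a$class[hit], horizon = a$horizon[hit])
}

#' Mediterranean versus Temperate macrobioclimate
#'
#' Mediterranean climates have a summer drought: under the default rule
#' there must be two consecutive summer-quarter months each with monthly
#' precipitation below twice the monthly mean temperature (P < 2T, P in
#' mm, T in degC). The alternative reading averages the two hottest
#' summer-quarter months and applies P < 2T to the pair means.
#'
#' @param clim [monthly_climatology()].
#' @param rule `"consecutive"` (default) or `"two-hottest-mean"`.
#' @param summer optional summer-quarter months.
#' @return `"Mediterranean"` or `"Temperate"`.
#' @export
macrobioclimate_test <- function(clim,
                                 rule = c("consecutive", "two-hottest-mean"),
                                 summer = summer_quarter(clim)) {
  rule <- match.arg(rule)
  dry <- clim$p[summer] < 2 * clim$t[summer]
  med <- if (rule == "consecutive") {
    any(dry[-1L] & dry[-length(dry)])
  } else {
    hot2 <- summer[order(-clim$t[summer], seq_along(summer))][1:2]
    mean(clim$p[hot2]) < 2 * mean(clim$t[hot2])
  }
  if (med) "Mediterranean" else "Temperate"
}

#' Full isobioclimate diagnosis
#'
#' Combines the macrobioclimate test with threshold-table classification:
#' bioclimate from Io (pluviseasonal / xeric / desertic bands) crossed
#' with oceanicity (Ic below/above the continental bound), thermotype
#' from Itc with a positive-temperature (Tp) fallback below the
#' thermicity scale's validity floor, ombrotype from Io, continentality
#' from Ic, and a submediterranean variant flag for Temperate diagnoses
#' with a summer-dry tendency (Ios3 below `submed_ios3`).
#'
#' @param v [bioclim_indices()] vector.
#' @param clim the underlying [monthly_climatology()].
#' @param tables from [load_threshold_tables()].
#' @param rule macrobioclimate rule, see [macrobioclimate_test()].
#' @param itc_floor Itc below which the thermotype is assigned from Tp
#'   instead (default: the lower end of the Itc thermotype scale).
#' @param submed_ios3 Ios3 cut for the submediterranean variant
#'   (default 2.0).
#' @return object of class `isobioclimate`.
#' @export
diagnose_isobioclimate <- function(v, clim,
                                   tables = load_threshold_tables(),
                                   rule = c("consecutive", "two-hottest-mean"),
                                   itc_floor = NULL,
                                   submed_ios3 = 2.0) {
  macro <- macrobioclimate_test(clim, rule)
  ic <- v[["Ic"]]; io <- v[["Io"]]; itc <- v[["Itc"]]; tp <- v[["Tp"]]
  cont <- classify_axis(ic, "continentality", tables)
  ombro <- if (is.na(io)) c(class = "<undefined>", horizon = "<undefined>")
           else classify_axis(io, "ombrotype", tables)
  oceanicity <- if (ic < 21) "oceanic" else "continental"
  suffix <- if (macro == "Mediterranean") "med" else "tem"
  itc_axis <- paste0("thermotype_", suffix, "_itc")
  tp_axis <- paste0("thermotype_", suffix, "_tp")
  if (is.null(itc_floor))
    itc_floor <- min(tables$lower[tables$axis == itc_axis])
  thermo <- if (itc >= itc_floor) classify_axis(itc, itc_axis, tables)
            else classify_axis(tp, tp_axis, tables)
  if (macro == "Mediterranean") {
    band <- if (is.na(io)) c(class = "<undefined>")
            else classify_axis(io, "bioclimate_med", tables)
    bioclimate <- paste(band[["class"]], oceanicity)
    variant <- "none"
  } else {
    bioclimate <- if (ic < 11) "hyperoceanic" else oceanicity
    ios3 <- v[["Ios3"]]
    variant <- if (!is.na(ios3) && ios3 < submed_ios3) "submediterranean"
               else "none"
  }
  structure(list(
    macrobioclimate = macro, bioclimate = bioclimate, variant = variant,
    continentality = unname(cont[["horizon"]]),
    continentality_class = unname(cont[["class"]]),
    thermotype = unname(thermo[["horizon"]]),
    thermotype_class = unname(thermo[["class"]]),
    ombrotype = unname(ombro[["horizon"]]),
    ombrotype_class = unname(ombro[["class"]])),
    class = "isobioclimate")
}

#' @export
format.isobioclimate <- function(x, ...) {
  paste(c(x$macrobioclimate, x$bioclimate,
          if (x$variant != "none") x$variant,
          x$continentality, x$thermotype, x$ombrotype),
        collapse = " ")
}

#' @export
print.isobioclimate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Ranked isobioclimate summary for a species
#'
#' Counts distinct isobioclimate labels over per-occurrence diagnoses and
#' ranks them by frequency (ties by label). Labels at or below the
#' rarity fraction are flagged parenthetical, matching the convention of
#' bracketing isobioclimates a taxon only occasionally occupies.
#'
#' @param diagnoses list of `isobioclimate` objects (or character labels).
#' @param rarity_fraction labels with relative frequency at or below
#'   this are parenthetical (default 0.05).
#' @return data.frame with `isobioclimate, n, fraction, parenthetical`,
#'   most frequent first.
#' @export
species_isobioclimate_summary <- function(diagnoses,
                                          rarity_fraction = 0.05) {
  if (length(diagnoses) == 0L) stop("need at least one diagnosis")
  labels <- vapply(diagnoses, function(d)
    if (is.character(d)) d else format(d), character(1))
  tab <- table(labels)
  out <- data.frame(isobioclimate = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$isobioclimate), , drop = FALSE]
  out$fraction <- out$n / sum(out$n)
  out$parenthetical <- out$fraction <= rarity_fraction
  rownames(out) <- NULL
  out
}
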