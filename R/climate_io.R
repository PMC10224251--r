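# Station and occurrence table input, quality control and gap filling.

#' Read long-format station climate records
#'
#' Reads a CSV with one row per station-year-month and assembles one
#' [station_series()] per station. Unparseable numeric entries (empty
#' strings, text) become missing cells, never zeroes.
#'
#' @param path CSV file path.
#' @param col_map named character vector mapping the canonical names
#'   `station_id, lon, lat, elev, year, month, tmean, prcp` to the file's
#'   column names. Defaults to the canonical names themselves.
#' @return list of [station_series()], one per station, named by id.
#' @export
read_station_records <- function(path, col_map = NULL) {
  canon <- c("station_id", "lon", "lat", "elev", "year", "month",
             "tmean", "prcp")
  map <- stats::setNames(canon, canon)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) stop("empty station file: ", path)
  missing_cols <- setdiff(unname(map), names(df))
  if (length(missing_cols))
    stop("station file lacks columns: ", paste(missing_cols, collapse = ", "))
  get <- function(nm) df[[map[[nm]]]]
  num <- function(x) suppressWarnings(as.numeric(x))
  id <- get("station_id")
  year <- as.integer(num(get("year")))
  month <- as.integer(num(get("month")))
  if (any(is.na(year)) || any(is.na(month)) ||
      any(month < 1L | month > 12L))
    stop("unparseable or out-of-range year/month values")
  key <- paste(id, year, month, sep = "/")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (station, year, month) rows, first: ", dup)
  }
  tmean <- num(get("tmean"))
  prcp <- num(get("prcp"))
  lon <- num(get("lon")); lat <- num(get("lat")); elev <- num(get("elev"))

  out <- lapply(split(seq_len(nrow(df)), id), function(i) {
    yrs <- sort(unique(year[i]))
    tm <- matrix(NA_real_, length(yrs), 12L)
    pm <- matrix(NA_real_, length(yrs), 12L)
    r <- match(year[i], yrs)
    tm[cbind(r, month[i])] <- tmean[i]
    pm[cbind(r, month[i])] <- prcp[i]
    station_series(id[i[1L]], lon[i[1L]], lat[i[1L]], elev[i[1L]],
                   yrs, tm, pm)
  })
  out[order(names(out))]
}

#' Quality-filter stations by completeness
#'
#' Retains a station iff its pooled missing-cell fraction (temperature and
#' precipitation together) is strictly below `max_missing_fraction`; a
#' station at exactly the threshold is rejected.
#'
#' @param stations list of [station_series()].
#' @param max_missing_fraction proportion in \[0, 1\]; default 0.10.
#' @return list with `kept` (list of stations) and `rejected`
#'   (data.frame of `station_id`, `missing_fraction`).
#' @export
qc_filter_stations <- function(stations, max_missing_fraction = 0.10) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  fr <- vapply(stations, missing_fraction, numeric(1))
  keep <- fr < max_missing_fraction
  rejected <- data.frame(
    station_id = vapply(stations[!keep], `[[`, "", "station_id"),
    missing_fraction = unname(fr[!keep]),
    row.names = NULL, stringsAsFactors = FALSE)
  list(kept = stations[keep], rejected = rejected)
}

#' Fill missing monthly cells with long-term monthly means
#'
#' Each missing cell is replaced by the mean of the observed values for
#' the same station, variable and calendar month; observed cells are
#' returned unchanged.
#'
#' @param station a [station_series()].
#' @return a complete [station_series()].
#' @export
impute_monthly_means <- function(station) {
  stopifnot(inherits(station, "station_series"))
  fill <- function(m, what) {
    for (j in seq_len(12L)) {
      obs <- !is.na(m[, j])
      if (any(!obs)) {
        if (!any(obs))
          stop(sprintf("station %s: %s for %s entirely missing",
                       station$station_id, what, month.abb[j]))
        m[!obs, j] <- mean(m[obs, j])
      }
    }
    m
  }
  station$temp <- fill(station$temp, "temperature")
  station$precip <- fill(station$precip, "precipitation")
  station
}

#' Read species occurrence records
#'
#' Reads a GBIF-style CSV export. Rows with unparseable or out-of-range
#' coordinates (|lat| > 90, |lon| > 180) are dropped and counted;
#' elevation is optional and kept as `NA` where absent.
#'
#' @param path CSV file path.
#' @param col_map named character vector mapping
#'   `species, lon, lat, elev` to the file's column names; default uses
#'   GBIF simple-export names (`species`, `decimalLongitude`,
#'   `decimalLatitude`, `elevation`).
#' @return data.frame with columns `species, lon, lat, elev` and
#'   attribute `n_dropped`.
#' @export
read_occurrences <- function(path, col_map = NULL) {
  map <- c(species = "species", lon = "decimalLongitude",
           lat = "decimalLatitude", elev = "elevation")
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- map[c("species", "lon", "lat")]
  missing_cols <- setdiff(unname(need), names(df))
  if (length(missing_cols))
    stop("occurrence file lacks columns: ",
         paste(missing_cols, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  out <- data.frame(
    species = df[[map[["species"]]]],
    lon = num(df[[map[["lon"]]]]),
    lat = num(df[[map[["lat"]]]]),
    elev = if (map[["elev"]] %in% names(df)) num(df[[map[["elev"]]]])
           else NA_real_,
    stringsAsFactors = FALSE)
  ok <- !is.na(out$lon) & !is.na(out$lat) & nzchar(out$species) &
    abs(out$lat) <= 90 & abs(out$lon) <= 180
  n_dropped <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) == 0L) stop("no parseable occurrence rows in ", path)
  message(sprintf("read_occurrences: %d records, %d rows dropped",
                  nrow(out), n_dropped))
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Clean occurrence records
#'
#' Drops, in order: records with absent or (0, 0) sentinel coordinates
#' ("lacking a precise locality"), records outside the study region
#' polygon, and exact duplicates after rounding coordinates to
#' `dedup_precision` decimal places (about 110 m at 3 decimals).
#'
#' @param occ data.frame from [read_occurrences()].
#' @param region optional polygon as a two-column (lon, lat) matrix or
#'   data.frame, vertices in order (closed implicitly). `NULL` skips the
#'   region filter.
#' @param dedup_precision decimal places for duplicate collapse
#'   (default 3).
#' @return list with `kept` (data.frame) and `report` (data.frame of
#'   reason, n). Reason counts sum to rows in minus rows out.
#' @export
clean_occurrences <- function(occ, region = NULL, dedup_precision = 3) {
  n_in <- nrow(occ)
  imprecise <- is.na(occ$lon) | is.na(occ$lat) |
    (occ$lon == 0 & occ$lat == 0)
  occ1 <- occ[!imprecise, , drop = FALSE]
  if (!is.null(region)) {
    region <- as.matrix(region)
    inside <- point_in_polygon(occ1$lon, occ1$lat, region)
  } else inside <- rep(TRUE, nrow(occ1))
  n_outside <- sum(!inside)
  occ2 <- occ1[inside, , drop = FALSE]
  key <- paste(occ2$species,
               round(occ2$lon, dedup_precision),
               round(occ2$lat, dedup_precision))
  dup <- duplicated(key)
  kept <- occ2[!dup, , drop = FALSE]
  rownames(kept) <- NULL
  report <- data.frame(
    reason = c("imprecise_locality", "outside_region", "duplicate"),
    n = c(sum(imprecise), n_outside, sum(dup)),
    stringsAsFactors = FALSE)
  stopifnot(sum(report$n) == n_in - nrow(kept))
  message(sprintf("clean_occurrences: %d -> %d (%s)", n_in, nrow(kept),
                  paste(report$reason, report$n, collapse = ", ")))
  list(kept = kept, report = report)
}

# Even-odd ray-casting point-in-polygon test; boundary points count as
# inside (adequate for coarse study-region gating).
point_in_polygon <- function(px, py, poly) {
  nv <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  inside <- logical(length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  on_vertex <- vapply(seq_along(px), function(k)
    any(xs == px[k] & ys == py[k]), logical(1))
  inside | on_vertex
}
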