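# Synthetic landscapes, station networks, climate series and occurrence
# records with known ground truth, so that every pipeline stage can be
# validated against construction.

#' Synthetic scenario configuration
#'
#' Defines a Mediterranean (winter-wet) landscape-climate scenario: a
#' coastal ridge landscape, a station network, monthly climate with
#' elevational lapse, latitudinal gradient, seasonal cycles, linear
#' interannual trends, independent noise, optional gross-outlier
#' contamination and missingness, and ground-truth species envelope
#' boxes. Defaults describe a 40-year (1980-2019) network in a
#' California-like coordinate window; temperatures peak in July and
#' precipitation in January, so low-elevation cells satisfy the
#' Mediterranean summer-drought criterion by construction.
#'
#' @param seed integer root seed; every generated artifact is a
#'   deterministic function of `(seed, cfg)`.
#' @param grid landscape [grid_spec()].
#' @param n_stations number of stations (>= 3).
#' @param years calendar years of the series (span >= 10).
#' @param max_elev ridge top elevation (m).
#' @param lapse_rate temperature lapse (degC per km, default -6.5).
#' @param t_base annual-mean temperature at sea level at `lat0` (degC).
#' @param lat0,lat_gradient latitude reference and gradient (degC per
#'   degree northward).
#' @param t_seasonal_amp temperature seasonal amplitude at the coast
#'   (degC).
#' @param t_seasonal_gradient fractional increase of the seasonal
#'   amplitude per degree east of the coastal grid edge, giving the
#'   inland rise of continentality (Ic) that coastal climates show.
#' @param p_annual sea-level annual precipitation at the coast (mm).
#' @param p_winter_amp winter weighting of monthly precipitation in
#'   \[0, 1\): 0 = uniform, near 1 = strongly winter-wet.
#' @param p_coast_gradient fractional precipitation change per degree
#'   east of the western (coastal) grid edge (negative = drier inland).
#' @param p_elev_gradient fractional precipitation increase per km of
#'   elevation.
#' @param t_trend temperature trend (degC per year).
#' @param p_trend fractional precipitation trend (per year).
#' @param t_noise_sd,p_noise_sd interannual noise s.d. (degC, mm);
#'   independent across months and years.
#' @param missing_fraction fraction of cells masked missing.
#' @param contamination_fraction fraction of station-year-months given
#'   gross outliers.
#' @param contamination_t,contamination_p outlier magnitudes (degC
#'   offset; mm added).
#' @param n_soil_orders number of elevation-banded soil classes.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            grid = grid_spec(-123, 36, 0.05, 50, 50),
                            n_stations = 60L,
                            years = 1980:2019,
                            max_elev = 3200,
                            lapse_rate = -6.5,
                            t_base = 17,
                            lat0 = 36, lat_gradient = -0.7,
                            t_seasonal_amp = 8,
                            t_seasonal_gradient = 0.12,
                            p_annual = 700,
                            p_winter_amp = 0.9,
                            p_coast_gradient = -0.15,
                            p_elev_gradient = 0.35,
                            t_trend = 0, p_trend = 0,
                            t_noise_sd = 0.5, p_noise_sd = 8,
                            missing_fraction = 0,
                            contamination_fraction = 0,
                            contamination_t = 8,
                            contamination_p = 150,
                            n_soil_orders = 4L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_stations >= 3L,
            length(cfg$years) >= 10L,
            cfg$missing_fraction >= 0, cfg$missing_fraction <= 1,
            cfg$contamination_fraction >= 0,
            cfg$contamination_fraction <= 1,
            cfg$p_winter_amp >= 0, cfg$p_winter_amp < 1)
  class(cfg) <- "scenario_config"
  cfg
}

#' The statewide scenario preset
#'
#' A larger network (177 stations, 40 years, finer grid) for end-to-end
#' demonstrations at the scale of a statewide station archive.
#' @param seed root seed.
#' @param ... overrides passed to [scenario_config()].
#' @export
scenario_statewide <- function(seed = 1L, ...) {
  scenario_config(seed = seed,
                  grid = grid_spec(-124, 35, 0.05, 80, 90),
                  n_stations = 177L, t_noise_sd = 0.6, p_noise_sd = 10,
                  missing_fraction = 0.03, ...)
}

#' Generate the landscape: DEM and soil-order rasters
#'
#' The DEM is a north-south ridge (Gaussian in longitude) with a gentle
#' latitudinal rise and smooth seeded undulations, clamped to
#' `[0, max_elev]`; soil orders are elevation bands (codes
#' `1..n_soil_orders`), so soils correlate with elevation as real soil
#' catenas do.
#'
#' @param cfg a [scenario_config()].
#' @return list with `dem` (continuous) and `soil` (categorical)
#'   [raster_layer()]s.
#' @export
gen_landscape <- function(cfg) {
  g <- cfg$grid
  cc <- cell_centres(g)
  lon <- matrix(cc$x, g$nrow, g$ncol, byrow = TRUE)
  lat <- matrix(cc$y, g$nrow, g$ncol)
  ridge_lon <- g$xmin + 0.62 * g$ncol * g$cellsize
  width <- 0.18 * g$ncol * g$cellsize
  base <- cfg$max_elev * exp(-((lon - ridge_lon) / width)^2) *
    (0.75 + 0.25 * (lat - g$ymin) / (g$nrow * g$cellsize))
  und <- with_seed(cfg$seed + 1L, {
    k <- 4L
    a <- stats::runif(k, 0.02, 0.06) * cfg$max_elev
    fx <- stats::runif(k, 0.5, 2.5); fy <- stats::runif(k, 0.5, 2.5)
    ph <- stats::runif(k, 0, 2 * pi)
    Reduce(`+`, lapply(seq_len(k), function(i)
      a[i] * sin(fx[i] * lon + ph[i]) * cos(fy[i] * lat + ph[i])))
  })
  dem <- raster_layer(g, pmin(pmax(base + und, 0), cfg$max_elev))
  brks <- stats::quantile(dem$values,
                          probs = seq(0, 1, length.out =
                                        cfg$n_soil_orders + 1L))
  brks[1L] <- -Inf; brks[length(brks)] <- Inf
  soil <- raster_layer(
    g, matrix(as.integer(cut(dem$values, brks)), g$nrow, g$ncol),
    "categorical")
  list(dem = dem, soil = soil)
}

#' Place stations on the landscape
#'
#' Seeded uniform draw of distinct grid cells; stations sit at cell
#' centres with elevation read from the DEM.
#'
#' @param cfg a [scenario_config()].
#' @param dem the landscape DEM.
#' @return data.frame `station_id, lon, lat, elev, row, col`.
#' @export
gen_stations <- function(cfg, dem) {
  g <- cfg$grid
  ncells <- g$nrow * g$ncol
  stopifnot(cfg$n_stations <= ncells)
  cells <- with_seed(cfg$seed + 2L,
                     sample.int(ncells, cfg$n_stations))
  row <- (cells - 1L) %% g$nrow + 1L
  col <- (cells - 1L) %/% g$nrow + 1L
  cc <- cell_centres(g)
  data.frame(station_id = sprintf("SYN%03d", seq_len(cfg$n_stations)),
             lon = cc$x[col], lat = cc$y[row],
             elev = dem$values[cbind(row, col)],
             row = row, col = col, stringsAsFactors = FALSE)
}

# Noise-free monthly normals at a location, at the trend offset of
# `at_year` (years counted from the first scenario year).
true_monthly_climate <- function(cfg, lon, lat, elev,
                                 at_year = cfg$years[1L]) {
  m <- 1:12
  dy <- at_year - cfg$years[1L]
  amp <- cfg$t_seasonal_amp *
    (1 + cfg$t_seasonal_gradient * (lon - cfg$grid$xmin))
  t <- cfg$t_base + cfg$lat_gradient * (lat - cfg$lat0) +
    cfg$lapse_rate * elev / 1000 +
    amp * cos(2 * pi * (m - 7) / 12) +
    cfg$t_trend * dy
  coast <- max(0.05, 1 + cfg$p_coast_gradient * (lon - cfg$grid$xmin))
  elevf <- 1 + cfg$p_elev_gradient * elev / 1000
  p <- (cfg$p_annual / 12) * (1 + cfg$p_winter_amp *
                                cos(2 * pi * (m - 1) / 12)) *
    coast * elevf * max(0, 1 + cfg$p_trend * dy)
  list(t = t, p = pmax(p, 0))
}

#' Generate station climate series
#'
#' Monthly temperature = location normal + linear trend + Gaussian
#' noise; monthly precipitation = winter-weighted normal scaled by a
#' fractional linear trend plus truncated Gaussian noise (floored at 0).
#' A seeded fraction of station-month cells receives gross outliers, and
#' a seeded missingness mask is applied last. The generator asserts that
#' its lowest-elevation station is Mediterranean (two consecutive dry
#' summer months) as the scenario promises.
#'
#' @param cfg a [scenario_config()].
#' @param stations from [gen_stations()].
#' @return list of [station_series()].
#' @export
gen_climate <- function(cfg, stations) {
  ny <- length(cfg$years)
  out <- with_seed(cfg$seed + 3L, {
    lapply(seq_len(nrow(stations)), function(i) {
      st <- stations[i, ]
      tm <- matrix(NA_real_, ny, 12L)
      pm <- matrix(NA_real_, ny, 12L)
      for (yi in seq_len(ny)) {
        tr <- true_monthly_climate(cfg, st$lon, st$lat, st$elev,
                                   at_year = cfg$years[yi])
        tm[yi, ] <- tr$t + stats::rnorm(12, 0, cfg$t_noise_sd)
        pm[yi, ] <- pmax(tr$p + stats::rnorm(12, 0, cfg$p_noise_sd), 0)
      }
      if (cfg$contamination_fraction > 0) {
        bad <- stats::runif(ny * 12L) < cfg$contamination_fraction
        sgn <- sample(c(-1, 1), sum(bad), replace = TRUE)
        tm[bad] <- tm[bad] + sgn * cfg$contamination_t
        pm[bad] <- pm[bad] + cfg$contamination_p
      }
      if (cfg$missing_fraction > 0) {
        drop <- stats::runif(ny * 12L) < cfg$missing_fraction
        tm[drop] <- NA_real_
        pm[drop] <- NA_real_
      }
      station_series(st$station_id, st$lon, st$lat, st$elev,
                     cfg$years, tm, pm)
    })
  })
  low <- which.min(stations$elev)
  tr <- true_monthly_climate(cfg, stations$lon[low], stations$lat[low],
                             stations$elev[low],
                             at_year = stats::median(cfg$years))
  clim <- monthly_climatology(tr$t, tr$p)
  stopifnot(macrobioclimate_test(clim) == "Mediterranean")
  out
}

#' Ground-truth variable rasters
#'
#' Noise-free bioclimatic index layers computed from the scenario's
#' climate formula at every grid cell (at the trend offset of `at_year`,
#' by default the period midpoint), plus the elevation and soil layers.
#' These are the layers against which envelope recovery is exact.
#'
#' @param cfg a [scenario_config()].
#' @param landscape from [gen_landscape()].
#' @param at_year year whose trend offset the normals carry.
#' @return named list of [raster_layer()]s: every [ENVELOPE_VARS]
#'   member plus `Ios1`, `elevation` and `soil`.
#' @export
gen_true_layers <- function(cfg, landscape,
                            at_year = stats::median(cfg$years)) {
  g <- cfg$grid
  cc <- cell_centres(g)
  dem <- landscape$dem$values
  vars <- c(ENVELOPE_VARS, "Ios1")
  mats <- lapply(vars, function(v) matrix(NA_real_, g$nrow, g$ncol))
  names(mats) <- vars
  for (r in seq_len(g$nrow)) {
    for (cl in seq_len(g$ncol)) {
      tr <- true_monthly_climate(cfg, cc$x[cl], cc$y[r], dem[r, cl],
                                 at_year = at_year)
      v <- bioclim_indices(monthly_climatology(tr$t, tr$p))
      for (nm in vars) mats[[nm]][r, cl] <- v[[nm]]
    }
  }
  out <- lapply(mats, raster_layer, grid = g)
  out$elevation <- landscape$dem
  out$soil <- landscape$soil
  out
}

#' Generate occurrence records from a ground-truth envelope box
#'
#' Samples occurrence points from the cells whose true variable vector
#' lies inside the species' ground-truth box (uniformly, without
#' replacement while distinct cells remain), placing points at cell
#' centres. A `junk_fraction` of the requested total is replaced by
#' records the cleaning step must remove: exact duplicates of valid
#' points and (0, 0)-coordinate sentinels, in equal shares.
#'
#' @param cfg a [scenario_config()].
#' @param layers from [gen_true_layers()].
#' @param species list with `name`, `box` (named list of `c(lo, hi)`
#'   per variable), optional `soils` (admissible codes).
#' @param n total records to return.
#' @param junk_fraction fraction of `n` that is junk (default 0).
#' @return data.frame `species, lon, lat, elev`, with the admissible
#'   cell count as attribute `n_admissible`.
#' @export
gen_occurrences <- function(cfg, layers, species, n = 100,
                            junk_fraction = 0) {
  adm <- admissible_cells(layers, species)
  n_adm <- sum(adm)
  if (n_adm == 0L) stop("species box admits no cells")
  g <- cfg$grid
  cc <- cell_centres(g)
  idx <- which(adm)
  n_junk <- round(n * junk_fraction)
  n_valid <- n - n_junk
  pick <- with_seed(cfg$seed + 4L,
                    idx[sample.int(n_adm, n_valid,
                                   replace = n_valid > n_adm)])
  row <- (pick - 1L) %% g$nrow + 1L
  col <- (pick - 1L) %/% g$nrow + 1L
  valid <- data.frame(species = species$name,
                      lon = cc$x[col], lat = cc$y[row],
                      elev = layers$elevation$values[cbind(row, col)],
                      stringsAsFactors = FALSE)
  junk <- NULL
  if (n_junk > 0L) {
    n_dup <- n_junk %/% 2L
    dup <- valid[rep_len(seq_len(nrow(valid)), n_dup), , drop = FALSE]
    zero <- data.frame(species = species$name,
                       lon = rep(0, n_junk - n_dup),
                       lat = rep(0, n_junk - n_dup),
                       elev = NA_real_, stringsAsFactors = FALSE)
    junk <- rbind(dup, zero)
  }
  out <- rbind(valid, junk)
  rownames(out) <- NULL
  attr(out, "n_admissible") <- n_adm
  attr(out, "n_valid") <- n_valid
  out
}

# Logical matrix of cells inside a species' ground-truth box.
admissible_cells <- function(layers, species) {
  ref <- layers[[1L]]$values
  adm <- matrix(TRUE, nrow(ref), ncol(ref))
  for (nm in names(species$box)) {
    if (is.null(layers[[nm]])) stop("no layer for box variable ", nm)
    v <- layers[[nm]]$values
    b <- species$box[[nm]]
    adm <- adm & !is.na(v) & v >= b[1L] & v <= b[2L]
  }
  if (!is.null(species$soils))
    adm <- adm & layers$soil$values %in% species$soils
  adm
}
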