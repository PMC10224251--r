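# End-to-end orchestration: characterisation, projection and suitability
# stages over in-memory objects, with optional CSV/ASCII-grid output and
# a reproducibility manifest.

#' Characterisation stage
#'
#' Quality-filters and gap-fills the station network, computes the
#' period index table, diagnoses each station's isobioclimate and, when
#' occurrence records and variable layers are supplied, fits each
#' species' envelope from the layer values at its occurrence points and
#' summarises the isobioclimates it occupies (each occurrence inherits
#' the diagnosis of its nearest retained station).
#'
#' @param stations list of [station_series()] (raw; may contain missing
#'   cells).
#' @param occurrences optional cleaned occurrence data.frame
#'   (`species, lon, lat`).
#' @param layers optional named list of variable [raster_layer()]s
#'   (including `elevation` and `soil`) used to attribute occurrences.
#' @param max_missing_fraction QC gate, see [qc_filter_stations()].
#' @param years climatology period, see [climatology_of()].
#' @param tables threshold tables for diagnosis.
#' @param outdir optional directory for CSV outputs.
#' @return list with `stations`, `rejected`, `index_table`,
#'   `diagnoses`, and per-species `envelopes` and `isobioclimates`.
#' @export
run_characterise <- function(stations, occurrences = NULL,
                             layers = NULL,
                             max_missing_fraction = 0.10,
                             years = NULL,
                             tables = load_threshold_tables(),
                             outdir = NULL) {
  qc <- qc_filter_stations(stations, max_missing_fraction)
  kept <- lapply(qc$kept, impute_monthly_means)
  idx <- station_index_table(kept, years)
  clims <- lapply(kept, climatology_of, years = years)
  diags <- lapply(seq_along(kept), function(i)
    diagnose_isobioclimate(
      bioclim_indices(clims[[i]], elevation = kept[[i]]$elevation),
      clims[[i]], tables))
  names(diags) <- idx$station_id
  envelopes <- list(); isoclims <- list()
  if (!is.null(occurrences) && !is.null(layers)) {
    for (sp in unique(occurrences$species)) {
      occ <- occurrences[occurrences$species == sp, , drop = FALSE]
      vals <- occurrence_values(occ, layers)
      envelopes[[sp]] <- bioclim_envelope(vals, species = sp)
      near <- nearest_station(occ, idx)
      isoclims[[sp]] <- species_isobioclimate_summary(diags[near])
    }
  }
  out <- list(stations = kept, rejected = qc$rejected,
              index_table = idx, diagnoses = diags,
              envelopes = envelopes, isobioclimates = isoclims)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(idx, file.path(outdir, "station_indices.csv"),
                     row.names = FALSE)
    utils::write.csv(qc$rejected, file.path(outdir, "qc_rejected.csv"),
                     row.names = FALSE)
    diag_tab <- data.frame(
      station_id = names(diags),
      t(vapply(diags, function(d) unlist(d[c(
        "macrobioclimate", "bioclimate", "variant", "continentality",
        "thermotype", "ombrotype")]), character(6))),
      row.names = NULL, stringsAsFactors = FALSE)
    utils::write.csv(diag_tab, file.path(outdir, "diagnoses.csv"),
                     row.names = FALSE)
    for (sp in names(envelopes))
      utils::write.csv(summarize_envelope(envelopes[[sp]]),
                       file.path(outdir, paste0("envelope_",
                                                gsub("\\W+", "_", sp),
                                                ".csv")),
                       row.names = FALSE)
  }
  out
}

#' Sample variable layers at occurrence points
#'
#' @param occ occurrence data.frame with `lon, lat`.
#' @param layers named list of [raster_layer()]s; the `soil` entry, if
#'   present, becomes the categorical `soil` column.
#' @return data.frame, one row per occurrence.
#' @export
occurrence_values <- function(occ, layers) {
  vals <- lapply(layers, sample_raster, lon = occ$lon, lat = occ$lat)
  as.data.frame(vals, optional = TRUE)
}

nearest_station <- function(occ, idx) {
  vapply(seq_len(nrow(occ)), function(i)
    which.min((idx$lon - occ$lon[i])^2 + (idx$lat - occ$lat[i])^2),
    integer(1))
}

#' Projection stage
#'
#' Fits the five-trend-model ensemble per station-month, reports the
#' model-selection frequencies, and projects every station's monthly
#' climate and bioclimatic indices to the target year.
#'
#' @param stations list of complete [station_series()].
#' @param target_year default 2050.
#' @param criterion,methods,... passed to the trend fitting, see
#'   [select_best_model()].
#' @param outdir optional directory for CSV outputs.
#' @return list with `fit_report`, `frequencies`, `climatologies`
#'   (per station) and `index_table` at the target year.
#' @export
run_project <- function(stations, target_year = 2050,
                        criterion = c("mar", "rmse"),
                        methods = MODEL_ORDER, ..., outdir = NULL) {
  criterion <- match.arg(criterion)
  report <- fit_station_trends(stations, methods, criterion, ...)
  freqs <- model_selection_frequencies(report)
  clims <- lapply(stations, project_station, target_year = target_year,
                  methods = methods, criterion = criterion, ...)
  idx <- do.call(rbind, lapply(seq_along(stations), function(i) {
    s <- stations[[i]]
    v <- bioclim_indices(clims[[i]], elevation = s$elevation)
    data.frame(station_id = s$station_id, lon = s$longitude,
               lat = s$latitude, t(unclass(v)),
               stringsAsFactors = FALSE)
  }))
  rownames(idx) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report, file.path(outdir, "trend_fits.csv"),
                     row.names = FALSE)
    utils::write.csv(freqs, file.path(outdir,
                                      "model_frequencies.csv"),
                     row.names = FALSE)
    utils::write.csv(idx, file.path(outdir, "station_indices_future.csv"),
                     row.names = FALSE)
  }
  list(fit_report = report, frequencies = freqs,
       climatologies = clims, index_table = idx)
}

#' Suitability and change stage
#'
#' Interpolates every envelope variable from the station index tables
#' onto the grid for the reference and future periods (elevation and
#' soil layers are period-invariant), builds suitable and optimal maps
#' for each envelope, derives the change rasters and the
#' gain/unstable/stable percentage table.
#'
#' @param index_current,index_future station index tables
#'   (from [station_index_table()] / [run_project()]).
#' @param envelopes named list of [bioclim_envelope()]s.
#' @param dem elevation [raster_layer()] (defines the grid).
#' @param soil optional categorical soil [raster_layer()].
#' @param method,... interpolation options, see
#'   [interpolate_surface()].
#' @param outdir optional directory for ASCII-grid and CSV outputs.
#' @return list with `layers_current`, `layers_future`, and per species
#'   `maps` (current/future suitable/optimal, change rasters) and
#'   `percentages` (data.frame species x class).
#' @export
run_suitability <- function(index_current, index_future, envelopes,
                            dem, soil = NULL, method = "idw", ...,
                            outdir = NULL) {
  vars <- unique(unlist(lapply(envelopes, function(e)
    setdiff(e$stats$variable, "elevation"))))
  interp_all <- function(idx) {
    ly <- lapply(vars, function(v)
      interpolate_surface(
        data.frame(lon = idx$lon, lat = idx$lat, value = idx[[v]]),
        dem$grid, method = method, ...))
    names(ly) <- vars
    ly$elevation <- dem
    ly
  }
  cur <- interp_all(index_current)
  fut <- interp_all(index_future)
  maps <- list(); rows <- list()
  for (sp in names(envelopes)) {
    e <- envelopes[[sp]]
    m <- list(
      suitable_current = suitability_map(e, cur, "suitable", soil),
      suitable_future = suitability_map(e, fut, "suitable", soil),
      optimal_current = suitability_map(e, cur, "optimal", soil),
      optimal_future = suitability_map(e, fut, "optimal", soil))
    m$change_suitable <- change_map(m$suitable_current,
                                    m$suitable_future)
    m$change_optimal <- change_map(m$optimal_current, m$optimal_future)
    maps[[sp]] <- m
    for (cls in c("suitable", "optimal")) {
      pc <- suppressWarnings(
        summarize_change(m[[paste0("change_", cls)]]))
      rows[[paste(sp, cls)]] <- data.frame(
        species = sp, class = cls, gain = pc[["gain"]],
        unstable = pc[["unstable"]], stable = pc[["stable"]],
        stringsAsFactors = FALSE)
    }
  }
  percentages <- do.call(rbind, rows)
  rownames(percentages) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(percentages,
                     file.path(outdir, "change_percentages.csv"),
                     row.names = FALSE)
    for (sp in names(maps))
      for (nm in c("change_suitable", "change_optimal"))
        write_ascii_grid(maps[[sp]][[nm]],
                         file.path(outdir,
                                   paste0(gsub("\\W+", "_", sp), "_",
                                          nm, ".asc")))
  }
  list(layers_current = cur, layers_future = fut, maps = maps,
       percentages = percentages)
}

#' Run a full synthetic scenario end to end
#'
#' Generates the landscape, stations, climate and occurrences for each
#' configured species, then runs characterisation, projection and
#' suitability, returning all stage outputs plus a run manifest
#' sufficient to reproduce the run.
#'
#' @param cfg a [scenario_config()].
#' @param species list of species definitions, see [gen_occurrences()].
#' @param n_occurrences points per species.
#' @param target_year projection year.
#' @param criterion trend-selection criterion.
#' @param interp_method surface interpolation method.
#' @param outdir optional output directory (CSV, grids, manifest JSON).
#' @return list with `landscape, stations, climate, true_layers,
#'   occurrences, characterisation, projection, suitability, manifest`.
#' @export
run_scenario <- function(cfg, species, n_occurrences = 150,
                         target_year = 2050,
                         criterion = c("mar", "rmse"),
                         interp_method = "idw", outdir = NULL) {
  criterion <- match.arg(criterion)
  t0 <- Sys.time()
  landscape <- gen_landscape(cfg)
  st <- gen_stations(cfg, landscape$dem)
  climate <- gen_climate(cfg, st)
  true_layers <- gen_true_layers(cfg, landscape)
  occ <- do.call(rbind, lapply(species, function(sp)
    gen_occurrences(cfg, true_layers, sp, n = n_occurrences)))
  chr <- run_characterise(climate, occ, true_layers,
                          outdir = if (is.null(outdir)) NULL
                                   else file.path(outdir, "characterise"))
  prj <- run_project(chr$stations, target_year = target_year,
                     criterion = criterion,
                     outdir = if (is.null(outdir)) NULL
                              else file.path(outdir, "project"))
  sut <- run_suitability(chr$index_table, prj$index_table,
                         chr$envelopes, landscape$dem, landscape$soil,
                         method = interp_method,
                         outdir = if (is.null(outdir)) NULL
                                  else file.path(outdir, "suitability"))
  manifest <- list(
    seed = cfg$seed,
    config_md5 = config_digest(cfg),
    package_version = as.character(utils::packageVersion("bioclimenv")),
    target_year = target_year, criterion = criterion,
    interpolation = interp_method,
    n_stations_kept = length(chr$stations),
    elapsed_s = round(as.numeric(difftime(Sys.time(), t0,
                                          units = "secs")), 2))
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  list(landscape = landscape, stations = st, climate = climate,
       true_layers = true_layers, occurrences = occ,
       characterisation = chr, projection = prj, suitability = sut,
       manifest = manifest)
}

config_digest <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(unclass(cfg)))]), f)
  unname(tools::md5sum(f))
}
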