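# Regular-grid rasters, station-to-grid interpolation (inverse-distance
# and ordinary kriging) and nearest-cell sampling. Geometry convention:
# WGS84 lon/lat (or any planar CRS tag), cell-centre registration,
# half-open cells, row 1 = northernmost row.

#' Regular grid specification
#'
#' @param xmin,ymin coordinates of the lower-left grid corner.
#' @param cellsize cell edge length (degrees or metres per `crs`).
#' @param ncol,nrow grid dimensions (>= 1).
#' @param crs free-text CRS tag (default `"EPSG:4326"`).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(xmin, ymin, cellsize, ncol, nrow,
                      crs = "EPSG:4326") {
  stopifnot(cellsize > 0, ncol >= 1, nrow >= 1)
  structure(list(xmin = xmin, ymin = ymin, cellsize = cellsize,
                 ncol = as.integer(ncol), nrow = as.integer(nrow),
                 crs = crs),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %dx%d cells of %g, origin (%g, %g), %s\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$ymin, x$crs))
  invisible(x)
}

# Cell-centre coordinate vectors: x by column, y by row (row 1 = north).
cell_centres <- function(grid) {
  list(x = grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$cellsize,
       y = grid$ymin + (grid$nrow - seq_len(grid$nrow) + 0.5) *
         grid$cellsize)
}

#' Raster layer on a regular grid
#'
#' @param grid a [grid_spec()].
#' @param values numeric matrix `nrow x ncol` (row 1 = northernmost);
#'   `NA` = nodata. A scalar is recycled.
#' @param semantics `"continuous"` or `"categorical"` (coded labels).
#' @return object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values,
                         semantics = c("continuous", "categorical")) {
  semantics <- match.arg(semantics)
  if (length(values) == 1L)
    values <- matrix(values, grid$nrow, grid$ncol)
  values <- as.matrix(values)
  if (!identical(dim(values), c(grid$nrow, grid$ncol)))
    stop("values shape does not match grid")
  structure(list(grid = grid, values = values, semantics = semantics),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<raster_layer:%s> %dx%d, range [%g, %g], %d nodata\n",
              x$semantics, x$grid$nrow, x$grid$ncol,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
plot.raster_layer <- function(x, main = NULL, ...) {
  cc <- cell_centres(x$grid)
  graphics::image(cc$x, rev(cc$y), t(x$values[x$grid$nrow:1, , drop = FALSE]),
                  xlab = "lon", ylab = "lat", main = main,
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, ...)
  invisible(x)
}

#' Interpolate station values onto a grid
#'
#' Inverse-distance weighting (power `idw_power`, exact at stations that
#' fall within `snap` of a cell centre) or ordinary kriging with a linear
#' or spherical semivariogram fitted to the empirical variogram cloud.
#' Kriging is an exact interpolator at the data points (zero nugget by
#' default); if the kriging system cannot be solved or the variogram fit
#' degenerates, the function falls back to IDW with a warning. Distances
#' are Euclidean in the grid's CRS units.
#'
#' @param points data.frame with columns `lon, lat, value` (finite).
#' @param grid a [grid_spec()].
#' @param method `"idw"` or `"ordinary_kriging"`.
#' @param variogram `"linear"`, `"power"` or `"spherical"` (kriging
#'   only). The power model `b h^a` (exponent fitted in (0, 2) on the
#'   log-log variogram cloud) follows smooth trend-dominated fields such
#'   as index surfaces much more closely than the linear model, whose
#'   shape makes the kriging weights insensitive to its slope.
#' @param idw_power IDW power (default 2).
#' @param nugget kriging nugget (default 0, exact interpolation).
#' @param snap distance treated as coincident with a station.
#' @return continuous [raster_layer()]; every cell receives a value.
#' @export
interpolate_surface <- function(points, grid,
                                method = c("idw", "ordinary_kriging"),
                                variogram = c("linear", "power",
                                              "spherical"),
                                idw_power = 2, nugget = 0,
                                snap = 1e-9) {
  method <- match.arg(method)
  variogram <- match.arg(variogram)
  stopifnot(all(c("lon", "lat", "value") %in% names(points)))
  pts <- points[is.finite(points$lon) & is.finite(points$lat) &
                  is.finite(points$value), , drop = FALSE]
  if (nrow(pts) < 1L) stop("no finite points to interpolate")
  cc <- cell_centres(grid)
  gx <- rep(cc$x, each = grid$nrow)
  gy <- rep(cc$y, times = grid$ncol)
  # distance matrix: cells x stations
  d <- sqrt(outer(gx, pts$lon, "-")^2 + outer(gy, pts$lat, "-")^2)
  vals <- NULL
  if (method == "ordinary_kriging") {
    if (nrow(pts) < 3L)
      stop("ordinary kriging needs at least 3 points")
    vals <- tryCatch(
      krige_values(pts, d, variogram, nugget),
      error = function(e) {
        warning("kriging failed (", conditionMessage(e),
                "); falling back to IDW")
        NULL
      })
  }
  if (is.null(vals)) vals <- idw_values(pts$value, d, idw_power, snap)
  raster_layer(grid, matrix(vals, grid$nrow, grid$ncol), "continuous")
}

idw_values <- function(v, d, power, snap) {
  w <- 1 / pmax(d, snap)^power
  w <- w / rowSums(w)
  est <- as.vector(w %*% v)
  hit <- d <= snap
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    est[idx[, 1L]] <- v[idx[, 2L]]
  }
  est
}

# Fit a variogram model to the pairwise cloud and solve the ordinary
# kriging system once for all grid cells.
krige_values <- function(pts, d, variogram, nugget) {
  n <- nrow(pts)
  dp <- as.matrix(stats::dist(cbind(pts$lon, pts$lat)))
  if (any(dp[upper.tri(dp)] == 0))
    stop("duplicate station locations")
  sv <- 0.5 * outer(pts$value, pts$value, "-")^2
  hu <- dp[upper.tri(dp)]
  su <- sv[upper.tri(sv)]
  gam <- fit_variogram(hu, su, variogram, nugget)
  A <- rbind(cbind(gam(dp), 1), c(rep(1, n), 0))
  B <- rbind(t(gam(d)), 1)           # (n+1) x ncells
  W <- solve(A, B)
  est <- as.vector(crossprod(W[seq_len(n), , drop = FALSE], pts$value))
  # exactness at data locations despite numeric round-off
  hit <- d <= 1e-9
  if (any(hit)) {
    idx <- which(hit, arr.ind = TRUE)
    est[idx[, 1L]] <- pts$value[idx[, 2L]]
  }
  est
}

fit_variogram <- function(h, s, model, nugget) {
  if (model == "linear") {
    b <- sum(h * s) / sum(h * h)  # least squares through the nugget
    if (!is.finite(b) || b <= 0) stop("flat linear variogram")
    function(d) nugget + b * d
  } else if (model == "power") {
    pos <- s > 0 & h > 0
    if (sum(pos) < 3L) stop("too few pairs for power variogram")
    a <- stats::cov(log(h[pos]), log(s[pos])) / stats::var(log(h[pos]))
    a <- min(max(a, 0.1), 1.99)  # validity requires exponent < 2
    b <- sum(h^a * s) / sum(h^(2 * a))
    if (!is.finite(b) || b <= 0) stop("flat power variogram")
    function(d) nugget + b * d^a
  } else {
    # spherical: moment fit of sill and range from the binned cloud
    rng0 <- stats::quantile(h, 0.7, names = FALSE)
    sill0 <- mean(s[h >= rng0])
    if (!is.finite(sill0) || sill0 <= 0) stop("flat spherical variogram")
    obj <- function(p) {
      rng <- p[1L]; sill <- p[2L]
      if (rng <= 0 || sill <= 0) return(Inf)
      g <- ifelse(h >= rng, sill,
                  sill * (1.5 * h / rng - 0.5 * (h / rng)^3))
      sum((g + nugget - s)^2)
    }
    p <- stats::optim(c(rng0, sill0), obj)$par
    rng <- p[1L]; sill <- p[2L]
    function(d) {
      g <- ifelse(d >= rng, sill,
                  sill * (1.5 * d / rng - 0.5 * (d / rng)^3))
      nugget + g
    }
  }
}

#' Sample a raster at point locations
#'
#' Nearest-cell (containing-cell) lookup, no interpolation between
#' cells; points outside the grid bounds yield `NA`.
#'
#' @param layer a [raster_layer()].
#' @param lon,lat point coordinates.
#' @return numeric vector of cell values.
#' @export
sample_raster <- function(layer, lon, lat) {
  g <- layer$grid
  cx <- (lon - g$xmin) / g$cellsize
  ry <- (lat - g$ymin) / g$cellsize
  col <- floor(cx) + 1L
  row <- g$nrow - floor(ry)
  ok <- cx >= 0 & cx < g$ncol & ry >= 0 & ry < g$nrow
  out <- rep(NA_real_, length(lon))
  out[ok] <- layer$values[cbind(row[ok], col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` raster (header + rows north to south), readable by
#' standard GIS tools; the package's on-disk raster format.
#'
#' @param layer a [raster_layer()].
#' @param path output file.
#' @param nodata nodata code written for `NA` (default -9999).
#' @export
write_ascii_grid <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  hdr <- c(paste("NCOLS", g$ncol), paste("NROWS", g$nrow),
           paste("XLLCORNER", g$xmin), paste("YLLCORNER", g$ymin),
           paste("CELLSIZE", g$cellsize), paste("NODATA_VALUE", nodata))
  v <- layer$values
  v[is.na(v)] <- nodata
  lines <- apply(v, 1L, function(r)
    paste(format(r, trim = TRUE, scientific = FALSE), collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path `.asc` file.
#' @param semantics see [raster_layer()].
#' @param crs CRS tag to attach.
#' @return a [raster_layer()].
#' @export
read_ascii_grid <- function(path, semantics = "continuous",
                            crs = "EPSG:4326") {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- toupper(vapply(hdr, `[[`, "", 1L))
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  h <- stats::setNames(vals, keys)
  v <- matrix(scan(text = paste(lines[-(1:6)], collapse = "\n"),
                   quiet = TRUE),
              nrow = h[["NROWS"]], ncol = h[["NCOLS"]], byrow = TRUE)
  v[v == h[["NODATA_VALUE"]]] <- NA_real_
  raster_layer(grid_spec(h[["XLLCORNER"]], h[["YLLCORNER"]],
                         h[["CELLSIZE"]], h[["NCOLS"]], h[["NROWS"]],
                         crs),
               v, semantics)
}
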