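# Envelope fitting, CON masks, suitability maps and change algebra.

mk_layers <- function(g, ...) {
  vals <- list(...)
  lapply(vals, function(v) raster_layer(g, v))
}

test_that("envelope quantiles follow the pinned linear-interpolation estimator", {
  d <- data.frame(Tavg = c(3, 5, 7, 9), Io = c(1, 1, 1, 1))
  e <- bioclim_envelope(d, "sp", vars = c("Tavg", "Io"), soil_col = NULL)
  s <- e$stats[e$stats$variable == "Tavg", ]
  # linear interpolation of order statistics (stats::quantile type 7)
  expect_equal(unlist(s[c("min", "q1", "q3", "max")], use.names = FALSE),
               c(3, 4.5, 7.5, 9))
  expect_equal(s$q1, unname(quantile(d$Tavg, 0.25, type = 7)))
  expect_equal(s$q3, unname(quantile(d$Tavg, 0.75, type = 7)))
  io <- e$stats[e$stats$variable == "Io", ]
  expect_true(all(unlist(io[-1]) == 1))  # degenerate: min=Q1=Q3=max
})

test_that("envelope drops incomplete rows with warning, errors under 4 points", {
  d <- data.frame(Tavg = c(1, 2, 3, 4, NA), Io = c(1, 2, 3, 4, 5))
  expect_warning(e <- bioclim_envelope(d, vars = c("Tavg", "Io"),
                                       soil_col = NULL), "dropped")
  expect_identical(e$n_occurrences, 4L)
  expect_error(suppressWarnings(
    bioclim_envelope(d[1:3, ], vars = c("Tavg", "Io"), soil_col = NULL)),
    "at least 4")
})

test_that("envelope converges to a known ground-truth box as n grows", {
  set.seed(17)
  box <- c(2, 8)
  width <- function(n) {
    x <- runif(n, box[1], box[2])
    e <- bioclim_envelope(data.frame(Tavg = x), vars = "Tavg",
                          soil_col = NULL)
    s <- e$stats
    expect_gte(s$min, box[1]); expect_lte(s$max, box[2])
    (s$min - box[1]) + (box[2] - s$max)
  }
  expect_lt(width(2000), width(20))
})

test_that("con_mask is inclusive at both bounds and zero on nodata", {
  g <- grid_spec(0, 0, 1, 3, 2)
  v <- matrix(c(1, 2, 3, 4, 5, NA), 2, 3)
  m <- con_mask(raster_layer(g, v), 2, 4)
  expect_equal(m$values, matrix(c(0, 1, 1, 1, 0, 0), 2, 3))
  set.seed(18)
  r <- matrix(runif(60, 0, 10), 6, 10)
  g2 <- grid_spec(0, 0, 1, 10, 6)
  mm <- con_mask(raster_layer(g2, r), 3, 7)$values
  for (i in seq_along(r))  # cell-by-cell oracle loop
    expect_identical(mm[i], if (r[i] >= 3 && r[i] <= 7) 1 else 0)
})

test_that("suitability is a conjunction; optimal is nested in suitable", {
  g <- grid_spec(0, 0, 1, 4, 4)
  set.seed(19)
  A <- matrix(runif(16, 0, 10), 4); B <- matrix(runif(16, 0, 10), 4)
  d <- data.frame(Tavg = c(2, 4, 6, 8), Io = c(1, 3, 5, 7))
  e <- bioclim_envelope(d, vars = c("Tavg", "Io"), soil_col = NULL)
  layers <- mk_layers(g, Tavg = A, Io = B)
  suit <- suitability_map(e, layers, "suitable")
  opt <- suitability_map(e, layers, "optimal")
  expect_true(all(opt$values <= suit$values))
  man <- (A >= 2 & A <= 8) * (B >= 1 & B <= 7)
  expect_equal(suit$values, man)
  # violating exactly one variable zeroes the cell
  A2 <- A; A2[1, 1] <- 99
  suit2 <- suitability_map(e, mk_layers(g, Tavg = A2, Io = B), "suitable")
  expect_equal(suit2$values[1, 1], 0)
  expect_error(suitability_map(e, layers["Tavg"], "suitable"), "missing")
})

test_that("soil admissibility is a hard AND when a soil layer is supplied", {
  g <- grid_spec(0, 0, 1, 2, 2)
  d <- data.frame(Tavg = c(1, 2, 3, 4), soil = c(1, 1, 2, 2))
  e <- bioclim_envelope(d, vars = "Tavg")
  expect_identical(e$soil_orders, c(1, 2))
  layers <- mk_layers(g, Tavg = matrix(2, 2, 2))
  soil <- raster_layer(g, matrix(c(1, 2, 3, 1), 2, 2), "categorical")
  suit <- suitability_map(e, layers, "suitable", soil = soil)
  expect_equal(suit$values, matrix(c(1, 1, 0, 1), 2, 2))
})

test_that("change map codes the four transitions and partitions the grid", {
  g <- grid_spec(0, 0, 1, 2, 2)
  cur <- raster_layer(g, matrix(c(0, 1, 1, 0), 2, 2))
  fut <- raster_layer(g, matrix(c(0, 0, 1, 1), 2, 2))
  ch <- change_map(cur, fut)
  expect_equal(ch$values, matrix(c(0L, 2L, 3L, 1L), 2, 2))
  set.seed(20)
  for (i in 1:20) {
    a <- matrix(rbinom(100, 1, 0.4), 10)
    b <- matrix(rbinom(100, 1, 0.4), 10)
    ch <- change_map(raster_layer(grid_spec(0, 0, 1, 10, 10), a),
                     raster_layer(grid_spec(0, 0, 1, 10, 10), b))
    expect_equal((ch$values == 1L) + (ch$values == 3L) > 0, b == 1)
    expect_equal((ch$values == 2L) + (ch$values == 3L) > 0, a == 1)
  }
})

test_that("change percentages use current-area denominators", {
  g <- grid_spec(0, 0, 1, 15, 7)
  cur <- matrix(0, 7, 15); fut <- matrix(0, 7, 15)
  cur[1:100] <- 1                    # 100 current cells
  fut[which(cur == 1)[1:40]] <- 1    # 40 stable
  fut[which(cur == 0)[1:5]] <- 1     # 5 gained
  pc <- summarize_change(change_map(raster_layer(g, cur),
                                    raster_layer(g, fut)))
  expect_equal(pc, c(gain = 5, unstable = 60, stable = 40))
  same <- summarize_change(change_map(raster_layer(g, cur),
                                      raster_layer(g, cur)))
  expect_equal(same, c(gain = 0, unstable = 0, stable = 100))
  empty <- change_map(raster_layer(g, matrix(0, 7, 15)),
                      raster_layer(g, matrix(0, 7, 15)))
  expect_warning(pc0 <- summarize_change(empty), "undefined")
  expect_true(all(is.na(pc0)))
})

test_that("characterisation table is ordered and rendered in the compact layout", {
  set.seed(21)
  d <- as.data.frame(matrix(runif(13 * 8, 0, 20), 8,
                            dimnames = list(NULL, ENVELOPE_VARS)))
  e <- bioclim_envelope(d, "sp", soil_col = NULL)
  s <- summarize_envelope(e)
  expect_identical(s$variable, ENVELOPE_VARS)
  expect_identical(nrow(s), 13L)
  txt <- format_characterisation(e)
  expect_match(txt, "^Tavg: ")
  # collapsed interquartile interval renders as a single bracketed value
  dd <- data.frame(Ic = c(22.5, 23.1, 23.1, 23.1, 23.1, 27.3))
  ee <- bioclim_envelope(dd, vars = "Ic", soil_col = NULL)
  expect_match(format_characterisation(ee), "Ic: 22.5 (23.1) 27.3",
               fixed = TRUE)
  # rendered numbers parse back within rounding distance; a collapsed
  # bracket stands for both quartiles
  parts <- strsplit(txt, "; ")[[1]]
  parsed <- lapply(parts, function(pp) {
    n <- as.numeric(  # a hyphen after a digit separates, it is not a sign
      regmatches(pp, gregexpr("(?<![0-9])-?[0-9]+\\.[0-9]+", pp,
                              perl = TRUE))[[1]])
    if (length(n) == 3L) n[c(1, 2, 2, 3)] else n
  })
  raw <- e$stats[match(summarize_envelope(e)$variable, e$stats$variable),
                 c("min", "q1", "q3", "max")]
  for (i in seq_along(parsed))
    expect_true(all(abs(parsed[[i]] - unlist(raw[i, ])) <= 0.05 + 1e-9))
})
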