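# Index formulas against brute-force oracles and their algebraic laws.

test_that("climatology_of averages month-wise and honours year ranges", {
  s <- toy_station(years = 2001:2002)
  s$temp[, 1] <- c(4, 6)
  cl <- climatology_of(s)
  expect_equal(cl$t[1], 5)
  one <- climatology_of(s, years = 2002)
  expect_equal(one$t, unname(s$temp[2, ]))
  expect_error(climatology_of(s, years = 1950:1960), "disjoint")
})

test_that("climatology recovers known normals from a noisy series", {
  set.seed(1)
  normals <- 10 + sin(2 * pi * (1:12 - 7) / 12) * 8
  ny <- 40; sd <- 1.5
  tm <- matrix(rep(normals, each = ny), ny) + rnorm(ny * 12, 0, sd)
  s <- station_series("N", -120, 38, 0, 2000 + 1:ny, tm,
                      matrix(50, ny, 12))
  cl <- climatology_of(s)
  expect_true(all(abs(cl$t - normals) < 3 * sd / sqrt(ny)))
})

test_that("positive sums use only months above 0 degC, Tp in tenths", {
  cl <- monthly_climatology(rep(10, 12), rep(50, 12))
  expect_equal(positive_sums(cl), c(Tp = 1200, Pp = 600))
  t <- c(-2, -2, rep(10, 10)); p <- rep(30, 12)
  ps <- positive_sums(monthly_climatology(t, p))
  expect_equal(ps[["Tp"]], 1000)
  expect_equal(ps[["Pp"]], 300)  # cold months' precipitation excluded
})

test_that("thermal extremes and Ic match a sort-based oracle", {
  cl <- monthly_climatology(1:12, rep(10, 12))
  expect_equal(thermal_extremes(cl), c(Tmax = 12, Tmin = 1, Ic = 11))
  expect_equal(thermal_extremes(monthly_climatology(rep(10, 12),
                                                    rep(0, 12)))[["Ic"]], 0)
  set.seed(2)
  for (i in 1:50) {
    cl <- rand_clim()
    srt <- sort(cl$t)
    ex <- thermal_extremes(cl)
    expect_equal(ex[["Ic"]], srt[12] - srt[1])
  }
})

test_that("thermicity and its continentality compensation", {
  # Ic 12.1: inside the no-compensation band
  cl <- monthly_climatology(c(rep(10.25, 10), 2, 14.1), rep(10, 12))
  th <- thermicity(cl)
  expect_equal(th[["It"]], th[["Itc"]])
  # hyperoceanic side: a climatology with Ic 8.1 and It 186.4
  mean_needed <- 186.4 / 10 - 2 * 5
  rest <- (12 * mean_needed - 5 - 13.1) / 10
  cl2 <- monthly_climatology(c(rep(rest, 10), 5, 13.1), rep(10, 12))
  th2 <- thermicity(cl2)
  expect_equal(th2[["It"]], 186.4, tolerance = 1e-9)
  expect_equal(th2[["Itc"]], 186.4 - 10 * (9 - 8.1), tolerance = 1e-9)
  # band edges belong to the identity band
  expect_equal(bioclimenv:::compensation_value(9), 0)
  expect_equal(bioclimenv:::compensation_value(18), 0)
  expect_equal(bioclimenv:::compensation_value(20), 10)
  expect_equal(bioclimenv:::compensation_value(23),
               3 * 5 + 2 * 10)  # cumulative slopes above 18 then 21
})

test_that("ombrothermic index and its undefined marker", {
  expect_equal(ombrothermic(monthly_climatology(rep(10, 12), rep(50, 12))), 5)
  expect_equal(ombrothermic(monthly_climatology(rep(10, 12), rep(0, 12))), 0)
  expect_true(is.na(ombrothermic(monthly_climatology(rep(-1, 12),
                                                     rep(50, 12)))))
})

test_that("summer quarter and the four summer ombrothermic indices", {
  t <- c(2, 3, 5, 8, 15, 20, 25, 22, 15, 10, 5, 3)
  p <- c(90, 80, 70, 50, 20, 10, 5, 15, 30, 50, 80, 90)
  cl <- monthly_climatology(t, p)
  expect_identical(summer_quarter(cl), 6:8)
  ios <- summer_ombrothermic(cl)
  expect_equal(ios[["Ios1"]], 5 / 25)
  expect_equal(ios[["Ios2"]], (5 + 15) / (25 + 22))
  expect_equal(ios[["Ios3"]], 30 / 67)
  expect_equal(ios[["Ios4"]], (20 + 30) / (15 + 67))
  # uniform year: every Ios is the common ratio
  clu <- monthly_climatology(rep(20, 12), rep(20, 12))
  expect_equal(unname(summer_ombrothermic(clu)), rep(1, 4))
  # doubling all precipitation doubles every Ios
  cl2 <- monthly_climatology(t, 2 * p)
  expect_equal(unname(summer_ombrothermic(cl2)),
               2 * unname(summer_ombrothermic(cl)))
})

test_that("index vector satisfies its defining identities on random climatologies", {
  set.seed(3)
  for (i in 1:200) {
    cl <- rand_clim()
    v <- bioclim_indices(cl)
    o <- oracle_indices(cl)
    expect_equal(v[["Ic"]], v[["Tmax"]] - v[["Tmin"]])
    expect_equal(v[["Tp"]], o$Tp, tolerance = 1e-12)
    expect_equal(v[["Ios3"]], o$Ios3, tolerance = 1e-12)
  }
})

test_that("precipitation homogeneity and temperature shift laws", {
  set.seed(4)
  for (i in 1:50) {
    cl <- rand_clim()
    k <- runif(1, 0.5, 3)
    v <- bioclim_indices(cl)
    vk <- bioclim_indices(monthly_climatology(cl$t, k * cl$p,
                                              cl$hemisphere))
    for (nm in c("Pavg", "Pp", "Io", "Ios1", "Ios2", "Ios3", "Ios4"))
      expect_equal(vk[[nm]], k * v[[nm]], tolerance = 1e-12)
    for (nm in c("Tavg", "Tmax", "Tmin", "Ic", "It", "Itc", "Tp"))
      expect_equal(vk[[nm]], v[[nm]])
  }
  # shift law on all-positive climatologies
  for (i in 1:50) {
    t <- runif(12, 1, 25); p <- runif(12, 0, 300); d <- runif(1, 0.5, 4)
    v <- bioclim_indices(monthly_climatology(t, p))
    vd <- bioclim_indices(monthly_climatology(t + d, p))
    expect_equal(vd[["Tavg"]], v[["Tavg"]] + d)
    expect_equal(vd[["Tmax"]], v[["Tmax"]] + d)
    expect_equal(vd[["Tmin"]], v[["Tmin"]] + d)
    expect_equal(vd[["Ic"]], v[["Ic"]], tolerance = 1e-12)
    expect_equal(vd[["It"]], v[["It"]] + 30 * d, tolerance = 1e-9)
  }
})

test_that("Ios3 equals Io of a synthetic year made of the summer months", {
  set.seed(5)
  for (i in 1:20) {
    cl <- rand_clim()
    sq <- summer_quarter(cl)
    if (sum(cl$t[sq]) <= 0) next
    year3 <- monthly_climatology(rep(cl$t[sq], 4), rep(cl$p[sq], 4))
    if (any(cl$t[sq] <= 0)) next  # Io excludes sub-zero months, Ios3 does not
    expect_equal(summer_ombrothermic(cl, sq)[["Ios3"]],
                 ombrothermic(year3), tolerance = 1e-12)
  }
})

test_that("aggregate vector carries elevation/soil as absent, not zero", {
  v <- bioclim_indices(monthly_climatology(rep(10, 12), rep(50, 12)))
  expect_true(is.na(v[["elevation"]]))
  expect_true(is.na(attr(v, "soil_order")))
  expect_equal(v[["Tavg"]], 10)
  expect_equal(v[["Pavg"]], 600)
  expect_equal(v[["It"]], 300)
  expect_equal(v[["Io"]], 5)
})
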