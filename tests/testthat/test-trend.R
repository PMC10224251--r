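# Trend estimators against enumeration oracles, selection, projection.

test_that("all five estimators recover an exact line", {
  x <- 0:9; y <- 1 + 2 * x
  for (m in c("ols", "theil_sen", "siegel", "m_estimator",
              "mm_estimator")) {
    f <- trend_fit(x, y, method = m)
    expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-9)
    expect_true(f$converged)
  }
})

test_that("Theil-Sen equals the pairwise-median enumeration oracle", {
  expect_same_coef(coef(trend_fit(0:2, c(1, 3, 5), "theil_sen")), c(1, 2))
  # the declared 4-point outlier case, against full enumeration
  x <- 0:3; y <- c(0, 1, 2, 100)
  o <- oracle_theil_sen(x, y)
  expect_equal(o[2], median(c(1, 1, 100 / 3, 1, 99 / 2, 98)))
  expect_same_coef(coef(trend_fit(x, y, "theil_sen")), o)
  # permutation invariance
  set.seed(8)
  perm <- sample(4)
  expect_same_coef(coef(trend_fit(x[perm], y[perm], "theil_sen")),
                   o, tol = 1e-12)
})

test_that("Siegel equals the repeated-median oracle and has high breakdown", {
  set.seed(9)
  x <- 1:5; y <- c(2, 4, 6, 50, -30)
  expect_same_coef(coef(trend_fit(x, y, "siegel")), oracle_siegel(x, y))
  # corrupting floor((n-1)/2) points of a 21-point exact line changes nothing
  x <- 1:21; y <- 3 + 0.5 * x
  bad <- sample(21, 10)
  y2 <- y; y2[bad] <- y2[bad] + runif(10, 50, 500)
  expect_same_coef(coef(trend_fit(x, y2, "siegel")), c(3, 0.5),
                   tol = 1e-12)
})

test_that("OLS matches the normal equations; M-estimator resists the outlier", {
  x <- 0:3; y <- c(0, 1, 2, 100)
  f <- trend_fit(x, y, "ols")
  expect_equal(f$slope, 150.5 / 5, tolerance = 1e-9)  # Sxy/Sxx by hand
  expect_same_coef(coef(f), oracle_ols(x, y), tol = 1e-9)
  x2 <- 0:9; y2 <- x2; y2[10] <- 100
  m <- trend_fit(x2, y2, "m_estimator")
  o <- trend_fit(x2, y2, "ols")
  expect_lt(abs(m$slope - 1), abs(o$slope - 1))
})

test_that("estimators agree with oracles across random series (n <= 30)", {
  set.seed(10)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    x <- sort(sample(1980:2019, n))
    y <- 0.05 * x + rnorm(n, 0, 3)
    if (i %% 3 == 0) y[sample(n, max(1, n %/% 5))] <- y[1] + 40
    expect_same_coef(coef(trend_fit(x, y, "theil_sen")),
                     oracle_theil_sen(x, y))
    expect_same_coef(coef(trend_fit(x, y, "siegel")),
                     oracle_siegel(x, y))
    expect_same_coef(coef(trend_fit(x, y, "ols")), oracle_ols(x, y),
                     tol = 1e-9)
  }
})

test_that("estimators are shift and scale equivariant", {
  set.seed(11)
  x <- 1990:2014
  y <- 2 + 0.1 * (x - 2000) + rnorm(25, 0, 1)
  for (m in c("ols", "theil_sen", "siegel", "m_estimator",
              "mm_estimator")) {
    f0 <- coef(trend_fit(x, y, m))
    fc <- coef(trend_fit(x, y + 7, m))
    expect_equal(unname(fc), unname(f0 + c(7, 0)), tolerance = 1e-6)
    fk <- coef(trend_fit(x, 3 * y, m))
    expect_equal(unname(fk), unname(3 * f0), tolerance = 1e-6)
  }
})

test_that("MM fit is deterministic under its internal seed", {
  set.seed(12)
  x <- 1980:2019
  y <- 0.02 * x + rnorm(40); y[c(3, 17)] <- y[c(3, 17)] + 30
  f1 <- trend_fit(x, y, "mm_estimator")
  junk <- runif(5)  # disturb the global RNG stream
  f2 <- trend_fit(x, y, "mm_estimator")
  expect_identical(coef(f1), coef(f2))
})

test_that("degenerate inputs error as declared", {
  expect_error(trend_fit(c(2000, 2000, 2000), c(1, 2, 3), "theil_sen"),
               "identical")
  expect_error(trend_fit(1:2, 1:2, "siegel"), "at least 3")
})

test_that("selection minimises the criterion with the declared tie-break", {
  x <- 0:9; y <- 2 + 0.5 * x
  best <- select_best_model(x, y)
  expect_identical(best$model, "ols")  # exact tie broken by model order
  # a contaminated series is won by a robust fit under the mar criterion
  set.seed(13)
  y2 <- 2 + 0.5 * x + rnorm(10, 0, 0.1)
  y2[c(2, 9)] <- y2[c(2, 9)] + 25
  best2 <- select_best_model(x, y2, criterion = "mar")
  expect_true(best2$model != "ols")
  expect_lt(abs(best2$slope - 0.5), abs(trend_fit(x, y2, "ols")$slope - 0.5))
  # under rmse the least-squares fit can never lose
  best3 <- select_best_model(x, y2, criterion = "rmse")
  expect_identical(best3$model, "ols")
  single <- select_best_model(x, y2, methods = "siegel")
  expect_identical(single$model, "siegel")
})

test_that("station-month decomposition yields 12 series per variable", {
  s1 <- toy_station("A", 1981:2020); s2 <- toy_station("B", 1981:2020)
  ser <- build_station_month_series(list(s1, s2), "temperature")
  expect_length(ser, 24L)
  expect_identical(unique(vapply(ser, function(x) length(x$values), 1L)),
                   40L)
  short <- toy_station("C", 2001:2005)
  w <- capture_warnings(build_station_month_series(list(short),
                                                   "temperature"))
  expect_length(w, 12L)
  expect_true(all(grepl("excluded", w)))
})

test_that("projection evaluates selected fits at the target year, floors precipitation", {
  s <- toy_station("A", 1981:2020)
  # temperatures rise 0.1/yr by construction; precipitation is constant
  cl <- project_station(s, target_year = 2050,
                        methods = c("ols", "theil_sen"))
  base <- climatology_of(s)
  expect_equal(cl$t - base$t, rep(0.1 * (2050 - mean(1981:2020)), 12),
               tolerance = 1e-6)
  expect_equal(cl$p, base$p, tolerance = 1e-9)
  # a steep negative precipitation trend cannot project below zero
  s$precip[, 6] <- pmax(100 - 5 * seq_len(40), 0.1)
  cl2 <- project_station(s, target_year = 2050,
                         methods = c("ols", "theil_sen"))
  expect_gte(cl2$p[6], 0)
})

test_that("zero-slope fits reproduce the historical means exactly", {
  s <- toy_station("A", 1981:2020)
  s$temp <- matrix(rep(10 + sin(1:12), each = 40), 40)  # year-constant
  cl <- project_station(s, target_year = 2050)
  expect_equal(cl$t, 10 + sin(1:12), tolerance = 1e-12)
})

test_that("selection frequencies sum to 100 per variable", {
  st <- list(toy_station("A", 1996:2015), toy_station("B", 1996:2015))
  rep_ <- fit_station_trends(st, methods = c("ols", "theil_sen"))
  fr <- model_selection_frequencies(rep_)
  agg <- tapply(fr$percent, fr$variable, sum)
  expect_equal(as.vector(agg), c(100, 100))
})
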