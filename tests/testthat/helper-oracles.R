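# Independent brute-force oracles and fixture builders shared by the
# suite. The oracles deliberately use plain month-by-month loops and
# enumeration, never the package's own vectorised paths.

rand_clim <- function() {
  monthly_climatology(runif(12, -5, 30), runif(12, 0, 300))
}

# Month-by-month accumulation of every index from first principles.
oracle_indices <- function(clim) {
  t <- clim$t; p <- clim$p
  Tp <- 0; Pp <- 0
  for (m in 1:12) if (t[m] > 0) { Tp <- Tp + 10 * t[m]; Pp <- Pp + p[m] }
  Tmax <- t[1]; Tmin <- t[1]
  for (m in 2:12) {
    if (t[m] > Tmax) Tmax <- t[m]
    if (t[m] < Tmin) Tmin <- t[m]
  }
  Ic <- Tmax - Tmin
  It <- 10 * (sum(t) / 12 + 2 * Tmin)
  Io <- if (Tp > 0) 10 * Pp / Tp else NA_real_
  # warmest three consecutive months by exhaustive window search
  best <- -Inf; m0 <- NA
  for (s in 1:12) {
    w <- ((s + 0:2 - 1) %% 12) + 1
    if (sum(t[w]) > best) { best <- sum(t[w]); m0 <- s }
  }
  sq <- ((m0 + 0:2 - 1) %% 12) + 1
  ord <- sq[order(-t[sq], seq_along(sq))]
  ratio <- function(set) {
    st <- sum(t[set]); if (st <= 0) NA_real_ else sum(p[set]) / st
  }
  prev <- ((sq[1] - 2) %% 12) + 1
  list(Tp = Tp, Pp = Pp, Tmax = Tmax, Tmin = Tmin, Ic = Ic, It = It,
       Io = Io, Ios1 = ratio(ord[1]), Ios2 = ratio(ord[1:2]),
       Ios3 = ratio(sq), Ios4 = ratio(c(prev, sq)), summer = sq)
}

# Theil-Sen by explicit double loop over pairs.
oracle_theil_sen <- function(x, y) {
  n <- length(x)
  sl <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (x[j] != x[i]) sl <- c(sl, (y[j] - y[i]) / (x[j] - x[i]))
  b <- median(sl)
  c(median(y - b * x), b)
}

# Siegel repeated medians by explicit nested loops.
oracle_siegel <- function(x, y) {
  n <- length(x)
  med_i <- numeric(n)
  for (i in 1:n) {
    sl <- c()
    for (j in setdiff(1:n, i))
      if (x[j] != x[i]) sl <- c(sl, (y[j] - y[i]) / (x[j] - x[i]))
    med_i[i] <- median(sl)
  }
  b <- median(med_i)
  c(median(y - b * x), b)
}

# OLS through the raw normal equations.
oracle_ols <- function(x, y) {
  n <- length(x)
  b <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  c((sum(y) - b * sum(x)) / n, b)
}

# A complete toy station: deterministic values, optionally with holes.
toy_station <- function(id = "T1", years = 2001:2010, lon = -120,
                        lat = 38, elev = 500) {
  ny <- length(years)
  tm <- outer(seq_len(ny) * 0.1, 10 + sin(2 * pi * (1:12 - 7) / 12) * 8,
              "+")
  pm <- outer(seq_len(ny) * 0, 60 + cos(2 * pi * (1:12 - 1) / 12) * 50,
              "+") + 1
  station_series(id, lon, lat, elev, years, tm, pm)
}

# A tiny scenario for pipeline-level tests.
tiny_cfg <- function(seed = 11, n_stations = 15L, ...) {
  scenario_config(seed = seed, grid = grid_spec(-123, 36, 0.1, 20, 20),
                  n_stations = n_stations, years = 1990:2019, ...)
}

expect_same_coef <- function(a, b, tol = 0) {
  expect_equal(unname(a), unname(b), tolerance = tol)
}
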