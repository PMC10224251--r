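# Robust linear trend models per station-month and projection of monthly
# climate to a target year.

MODEL_ORDER <- c("ols", "theil_sen", "siegel", "m_estimator",
                 "mm_estimator")

#' Fit a linear trend to a yearly series
#'
#' One interface over five estimators of `value = intercept + slope*year`:
#' ordinary least squares; Theil-Sen (median of all pairwise slopes);
#' Siegel repeated medians (median over points of the median pairwise
#' slope through each point); a Huber M-estimator; and a high-breakdown
#' MM-estimator (S-estimate initial scale followed by a bisquare M-step).
#' For Theil-Sen and Siegel the intercept is `median(y - slope*x)`. The
#' M and MM fits fall back to least squares with a warning if they do not
#' converge; when the data lie exactly on a line all estimators return
#' that line.
#'
#' @param x numeric predictor (years).
#' @param y numeric response, same length.
#' @param method one of `"ols"`, `"theil_sen"`, `"siegel"`,
#'   `"m_estimator"`, `"mm_estimator"`.
#' @param huber_k Huber tuning constant in scale units (default 1.345).
#' @param seed integer seed for the MM-estimator's internal subsampling,
#'   making the fit deterministic; the caller's RNG state is preserved.
#' @return object of class `trend_fit` with elements `model, slope,
#'   intercept, n, rmse, mar` (root-mean-square and median absolute
#'   residual), `converged`, and the data.
#' @export
trend_fit <- function(x, y, method = MODEL_ORDER, huber_k = 1.345,
                      seed = 1L) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  nmin <- if (method == "theil_sen") 2L else 3L
  if (n < nmin) stop(method, " needs at least ", nmin, " points")
  if (length(unique(x)) < 2L) stop("all years identical; no trend defined")
  converged <- TRUE
  cf <- switch(method,
    ols = ols_coef(x, y),
    theil_sen = theil_sen_coef(x, y),
    siegel = siegel_coef(x, y),
    m_estimator = ,
    mm_estimator = {
      base <- ols_coef(x, y)
      res0 <- y - base[1L] - base[2L] * x
      if (max(abs(res0)) < 1e-10 * max(1, max(abs(y)))) {
        base  # exact line: every M-estimate coincides with it
      } else {
        fit <- tryCatch(
          if (method == "m_estimator")
            MASS::rlm(y ~ x, psi = MASS::psi.huber, k = huber_k,
                      maxit = 100)
          else
            with_seed(seed, MASS::rlm(y ~ x, method = "MM", maxit = 100)),
          error = function(e) NULL)
        if (is.null(fit) || !fit$converged) {
          warning(method, " did not converge; falling back to least squares")
          converged <- FALSE
          base
        } else unname(stats::coef(fit))
      }
    })
  res <- y - cf[1L] - cf[2L] * x
  structure(list(model = method, slope = cf[2L], intercept = cf[1L],
                 n = n, rmse = sqrt(mean(res^2)),
                 mar = stats::median(abs(res)),
                 converged = converged, x = x, y = y),
            class = "trend_fit")
}

ols_coef <- function(x, y) {
  xm <- mean(x); ym <- mean(y)
  b <- sum((x - xm) * (y - ym)) / sum((x - xm)^2)
  c(ym - b * xm, b)
}

theil_sen_coef <- function(x, y) {
  n <- length(x)
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2L, ]] - x[ij[1L, ]]
  sl <- (y[ij[2L, ]] - y[ij[1L, ]])[dx != 0] / dx[dx != 0]
  b <- stats::median(sl)
  c(stats::median(y - b * x), b)
}

siegel_coef <- function(x, y) {
  n <- length(x)
  med_i <- vapply(seq_len(n), function(i) {
    dx <- x[-i] - x[i]
    stats::median((y[-i] - y[i])[dx != 0] / dx[dx != 0])
  }, numeric(1))
  b <- stats::median(med_i)
  c(stats::median(y - b * x), b)
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  expr
}

#' @export
coef.trend_fit <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' @export
predict.trend_fit <- function(object, newyear = NULL, ...) {
  if (is.null(newyear)) newyear <- object$x
  object$intercept + object$slope * newyear
}

#' @export
residuals.trend_fit <- function(object, ...)
  object$y - predict(object, object$x)

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit:%s> slope %.4g /yr, intercept %.4g (n=%d, rmse %.3g, mar %.3g)%s\n",
              x$model, x$slope, x$intercept, x$n, x$rmse, x$mar,
              if (x$converged) "" else " [fallback]"))
  invisible(x)
}

#' @export
plot.trend_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = "year", ylab = "value",
                 main = paste("trend:", x$model), ...)
  graphics::abline(x$intercept, x$slope, col = "red3", lwd = 2)
  invisible(x)
}

#' Per-month yearly series for each station
#'
#' Decomposes complete stations into one series per station, variable and
#' calendar month (the station-by-12 design of the trend analysis).
#' Series shorter than `min_years` are excluded with a warning.
#'
#' @param stations list of complete [station_series()].
#' @param variable `"temperature"` or `"precipitation"`.
#' @param min_years minimum points per series (default 10).
#' @return list of lists with `station_id, variable, month, years,
#'   values`.
#' @export
build_station_month_series <- function(stations,
                                       variable = c("temperature",
                                                    "precipitation"),
                                       min_years = 10L) {
  variable <- match.arg(variable)
  out <- list()
  for (s in stations) {
    m <- if (variable == "temperature") s$temp else s$precip
    for (j in seq_len(12L)) {
      ok <- !is.na(m[, j])
      if (sum(ok) < min_years) {
        warning(sprintf("%s %s month %d: only %d points; excluded",
                        s$station_id, variable, j, sum(ok)))
        next
      }
      out[[length(out) + 1L]] <- list(
        station_id = s$station_id, variable = variable, month = j,
        years = s$years[ok], values = m[ok, j])
    }
  }
  out
}

#' Select the best trend model for a series
#'
#' Fits the requested estimators and returns the one minimising the
#' selection criterion: median absolute residual (default) or
#' root-mean-square residual. Least squares minimises the in-sample RMSE
#' by construction, so the RMSE criterion can only ever prefer it; the
#' median-absolute-residual default lets robust fits win on contaminated
#' series. Ties (within 1e-12) are broken by the declared model order
#' `ols, theil_sen, siegel, m_estimator, mm_estimator`.
#'
#' @param x,y the series.
#' @param methods candidate estimators (default all five).
#' @param criterion `"mar"` or `"rmse"`.
#' @param ... passed to [trend_fit()].
#' @return the winning `trend_fit`.
#' @export
select_best_model <- function(x, y, methods = MODEL_ORDER,
                              criterion = c("mar", "rmse"), ...) {
  criterion <- match.arg(criterion)
  methods <- intersect(MODEL_ORDER, methods)
  fits <- list()
  for (m in methods) {
    f <- tryCatch(suppressWarnings(trend_fit(x, y, method = m, ...)),
                  error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (length(fits) == 0L) stop("no model could be fitted")
  if (length(fits) == 1L) return(fits[[1L]])
  scores <- vapply(fits, `[[`, numeric(1), criterion)
  best <- which(scores <= min(scores) + 1e-12)[1L]
  fits[[best]]
}

#' Fit and select trend models for every station-month
#'
#' @param stations list of complete [station_series()].
#' @param methods,criterion,... passed to [select_best_model()].
#' @return data.frame report: `station_id, variable, month, model, slope,
#'   intercept, score, n`, plus the fits as attribute `"fits"`.
#' @export
fit_station_trends <- function(stations, methods = MODEL_ORDER,
                               criterion = c("mar", "rmse"), ...) {
  criterion <- match.arg(criterion)
  series <- c(build_station_month_series(stations, "temperature"),
              build_station_month_series(stations, "precipitation"))
  fits <- lapply(series, function(s)
    select_best_model(s$years, s$values, methods, criterion, ...))
  report <- data.frame(
    station_id = vapply(series, `[[`, "", "station_id"),
    variable = vapply(series, `[[`, "", "variable"),
    month = vapply(series, `[[`, 1L, "month"),
    model = vapply(fits, `[[`, "", "model"),
    slope = vapply(fits, `[[`, 1, "slope"),
    intercept = vapply(fits, `[[`, 1, "intercept"),
    score = vapply(fits, `[[`, 1, criterion),
    n = vapply(fits, `[[`, 1L, "n"),
    stringsAsFactors = FALSE)
  attr(report, "fits") <- fits
  attr(report, "criterion") <- criterion
  report
}

#' Model-selection frequency table
#'
#' Percentage of station-month series won by each estimator, by
#' variable — the summary used to compare estimator families over a
#' station network.
#'
#' @param report from [fit_station_trends()].
#' @return data.frame `variable, model, n, percent`.
#' @export
model_selection_frequencies <- function(report) {
  out <- do.call(rbind, lapply(split(report, report$variable), function(d) {
    tab <- table(factor(d$model, levels = MODEL_ORDER))
    data.frame(variable = d$variable[1L], model = names(tab),
               n = as.integer(tab),
               percent = 100 * as.integer(tab) / nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Project a station's monthly climate to a target year
#'
#' Evaluates the selected per-month trend fits at the target year;
#' projected precipitation is floored at 0 mm, temperature is left
#' unclamped. Bioclimatic indices for the target year are then
#' recomputed from this projected climatology with [bioclim_indices()],
#' never by extrapolating indices directly, so inter-index identities
#' are preserved.
#'
#' @param station a complete [station_series()].
#' @param target_year default 2050.
#' @param methods,criterion,... passed to [select_best_model()].
#' @return [monthly_climatology()] at the target year.
#' @export
project_station <- function(station, target_year = 2050,
                            methods = MODEL_ORDER,
                            criterion = c("mar", "rmse"), ...) {
  criterion <- match.arg(criterion)
  proj <- function(m, floor0) {
    vapply(seq_len(12L), function(j) {
      ok <- !is.na(m[, j])
      f <- select_best_model(station$years[ok], m[ok, j], methods,
                             criterion, ...)
      p <- predict(f, target_year)
      if (floor0) max(p, 0) else p
    }, numeric(1))
  }
  monthly_climatology(proj(station$temp, FALSE),
                      proj(station$precip, TRUE),
                      hemisphere = if (station$latitude >= 0) "north"
                                   else "south")
}
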