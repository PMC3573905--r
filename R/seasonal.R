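# Seasonal summaries: within-year seasonal effect curves, peak-to-trough
# incidence rate ratios, calendar timing of peak and trough, trend rates.

.seasonal_coefs <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) < 6L) stop("theta must be the length-6 state vector")
  theta[3:6]
}

# s, s', s'' of the two-harmonic seasonal effect, vectorized over rows of
# A (m x 4 coefficients) against a phase vector d (length m or 1)
.s_eval <- function(A, d, period, deriv = 0L) {
  w <- 2 * pi / period
  w1 <- w * d
  w2 <- 2 * w * d
  switch(as.character(deriv),
    "0" = A[, 1L] * cos(w1) + A[, 2L] * sin(w1) +
          A[, 3L] * cos(w2) + A[, 4L] * sin(w2),
    "1" = w * (-A[, 1L] * sin(w1) + A[, 2L] * cos(w1)) +
          2 * w * (-A[, 3L] * sin(w2) + A[, 4L] * cos(w2)),
    "2" = -w^2 * (A[, 1L] * cos(w1) + A[, 2L] * sin(w1)) -
          4 * w^2 * (A[, 3L] * cos(w2) + A[, 4L] * sin(w2)))
}

# Newton polish of grid extrema of s(d); keeps the grid point when the
# polish does not improve the objective (e.g. near-flat curves)
.polish_extremum <- function(A, d0, period, maximize = TRUE, steps = 8L) {
  sgn <- if (maximize) 1 else -1
  d <- d0
  best <- .s_eval(A, d, period)
  for (k in seq_len(steps)) {
    g <- .s_eval(A, d, period, 1L)
    h <- .s_eval(A, d, period, 2L)
    step <- ifelse(abs(h) > 1e-14, g / h, 0)
    step <- pmin(pmax(step, -period / 50), period / 50)
    d <- d - step
  }
  val <- .s_eval(A, d, period)
  keep <- is.finite(val) & (sgn * val >= sgn * best)
  d <- ifelse(keep, d, d0)
  list(d = d %% period, value = ifelse(keep, val, best))
}

.grid_extrema <- function(A, period, grid_size) {
  if (grid_size < 4L) stop("grid_size must be at least 4")
  grid <- seq(0, period, length.out = grid_size + 1L)[seq_len(grid_size)]
  B <- t(build_design(grid, period)[, 3:6])   # 4 x grid basis
  S <- A %*% B                                # m x grid
  imax <- max.col(S, ties.method = "first")
  imin <- max.col(-S, ties.method = "first")
  pk <- .polish_extremum(A, grid[imax], period, maximize = TRUE)
  tr <- .polish_extremum(A, grid[imin], period, maximize = FALSE)
  list(peak_d = pk$d, peak_s = pk$value, trough_d = tr$d, trough_s = tr$value)
}

#' Within-year seasonal effect curve
#'
#' Evaluates `s(d) = a1 cos(2 pi d / P) + b1 sin(2 pi d / P) +
#' a2 cos(4 pi d / P) + b2 sin(4 pi d / P)` on an equispaced grid over one
#' year, `d` in weeks.
#'
#' @param theta state vector (length 6; the four seasonal coefficients are
#'   positions 3 to 6).
#' @param period weeks per year.
#' @param grid_size number of grid points (>= 4).
#' @return A data frame with columns `d` (weeks into the year) and `s`
#'   (seasonal effect on the log-rate scale).
#' @export
seasonal_curve <- function(theta, period, grid_size = 1000L) {
  if (grid_size < 4L) stop("grid_size must be at least 4")
  a <- .seasonal_coefs(theta)
  d <- seq(0, period, length.out = grid_size + 1L)[seq_len(grid_size)]
  s <- as.numeric(build_design(d, period)[, 3:6] %*% a)
  data.frame(d = d, s = s)
}

#' Peak-to-trough incidence rate ratio
#'
#' `exp(max_d s(d) - min_d s(d))` of the within-year seasonal effect,
#' located by a dense grid search with a Newton polish at the grid extrema.
#' An incidence rate ratio (dimensionless, >= 1) summarizing the intensity
#' of the seasonal variation.
#'
#' @inheritParams seasonal_curve
#' @return Scalar PTT ratio.
#' @export
ptt_ratio <- function(theta, period, grid_size = 1000L) {
  a <- matrix(.seasonal_coefs(theta), nrow = 1L)
  ex <- .grid_extrema(a, period, grid_size)
  exp(ex$peak_s - ex$trough_s)
}

#' Weekly peak-to-trough ratio trajectory
#'
#' Applies [ptt_ratio()] to every smoothed state of a fitted model,
#' vectorized over weeks.
#'
#' @param states an `n x 6` matrix of state vectors (rows), a
#'   [kalman_smoother()] result, or a `dglm_fit`.
#' @inheritParams seasonal_curve
#' @return Numeric vector of weekly PTT ratios.
#' @export
ptt_series <- function(states, period, grid_size = 1000L) {
  A <- .states_matrix(states)[, 3:6, drop = FALSE]
  ex <- .grid_extrema(A, period, grid_size)
  exp(ex$peak_s - ex$trough_s)
}

.states_matrix <- function(states) {
  if (inherits(states, "dglm_fit")) states <- states$smoother
  if (inherits(states, "kf_smoother")) return(t(states$shat))
  as.matrix(states)
}

#' Calendar timing of seasonal peak and trough
#'
#' Day-of-year (1 January = day 0, year length `7 * period` days) of the
#' maximum and minimum of the seasonal effect.  Ties are broken by the
#' earliest day; a flat curve yields `NA` for both.
#'
#' @inheritParams seasonal_curve
#' @param anchor_date optional `Date` giving the calendar date at phase
#'   `d = 0` (the series' first week start); when `NULL`, phase 0 is taken
#'   as 1 January.
#' @return A list with `peak_day` and `trough_day`.
#' @export
peak_trough_times <- function(theta, period, grid_size = 1000L,
                              anchor_date = NULL) {
  a <- matrix(.seasonal_coefs(theta), nrow = 1L)
  ex <- .grid_extrema(a, period, grid_size)
  if (ex$peak_s - ex$trough_s < 1e-12)
    return(list(peak_day = NA_real_, trough_day = NA_real_))
  year_days <- 7 * period
  anchor <- if (is.null(anchor_date)) 0 else as.POSIXlt(anchor_date)$yday
  list(peak_day = (anchor + 7 * ex$peak_d) %% year_days,
       trough_day = (anchor + 7 * ex$trough_d) %% year_days)
}

#' Percent deviation of the seasonal rate factor from its annual median
#'
#' `100 * (exp(s(d)) / median_d exp(s(d)) - 1)` over the within-year grid,
#' the percentual deviation of the seasonal incidence rate factor from the
#' annual median.
#'
#' @inheritParams seasonal_curve
#' @return A data frame with columns `d` and `pct`.
#' @export
percent_deviation <- function(theta, period, grid_size = 1000L) {
  cur <- seasonal_curve(theta, period, grid_size)
  f <- exp(cur$s)
  data.frame(d = cur$d, pct = 100 * (f / stats::median(f) - 1))
}

#' Seasonally adjusted trend incidence rates
#'
#' `rate_t = exp(level_t)` from the smoothed states, with pointwise
#' intervals `exp(level_t +/- 1.96 sd)` from the smoothed level variance.
#' Units follow the offset convention (per 100 person-years).
#'
#' @param smoother a [kalman_smoother()] result over the fitted series (or a
#'   `dglm_fit`).
#' @param series the fitted [weekly_series()].
#' @return A data frame with `week`, `date`, `rate`, `ci_low`, `ci_high`.
#' @export
trend_rates <- function(smoother, series) {
  if (inherits(smoother, "dglm_fit")) smoother <- smoother$smoother
  stopifnot(inherits(smoother, "kf_smoother"), inherits(series, "weekly_series"))
  if (smoother$n != series$n) stop("smoother and series lengths differ")
  level <- smoother$shat[1L, ]
  sdl <- sqrt(pmax(smoother$Shat[1L, 1L, ], 0))
  data.frame(week = seq_len(series$n), date = series$start_dates,
             rate = exp(level),
             ci_low = exp(level - 1.96 * sdl),
             ci_high = exp(level + 1.96 * sdl))
}

#' Weekly seasonal summary table
#'
#' One row per week: the PTT ratio and the day-of-year of the seasonal peak
#' and trough implied by the smoothed state, plus the trend rate and its
#' pointwise interval.
#'
#' @param fit a `dglm_fit` (or a [kalman_smoother()] result).
#' @param series the fitted [weekly_series()]; taken from the fit when
#'   omitted.
#' @inheritParams seasonal_curve
#' @return A tidy data frame, one row per week.
#' @export
seasonal_summary <- function(fit, series = NULL, period = NULL,
                             grid_size = 1000L) {
  if (inherits(fit, "dglm_fit")) {
    if (is.null(series)) series <- fit$series
    if (is.null(period)) period <- fit$spec$period
    smoother <- fit$smoother
  } else {
    smoother <- fit
    if (is.null(series) || is.null(period))
      stop("series and period are required when passing a smoother")
  }
  A <- t(smoother$shat)
  ex <- .grid_extrema(A[, 3:6, drop = FALSE], period, grid_size)
  year_days <- 7 * period
  anchor <- as.POSIXlt(series$start_dates[1L])$yday
  flat <- (ex$peak_s - ex$trough_s) < 1e-12
  tr <- trend_rates(smoother, series)
  data.frame(week = seq_len(series$n), date = series$start_dates,
             ptt = exp(ex$peak_s - ex$trough_s),
             peak_day = ifelse(flat, NA_real_,
                               (anchor + 7 * ex$peak_d) %% year_days),
             trough_day = ifelse(flat, NA_real_,
                                 (anchor + 7 * ex$trough_d) %% year_days),
             rate = tr$rate, ci_low = tr$ci_low, ci_high = tr$ci_high)
}
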