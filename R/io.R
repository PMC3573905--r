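# CSV input/output and event-to-week aggregation.

#' Read a weekly series from CSV
#'
#' Expects a header with columns `date`, `count`, `persontime` (ISO-8601
#' dates, UTF-8, period decimal separator).  Validation errors name the
#' offending row; a missing week names the missing date.
#'
#' @param path CSV file path.
#' @return A [weekly_series()].
#' @export
read_weekly_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "count", "persontime")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")))
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stop(sprintf("unparseable date at row %d: '%s'", bad[1L], df$date[bad[1L]]))
  dd <- diff(as.integer(dates))
  gap <- which(dd != 7L)
  if (length(gap)) {
    i <- gap[1L]
    if (dd[i] > 7L)
      stop(sprintf("week gap after row %d: missing week starting %s",
                   i, format(dates[i] + 7L)))
    stop(sprintf("dates must advance by 7 days; violated at row %d (%s -> %s)",
                 i + 1L, format(dates[i]), format(dates[i + 1L])))
  }
  bad <- which(!is.finite(df$count) | df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop(sprintf("invalid count at row %d: %s", bad[1L], df$count[bad[1L]]))
  bad <- which(!is.finite(df$persontime) | df$persontime <= 0)
  if (length(bad))
    stop(sprintf("invalid persontime at row %d: %s", bad[1L], df$persontime[bad[1L]]))
  weekly_series(dates, df$count, df$persontime)
}

#' Write a weekly series to CSV
#'
#' Canonical dialect: header `date,count,persontime`, ISO-8601 dates,
#' offsets printed with 10 significant digits.  Writing the result of
#' [read_weekly_csv()] on a canonical file reproduces it byte for byte.
#'
#' @param series a [weekly_series()].
#' @param path output file path.
#' @export
write_weekly_csv <- function(series, path) {
  stopifnot(inherits(series, "weekly_series"))
  df <- data.frame(date = format(series$start_dates, "%Y-%m-%d"),
                   count = format(series$counts, trim = TRUE, scientific = FALSE),
                   persontime = sprintf("%.10g", series$offsets))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate daily events and person-time to seven-day bins
#'
#' Counts events per consecutive 7-day bin anchored at `origin_date` and
#' sums the per-day person-time (person-days) per bin, converting it to the
#' per-100-person-year offset convention (`person-days / 36525`).  Trailing
#' days not filling a complete week are dropped.
#'
#' @param event_dates `Date` vector of event dates.
#' @param risk_days numeric vector of person-time at risk (person-days), one
#'   entry per calendar day starting at `origin_date`.
#' @param origin_date `Date`, the first day of the first bin.
#' @return A [weekly_series()].
#' @export
aggregate_events <- function(event_dates, risk_days, origin_date) {
  origin_date <- as.Date(origin_date)
  event_dates <- as.Date(event_dates)
  n_weeks <- length(risk_days) %/% 7L
  if (n_weeks < 2L) stop("risk_days must cover at least two full weeks")
  span_end <- origin_date + 7L * n_weeks
  out <- which(event_dates < origin_date | event_dates >= span_end)
  if (length(out))
    stop(sprintf("event at %s lies outside the risk span [%s, %s)",
                 format(event_dates[out[1L]]), format(origin_date),
                 format(span_end)))
  bin <- as.integer(event_dates - origin_date) %/% 7L
  counts <- tabulate(bin + 1L, nbins = n_weeks)
  week_of_day <- rep(seq_len(n_weeks), each = 7L)
  offsets <- as.numeric(tapply(risk_days[seq_len(7L * n_weeks)], week_of_day, sum)) / 36525
  weekly_series(origin_date + 7L * (seq_len(n_weeks) - 1L), counts, offsets)
}

#' Write a fit result to JSON
#'
#' Emits the estimated hyperparameters, log-likelihood, AIC and run metadata
#' as JSON.
#'
#' @param fit a `dglm_fit`.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "dglm_fit"))
  x <- list(phi_hat = as.numeric(fit$phi_hat),
            loglik = fit$loglik, loglik_se = fit$loglik_se,
            aic = fit$aic, k_params = fit$k_params,
            dynamic_seasonal = fit$dynamic_seasonal,
            n_draws = fit$n_draws, seed = fit$seed,
            em_iterations = if (!is.null(fit$em_trace)) fit$em_trace$iterations else NA,
            em_converged = if (!is.null(fit$em_trace)) fit$em_trace$converged else NA,
            package_version = as.character(utils::packageVersion("dglmseas")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
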