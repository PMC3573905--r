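# Residual analysis on the approximating Gaussian model.

#' Standardized prediction (innovation) residuals
#'
#' Runs the Kalman filter on the converged approximating Gaussian model and
#' returns `e_t / sqrt(q_t)`, the one-step prediction errors standardized by
#' their variance.  Under a correctly specified Gaussian model these are
#' independent standard normal.
#'
#' @param approx a converged `gaussian_approx` (from
#'   [iterated_smoothing()]), or a [gaussian_obs()] directly.
#' @param spec a [dglm_spec()].
#' @param W evolution covariance.
#' @return Numeric vector of standardized innovations (NA for missing
#'   weeks).
#' @export
prediction_residuals <- function(approx, spec, W) {
  obs <- if (inherits(approx, "gaussian_approx")) approx$obs else approx
  flt <- kalman_filter(obs, spec, W)
  flt$e / sqrt(flt$q)
}

#' Standardized smoothed residuals
#'
#' `(ytilde_t - F_t' shat_t) / sqrt(vtilde_t - F_t' Shat_t F_t)`: the
#' pseudo-observation minus its smoothed fit, standardized by the residual
#' variance of the smoothed fit.
#'
#' @inheritParams prediction_residuals
#' @param smoother the matching [kalman_smoother()] result; recomputed when
#'   omitted.
#' @return Numeric vector of standardized smoothed residuals.
#' @export
smoothed_residuals <- function(approx, spec, W, smoother = NULL) {
  obs <- if (inherits(approx, "gaussian_approx")) approx$obs else approx
  if (is.null(smoother))
    smoother <- kalman_smoother(kalman_filter(obs, spec, W))
  Fmat <- .design_matrix(spec, obs$n)
  etahat <- rowSums(Fmat * t(smoother$shat))
  v <- vapply(seq_len(obs$n), function(t)
    obs$vtilde[t] - drop(Fmat[t, ] %*% smoother$Shat[, , t] %*% Fmat[t, ]),
    numeric(1))
  v <- pmax(v, 1e-12 * obs$vtilde)
  (obs$ytilde - etahat) / sqrt(v)
}

#' Sample autocorrelation of a residual sequence
#'
#' @param x residual sequence (NAs dropped).
#' @param max_lag maximum lag, `< length(x)`.
#' @return Numeric vector of autocorrelations at lags `0..max_lag`
#'   (`acf[1] == 1` for lag 0).
#' @export
residual_acf <- function(x, max_lag = 20L) {
  x <- x[!is.na(x)]
  if (max_lag >= length(x)) stop("max_lag must be smaller than the series length")
  if (sd(x) == 0) stop("undefined ACF: residual sequence is constant")
  as.numeric(stats::acf(x, lag.max = max_lag, plot = FALSE,
                        demean = TRUE)$acf)
}

#' Assemble a residual set for a fitted model
#'
#' @param fit a `dglm_fit`, or a `gaussian_approx` with `spec` and `W`
#'   supplied.
#' @param spec,W model pieces, required when `fit` is not a `dglm_fit`.
#' @param max_lag maximum ACF lag.
#' @return An object of class `residual_set` with
#'   `standardized_prediction`, `standardized_smoothed`, `acf` and
#'   `fitted` (the smoothed linear predictor).
#' @export
residual_set <- function(fit, spec = NULL, W = NULL, max_lag = 20L) {
  if (inherits(fit, "dglm_fit")) {
    approx <- fit$approx
    spec <- fit$spec
    W <- build_W(as.numeric(fit$phi_hat))
    smoother <- fit$smoother
  } else {
    approx <- fit
    if (is.null(spec) || is.null(W))
      stop("spec and W are required when fit is not a dglm_fit")
    smoother <- NULL
  }
  pred <- prediction_residuals(approx, spec, W)
  smo <- smoothed_residuals(approx, spec, W, smoother = smoother)
  lags <- min(max_lag, sum(!is.na(pred)) - 1L)
  # a constant residual sequence (e.g. a perfect fit) has no defined ACF
  # beyond lag zero; report that rather than failing the whole summary
  acf_vals <- if (sd(pred, na.rm = TRUE) == 0)
    c(1, rep(NA_real_, lags))
  else residual_acf(pred, max_lag = lags)
  structure(list(standardized_prediction = pred,
                 standardized_smoothed = smo,
                 acf = acf_vals,
                 fitted = approx$eta_hat,
                 n = length(pred)),
            class = "residual_set")
}

#' Summarize residuals for misspecification screening
#'
#' Deterministic summary of a [residual_set()]: moments of the standardized
#' innovations, extreme values, and ACF lags exceeding the approximate 95%
#' white-noise band `1.96 / sqrt(n)`.
#'
#' @param residuals a [residual_set()].
#' @param z_extreme threshold flagging extreme standardized residuals.
#' @return A list of class `residual_report`.
#' @export
residual_report <- function(residuals, z_extreme = 3) {
  stopifnot(inherits(residuals, "residual_set"))
  z <- residuals$standardized_prediction
  z <- z[!is.na(z)]
  n <- length(z)
  lag_acf <- residuals$acf[-1L]
  band <- 1.96 / sqrt(n)
  exceed <- which(!is.na(lag_acf) & abs(lag_acf) > band)
  structure(list(n = n,
                 mean = mean(z),
                 variance = if (n > 1L) var(z) else 0,
                 max_abs = if (n) max(abs(z)) else NA_real_,
                 n_extreme = sum(abs(z) > z_extreme),
                 extreme_weeks = which(abs(residuals$standardized_prediction) > z_extreme),
                 acf_band = band,
                 acf_lags_exceeding = exceed),
            class = "residual_report")
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("residual_report: n = %d, mean %.4f, variance %.4f\n",
              x$n, x$mean, x$variance))
  cat(sprintf("  |z| > threshold at %d weeks; ACF lags outside +/-%.3f: %s\n",
              x$n_extreme, x$acf_band,
              if (length(x$acf_lags_exceeding))
                paste(x$acf_lags_exceeding, collapse = ", ") else "none"))
  invisible(x)
}
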