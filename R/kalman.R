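#' Gaussian pseudo-observations
#'
#' Pairs a pseudo-observation sequence with strictly positive
#' pseudo-variances, the observation side of the approximating Gaussian
#' model.  `ytilde` may contain `NA` for missing weeks (the filter then
#' performs a prediction-only step).
#'
#' @param ytilde numeric vector of pseudo-observations.
#' @param vtilde numeric vector of pseudo-variances (> 0, finite).
#' @return An object of class `gaussian_obs`.
#' @export
gaussian_obs <- function(ytilde, vtilde) {
  if (length(ytilde) != length(vtilde))
    stop("ytilde and vtilde must have equal length")
  if (any(!is.finite(vtilde)) || any(vtilde <= 0))
    stop("vtilde must be strictly positive and finite")
  if (any(!is.finite(ytilde) & !is.na(ytilde)))
    stop("ytilde must be finite or NA")
  structure(list(ytilde = as.numeric(ytilde), vtilde = as.numeric(vtilde),
                 n = length(ytilde)),
            class = "gaussian_obs")
}

.design_matrix <- function(spec, n) {
  Fmat <- spec$design(seq_len(n) - 1)
  if (!is.matrix(Fmat) || nrow(Fmat) != n || ncol(Fmat) != spec$state_dim)
    stop("design function must return an n x state_dim matrix")
  Fmat
}

#' Kalman filter for the approximating Gaussian model
#'
#' Standard predict/update recursions with univariate observations:
#' `a_t = G m_{t-1}`, `R_t = G C_{t-1} G' + W`, update through the design row
#' `F_t` with observation variance `vtilde_t`.  Missing observations are
#' skipped (prediction only).  The returned `loglik` is the prediction-error
#' decomposition of the Gaussian log density of `ytilde`.
#'
#' @param obs a [gaussian_obs()].
#' @param spec a [dglm_spec()].
#' @param W evolution covariance matrix (PSD).
#' @return An object of class `kf_filter` with predicted moments (`a`, `R`),
#'   filtered moments (`m`, `C`), innovations `e`, innovation variances `q`,
#'   `loglik`, and the model matrices used.
#' @export
kalman_filter <- function(obs, spec, W) {
  stopifnot(inherits(obs, "gaussian_obs"), inherits(spec, "dglm_spec"))
  W <- .as_W(W, spec)
  Fmat <- .design_matrix(spec, obs$n)
  out <- cpp_kf(obs$ytilde, obs$vtilde, Fmat, spec$G, W, spec$m0, spec$C0,
                smooth = FALSE)
  structure(list(a = out$a, R = out$R, m = out$m, C = out$C,
                 e = as.numeric(out$e), q = as.numeric(out$q),
                 loglik = out$loglik,
                 obs = obs, spec = spec, W = W, Fmat = Fmat),
            class = "kf_filter")
}

#' Kalman (RTS) smoother with lag-one covariances
#'
#' Backward recursion conditioning every state on the full series, including
#' the smoothed moments of the time-zero state and the lag-one smoothed
#' cross-covariances `Cov(theta_t, theta_{t-1} | data)` needed by the EM
#' M-step.  At the final time point the smoothed moments equal the filtered
#' moments.
#'
#' @param filter a [kalman_filter()] result.
#' @return An object of class `kf_smoother` with `shat` (`d x n` smoothed
#'   means for t = 1..n), `Shat` (`d x d x n`), `lag1` (`d x d x n`, slice t
#'   = `Cov(theta_t, theta_{t-1})`), and `s0`/`S0` for time zero.
#' @export
kalman_smoother <- function(filter) {
  stopifnot(inherits(filter, "kf_filter"))
  obs <- filter$obs
  spec <- filter$spec
  out <- cpp_kf(obs$ytilde, obs$vtilde, filter$Fmat, spec$G, filter$W,
                spec$m0, spec$C0, smooth = TRUE)
  n <- obs$n
  structure(list(shat = out$shat[, -1L, drop = FALSE],
                 Shat = out$Shat[, , -1L, drop = FALSE],
                 lag1 = out$lag1,
                 s0 = as.numeric(out$shat[, 1L]),
                 S0 = out$Shat[, , 1L],
                 n = n),
            class = "kf_smoother")
}

#' Gaussian log-likelihood of the approximating model
#'
#' `sum_t log N(ytilde_t; F_t' a_t, F_t' R_t F_t + vtilde_t)` via the
#' prediction-error decomposition.
#'
#' @inheritParams kalman_filter
#' @return Scalar log-likelihood.
#' @export
gaussian_loglik <- function(obs, spec, W) {
  kalman_filter(obs, spec, W)$loglik
}
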