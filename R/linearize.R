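#' Linearize the Poisson observation model
#'
#' Second-order Taylor match of the Poisson log-likelihood in the linear
#' predictor at a trial value `eta`: with `mu_t = offset_t * exp(eta_t)`, the
#' pseudo-observation is `ytilde_t = eta_t + (y_t - mu_t) / mu_t` and the
#' pseudo-variance `vtilde_t = 1 / mu_t`.  The resulting Gaussian model has
#' the same score and curvature in `eta` as the Poisson model.
#'
#' @param series a [weekly_series()].
#' @param eta trial linear predictor, length `n`, finite.
#' @return A [gaussian_obs()].
#' @export
linearize <- function(series, eta) {
  stopifnot(inherits(series, "weekly_series"))
  if (length(eta) != series$n || anyNA(eta) || any(!is.finite(eta)))
    stop("eta must be finite with one value per week")
  mu <- series$offsets * exp(eta)
  bad <- which(!is.finite(mu) | mu <= 0)
  if (length(bad))
    stop(sprintf("numerical range error: offset * exp(eta) overflows or vanishes at t = %d", bad[1L]))
  gaussian_obs(ytilde = eta + (series$counts - mu) / mu, vtilde = 1 / mu)
}

#' Iterated extended Kalman smoothing
#'
#' Finds the posterior mode of the latent states under the Poisson
#' observation model by repeatedly linearizing around the current smoothed
#' linear predictor and re-running the Kalman filter and smoother, until the
#' sup-norm change in `eta` falls below `tol`.  At convergence the
#' approximating Gaussian model shares the mode and curvature at the mode
#' with the Poisson model.
#'
#' @param series a [weekly_series()].
#' @param spec a [dglm_spec()].
#' @param W evolution covariance (matrix, or length-8 phi vector).
#' @param tol convergence tolerance on `max_t |delta eta_t|`.
#' @param max_iter maximum number of linearization sweeps.
#' @param eta0 optional starting trial value; default
#'   `log((y + 0.5) / offset)`, finite for zero counts.
#' @return A list with components `approx` (class `gaussian_approx`:
#'   `obs`, `eta_hat`, `iterations`, `converged`) and `smoother`
#'   (a [kalman_smoother()] result at the mode).  Non-convergence is
#'   reported via `converged = FALSE`, not an error.
#' @export
iterated_smoothing <- function(series, spec, W, tol = 1e-8, max_iter = 50L,
                               eta0 = NULL) {
  stopifnot(inherits(series, "weekly_series"), inherits(spec, "dglm_spec"))
  if (!is.finite(tol) || tol <= 0) stop("tol must be positive")
  W <- .as_W(W, spec)
  n <- series$n
  eta <- if (is.null(eta0)) log((series$counts + 0.5) / series$offsets) else as.numeric(eta0)
  if (length(eta) != n || any(!is.finite(eta)))
    stop("eta0 must be finite with one value per week")

  converged <- FALSE
  obs <- NULL
  sm <- NULL
  iter <- 0L
  delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    obs <- linearize(series, eta)
    flt <- kalman_filter(obs, spec, W)
    sm <- kalman_smoother(flt)
    eta_new <- rowSums(flt$Fmat * t(sm$shat))
    delta <- max(abs(eta_new - eta))
    eta <- eta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  # re-linearize at the converged mode so obs, smoother and eta_hat agree
  obs <- linearize(series, eta)
  sm <- kalman_smoother(kalman_filter(obs, spec, W))
  approx <- structure(list(obs = obs, eta_hat = eta, iterations = iter,
                           converged = converged, last_delta = delta),
                      class = "gaussian_approx")
  list(approx = approx, smoother = sm)
}
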