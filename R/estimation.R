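# Hyperparameter estimation: EM on the structured evolution covariance,
# importance-sampling evaluation of the exact log-likelihood, and numerical
# refinement of the maximum.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# E-step: unconstrained M-step moment matrix Vhat and the approximating
# Gaussian log-likelihood under W, either for supplied Gaussian
# pseudo-observations or via the fused Poisson mode iteration in C++.
.em_estep <- function(series, spec, W, gaussian_obs = NULL, eta0 = NULL,
                      tol = 1e-8, max_iter = 50L) {
  if (!is.null(gaussian_obs)) {
    flt <- kalman_filter(gaussian_obs, spec, W)
    sm <- kalman_smoother(flt)
    arr <- .smoother_full_arrays(sm)
    list(vhat = cpp_em_vhat(arr$s, arr$S, sm$lag1, spec$G),
         loglik = flt$loglik, eta = NULL, converged = TRUE)
  } else {
    Fmat <- .design_matrix(spec, series$n)
    eta <- if (is.null(eta0)) log((series$counts + 0.5) / series$offsets) else eta0
    res <- cpp_mode_em(series$counts, series$offsets, Fmat, spec$G, W,
                       spec$m0, spec$C0, eta, tol, max_iter, TRUE)
    list(vhat = res$vhat, loglik = res$loglik, eta = as.numeric(res$eta),
         converged = res$converged)
  }
}

# preallocation-friendly EM core used by run_em (Poisson path)
.run_em_poisson <- function(series, spec, phi0, loglik_tol, max_iter,
                            dynamic_seasonal, verbose) {
  Fmat <- .design_matrix(spec, series$n)
  phi <- hyperparams(as.numeric(phi0))
  phi_path <- matrix(NA_real_, max_iter + 1L, 8L,
                     dimnames = list(NULL, .phi_names))
  phi_path[1L, ] <- unclass(phi)
  loglik_path <- rep(NA_real_, max_iter)
  eta <- log((series$counts + 0.5) / series$offsets)
  converged <- FALSE
  iter <- 0L
  mode_warn <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- .as_W(build_W(as.numeric(phi)), spec)
    res <- cpp_mode_em(series$counts, series$offsets, Fmat, spec$G, W,
                       spec$m0, spec$C0, eta, 1e-8, 50L, TRUE)
    if (!res$converged) mode_warn <- TRUE
    eta <- as.numeric(res$eta)
    phi <- .em_mstep(res$vhat, dynamic_seasonal = dynamic_seasonal)
    loglik_path[iter] <- res$loglik
    phi_path[iter + 1L, ] <- unclass(phi)
    if (verbose && iter %% 50L == 0L)
      message(sprintf("EM iteration %d: approximating loglik %.4f",
                      iter, res$loglik))
    if (iter >= 2L &&
        abs(loglik_path[iter] - loglik_path[iter - 1L]) < loglik_tol) {
      converged <- TRUE
      break
    }
  }
  if (mode_warn)
    warning("mode iteration hit its iteration cap during at least one EM step")
  structure(list(phi = phi,
                 phi_path = phi_path[seq_len(iter + 1L), , drop = FALSE],
                 loglik_path = loglik_path[seq_len(iter)],
                 iterations = iter, converged = converged,
                 dynamic_seasonal = dynamic_seasonal),
            class = "em_trace")
}

.smoother_full_arrays <- function(sm) {
  d <- nrow(sm$shat)
  n <- sm$n
  sfull <- cbind(sm$s0, sm$shat, deparse.level = 0)
  Sfull <- array(0, dim = c(d, d, n + 1L))
  Sfull[, , 1L] <- sm$S0
  Sfull[, , -1L] <- sm$Shat
  list(s = sfull, S = Sfull)
}

# M-step: unconstrained update projected onto the tied-entry structure.
# The pattern is the fixed-point subalgebra of the pair-swap / seasonal
# sign-flip symmetries and is closed under inversion, so entry averaging is
# the exact constrained maximizer of the complete-data likelihood.
.em_mstep <- function(Vhat, dynamic_seasonal = TRUE) {
  phi <- unclass(phi_from_W(Vhat))
  phi[c(1L, 2L, 4L, 5L)] <- pmax(phi[c(1L, 2L, 4L, 5L)], 0)
  if (!dynamic_seasonal) phi[4L:8L] <- 0
  # covariance shrinkage fallback; unreachable in regular cases since the
  # projection of a PSD moment matrix stays PSD
  tries <- 0L
  while (!validate_psd(build_W(phi), tol = 1e-10) && tries < 200L) {
    phi[c(3L, 6L, 7L, 8L)] <- 0.9 * phi[c(3L, 6L, 7L, 8L)]
    tries <- tries + 1L
  }
  if (tries > 0L)
    warning(sprintf("M-step update shrunk covariances %d times to restore PSD", tries))
  hyperparams(phi)
}

#' One EM step for the evolution covariance hyperparameters
#'
#' E-step: iterated extended Kalman smoothing under `W(phi)` (or a plain
#' Kalman smooth when Gaussian pseudo-observations are supplied directly),
#' giving smoothed means, covariances and lag-one cross-covariances.
#' M-step: the unconstrained update
#' `Vhat = (1/n) sum_t E[(theta_t - G theta_{t-1})(theta_t - G theta_{t-1})' | data]`
#' projected onto the tied-entry structure by averaging (variance pairs,
#' within-pair covariances, the four cross-pair covariances).
#'
#' @param series a [weekly_series()].
#' @param spec a [dglm_spec()] with the standard six-dimensional state.
#' @param phi current hyperparameters (length 8).
#' @param gaussian_obs optional [gaussian_obs()]; when supplied the
#'   observation model is taken as Gaussian with these moments and no
#'   linearization is performed (used for exact-EM fixtures).
#' @param dynamic_seasonal if `FALSE`, the seasonal block is pinned to zero
#'   (static seasonal variation) and only the trend block is updated.
#' @return Updated `hyperparams`, with the approximating-model log-likelihood
#'   at the *input* `phi` attached as attribute `"loglik"`.
#' @export
em_step <- function(series, spec, phi, gaussian_obs = NULL,
                    dynamic_seasonal = TRUE) {
  W <- .as_W(build_W(as.numeric(phi)), spec)
  es <- .em_estep(series, spec, W, gaussian_obs = gaussian_obs)
  out <- .em_mstep(es$vhat, dynamic_seasonal = dynamic_seasonal)
  attr(out, "loglik") <- es$loglik
  out
}

#' Run the EM algorithm
#'
#' Iterates [em_step()] until the change in the approximating-model
#' log-likelihood between two steps is smaller than `loglik_tol` or
#' `max_iter` is reached.  The mode iteration is warm-started from the
#' previous EM iteration's linear predictor.
#'
#' @inheritParams em_step
#' @param phi0 starting hyperparameters; see [default_phi0()].
#' @param loglik_tol stopping threshold on the log-likelihood difference.
#' @param max_iter maximum number of EM iterations; `0` returns `phi0`
#'   unchanged with `converged = FALSE`.
#' @param verbose print the log-likelihood trace.
#' @return An object of class `em_trace`: `phi` (final), `phi_path`
#'   (one row per iterate, including `phi0`), `loglik_path`, `iterations`,
#'   `converged`.
#' @export
run_em <- function(series, spec, phi0, loglik_tol = 0.1, max_iter = 1000L,
                   gaussian_obs = NULL, dynamic_seasonal = TRUE,
                   verbose = FALSE) {
  if (is.null(gaussian_obs) && max_iter > 0L)
    return(.run_em_poisson(series, spec, phi0, loglik_tol, max_iter,
                           dynamic_seasonal, verbose))
  phi <- hyperparams(as.numeric(phi0))
  phi_path <- matrix(unclass(phi), nrow = 1L,
                     dimnames = list(NULL, .phi_names))
  loglik_path <- numeric(0)
  converged <- FALSE
  eta <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    W <- .as_W(build_W(as.numeric(phi)), spec)
    es <- .em_estep(series, spec, W, gaussian_obs = gaussian_obs, eta0 = eta)
    if (!es$converged)
      warning(sprintf("mode iteration did not converge at EM iteration %d", iter))
    eta <- es$eta
    phi <- .em_mstep(es$vhat, dynamic_seasonal = dynamic_seasonal)
    loglik_path <- c(loglik_path, es$loglik)
    phi_path <- rbind(phi_path, unclass(phi))
    if (verbose)
      message(sprintf("EM iteration %d: approximating loglik %.4f", iter, es$loglik))
    if (iter >= 2L &&
        abs(loglik_path[iter] - loglik_path[iter - 1L]) < loglik_tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(phi = phi, phi_path = phi_path, loglik_path = loglik_path,
                 iterations = iter, converged = converged,
                 dynamic_seasonal = dynamic_seasonal),
            class = "em_trace")
}

#' @export
print.em_trace <- function(x, ...) {
  cat(sprintf("em_trace: %d iterations, converged = %s\n", x$iterations,
              x$converged))
  if (length(x$loglik_path))
    cat(sprintf("  approximating loglik: %.4f -> %.4f\n",
                x$loglik_path[1L], x$loglik_path[length(x$loglik_path)]))
  invisible(x)
}

#' Importance-sampling log-likelihood
#'
#' Evaluates the exact marginal log-likelihood of the Poisson model as
#' `log L = log L_g + log((1/N) sum_i w_i)`, where `L_g` is the Gaussian
#' likelihood of the pseudo-observations of the mode-matched approximating
#' model, the draws come from its smoothing density via the mean-correction
#' simulation smoother, and `w_i` is the Poisson-to-Gaussian observation
#' density ratio along each draw.  Antithetic location pairs halve the number
#' of simulation-smoother passes and balance the draws around the mode.
#'
#' @param series a [weekly_series()].
#' @param spec a [dglm_spec()].
#' @param phi hyperparameters (length-8 vector) or a full evolution
#'   covariance matrix matching the spec (for reduced toy models).
#' @param n_draws total number of importance draws.
#' @param seed integer seed; fixed seed gives bit-identical results.
#' @param antithetic use location-balanced antithetic pairs.
#' @param tol,max_iter passed to [iterated_smoothing()].
#' @return A list with `loglik`, its delta-method standard error `se`
#'   (computed on antithetic pair means when pairing is on), `n_draws`, and
#'   `gaussian_loglik`.
#' @export
is_loglik <- function(series, spec, phi, n_draws = 1000L, seed = 1L,
                      antithetic = TRUE, tol = 1e-8, max_iter = 50L,
                      eta0 = NULL) {
  stopifnot(n_draws >= 1L)
  W <- .as_W(phi, spec)
  Fmat <- .design_matrix(spec, series$n)
  if (is.null(eta0)) eta0 <- log((series$counts + 0.5) / series$offsets)
  mode <- cpp_mode_em(series$counts, series$offsets, Fmat, spec$G, W,
                      spec$m0, spec$C0, eta0, tol, max_iter, FALSE)
  obs <- linearize(series, as.numeric(mode$eta))
  lg <- gaussian_loglik(obs, spec, W)
  M <- if (antithetic) as.integer(ceiling(n_draws / 2)) else as.integer(n_draws)
  res <- .with_seed(seed,
    cpp_is_weights(series$counts, series$offsets, obs$ytilde, obs$vtilde,
                   Fmat, spec$G, W, spec$m0, spec$C0,
                   .mat_sqrt(W), .mat_sqrt(spec$C0), M, antithetic))
  logw <- as.numeric(res$logw)
  a <- max(logw)
  wi <- exp(logw - a)
  lhat <- a + log(mean(wi))
  wp <- if (antithetic) (wi[seq_len(M)] + wi[M + seq_len(M)]) / 2 else wi
  se <- if (length(wp) > 1L) sd(wp) / (mean(wp) * sqrt(length(wp))) else NA_real_
  list(loglik = lg + lhat, se = se, n_draws = length(logw),
       gaussian_loglik = lg, eta_hat = as.numeric(mode$eta))
}

#' Akaike's information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of estimated parameters.
#' @return `-2 * loglik + 2 * k_params`.
#' @export
compute_aic <- function(loglik, k_params) {
  if (k_params < 0) stop("k_params must be non-negative")
  -2 * loglik + 2 * k_params
}

# transform between phi and the optimizer scale: variances on the log
# scale (they range over orders of magnitude), covariances as correlations
# relative to the variances they couple
.phi_to_par <- function(phi, free_cor) {
  v <- pmax(phi[c(1L, 2L, 4L, 5L)], 1e-16)
  r <- c(phi[3L] / sqrt(v[1L] * v[2L]),
         phi[6L] / v[3L],
         phi[7L] / v[4L],
         phi[8L] / sqrt(v[3L] * v[4L]))
  r <- pmin(pmax(r, -0.99), 0.99)
  if (free_cor) c(log(v), r) else c(log(v[1:2]), r[1L])
}

.par_to_phi <- function(p, free_cor) {
  if (free_cor) {
    v <- exp(p[1:4])
    c(v[1L], v[2L], p[5L] * sqrt(v[1L] * v[2L]),
      v[3L], v[4L], p[6L] * v[3L], p[7L] * v[4L],
      p[8L] * sqrt(v[3L] * v[4L]))
  } else {
    v <- exp(p[1:2])
    c(v[1L], v[2L], p[3L] * sqrt(v[1L] * v[2L]), rep(0, 5))
  }
}

#' Refine hyperparameters by maximizing the importance-sampling likelihood
#'
#' Nelder--Mead maximization of [is_loglik()] over the free hyperparameters
#' (all eight, or the three trend parameters when the seasonal block is
#' static), with common random numbers: every evaluation reuses the same
#' seed, so the Monte Carlo objective is a smooth deterministic surface.
#' The search runs on a transformed scale -- log variances (EM often lands
#' orders of magnitude away for weakly identified variance components) and
#' correlation-scaled covariances -- and proposals whose `W` is not PSD are
#' rejected through a large finite penalty.
#'
#' @inheritParams is_loglik
#' @param phi_start starting hyperparameters, typically the EM estimate.
#' @param dynamic_seasonal if `FALSE`, the seasonal block is fixed at zero.
#' @param maxit maximum number of Nelder--Mead iterations.
#' @return An object of class `dglm_fit`; see [fit_dglm()].
#' @export
optimize_loglik <- function(series, spec, phi_start, n_draws = 1000L,
                            seed = 1L, dynamic_seasonal = TRUE,
                            maxit = 200L, antithetic = TRUE) {
  phi_start <- hyperparams(as.numeric(phi_start))
  p0 <- .phi_to_par(unclass(phi_start), dynamic_seasonal)

  # the posterior mode moves little between optimizer proposals: warm-start
  # the inner linearization loop from the previous evaluation's mode
  eta_warm <- NULL
  objective <- function(p) {
    if (any(!is.finite(p)) || any(abs(p) > 60)) return(1e10)
    phi <- .par_to_phi(p, dynamic_seasonal)
    W <- build_W(phi)
    if (!validate_psd(W, tol = 1e-10)) return(1e10)
    r <- is_loglik(series, spec, W, n_draws = n_draws, seed = seed,
                   antithetic = antithetic, eta0 = eta_warm)
    eta_warm <<- r$eta_hat
    -r$loglik
  }
  opt <- optim(p0, objective, method = "Nelder-Mead",
               control = list(maxit = maxit))
  if (opt$convergence != 0L)
    warning("optimizer did not report convergence; returning the best iterate")
  phi_hat <- hyperparams(.par_to_phi(opt$par, dynamic_seasonal))
  .assemble_fit(series, spec, phi_hat, dynamic_seasonal, n_draws, seed,
                antithetic, optim_convergence = opt$convergence,
                optim_evals = opt$counts[[1L]])
}

.assemble_fit <- function(series, spec, phi_hat, dynamic_seasonal, n_draws,
                          seed, antithetic, em_trace = NULL,
                          optim_convergence = NA_integer_,
                          optim_evals = NA_integer_) {
  W <- .as_W(build_W(as.numeric(phi_hat)), spec)
  mode_fit <- iterated_smoothing(series, spec, W)
  ll <- is_loglik(series, spec, W, n_draws = n_draws, seed = seed,
                  antithetic = antithetic)
  k <- (if (dynamic_seasonal) 8L else 3L) + spec$state_dim
  structure(list(phi_hat = phi_hat,
                 loglik = ll$loglik, loglik_se = ll$se,
                 aic = compute_aic(ll$loglik, k), k_params = k,
                 smoother = mode_fit$smoother, approx = mode_fit$approx,
                 series = series, spec = spec,
                 dynamic_seasonal = dynamic_seasonal,
                 n_draws = n_draws, seed = seed,
                 em_trace = em_trace,
                 optim_convergence = optim_convergence,
                 optim_evals = optim_evals),
            class = "dglm_fit")
}

#' Default EM starting value for the hyperparameters
#'
#' `1e-4 * (10, 0.01, 0.001, 3, 3, 1, 1, 1)`, with the seasonal entries
#' zeroed for the static-seasonality model.
#'
#' @param dynamic_seasonal static or dynamic seasonal block.
#' @return A `hyperparams` vector.
#' @export
default_phi0 <- function(dynamic_seasonal = TRUE) {
  phi <- 1e-4 * c(10, 0.01, 0.001, 3, 3, 1, 1, 1)
  if (!dynamic_seasonal) phi[4:8] <- 0
  hyperparams(phi)
}

#' Fit the seasonal DGLM
#'
#' Two-stage estimation: EM from `phi0` until the likelihood difference
#' criterion is met, then (optionally) Nelder--Mead refinement of the
#' importance-sampling log-likelihood.  The AIC uses
#' `k = free hyperparameters + state dimension` (14 dynamic, 9 static).
#'
#' @inheritParams run_em
#' @inheritParams optimize_loglik
#' @param refine run the numerical refinement stage after EM.
#' @param em_tol,em_max_iter EM stopping rule (log-likelihood difference
#'   threshold and iteration cap).
#' @param optim_maxit Nelder--Mead iteration cap for the refinement stage.
#' @return An object of class `dglm_fit` with the estimated `phi_hat`,
#'   importance-sampling `loglik` (and `loglik_se`), `aic`, the smoothed
#'   states at the estimate, the converged Gaussian approximation, and the
#'   EM trace.
#' @export
fit_dglm <- function(series, spec = dglm_spec(),
                     phi0 = default_phi0(dynamic_seasonal),
                     dynamic_seasonal = TRUE,
                     em_tol = 0.1, em_max_iter = 1000L,
                     refine = TRUE, n_draws = 1000L, seed = 1L,
                     optim_maxit = 100L, antithetic = TRUE,
                     verbose = FALSE) {
  trace <- run_em(series, spec, phi0, loglik_tol = em_tol,
                  max_iter = em_max_iter,
                  dynamic_seasonal = dynamic_seasonal, verbose = verbose)
  if (refine) {
    fit <- optimize_loglik(series, spec, trace$phi, n_draws = n_draws,
                           seed = seed, dynamic_seasonal = dynamic_seasonal,
                           maxit = optim_maxit, antithetic = antithetic)
    fit$em_trace <- trace
    fit
  } else {
    .assemble_fit(series, spec, trace$phi, dynamic_seasonal, n_draws, seed,
                  antithetic, em_trace = trace)
  }
}

#' @export
print.dglm_fit <- function(x, ...) {
  cat(sprintf("dglm_fit (%s seasonal variation)\n",
              if (x$dynamic_seasonal) "dynamic" else "static"))
  cat("  phi_hat: ", paste(sprintf("%.3g", as.numeric(x$phi_hat)),
                           collapse = " "), "\n")
  cat(sprintf("  loglik: %.2f (IS se %.3g, %d draws), AIC: %.1f (k = %d)\n",
              x$loglik, x$loglik_se, x$n_draws, x$aic, x$k_params))
  if (!is.null(x$em_trace))
    cat(sprintf("  EM: %d iterations, converged = %s\n",
                x$em_trace$iterations, x$em_trace$converged))
  invisible(x)
}
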