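# Independent oracles used to derive expected values: direct joint-Gaussian
# conditioning for the Kalman recursions, dense product quadrature for the
# marginal Poisson likelihood of a tiny local-level model, and finite
# differences for posterior-mode gradients.  These deliberately avoid the
# package's recursive implementations.

# Joint multivariate-normal conditioning for the linear Gaussian model:
# builds the exact joint distribution of (theta_1..theta_n, ytilde_1..n)
# and conditions directly.
joint_gaussian_oracle <- function(Fmat, G, W, m0, C0, vtilde, ytilde) {
  n <- nrow(Fmat)
  d <- length(m0)
  Gp <- vector("list", n + 1L)  # powers of G
  Gp[[1L]] <- diag(d)
  for (k in seq_len(n)) Gp[[k + 1L]] <- G %*% Gp[[k]]

  mu <- matrix(0, d, n)
  P <- vector("list", n)        # marginal Var(theta_t)
  Pprev <- C0
  for (t in seq_len(n)) {
    mu[, t] <- Gp[[t + 1L]] %*% m0
    Pprev <- G %*% Pprev %*% t(G) + W
    P[[t]] <- Pprev
  }
  Sig <- matrix(0, n * d, n * d)
  idx <- function(t) ((t - 1L) * d + 1L):(t * d)
  for (t in seq_len(n)) for (s in seq_len(t)) {
    blk <- if (t == s) P[[s]] else Gp[[t - s + 1L]] %*% P[[s]]
    Sig[idx(t), idx(s)] <- blk
    Sig[idx(s), idx(t)] <- t(blk)
  }
  H <- matrix(0, n, n * d)
  for (t in seq_len(n)) H[t, idx(t)] <- Fmat[t, ]
  muy <- as.numeric(H %*% as.numeric(mu))
  Sy <- H %*% Sig %*% t(H) + diag(vtilde, n)
  Sxy <- Sig %*% t(H)

  cond <- function(obs_idx) {
    A <- Sy[obs_idx, obs_idx, drop = FALSE]
    B <- Sxy[, obs_idx, drop = FALSE]
    K <- B %*% solve(A)
    list(mean = as.numeric(mu) + as.numeric(K %*% (ytilde[obs_idx] - muy[obs_idx])),
         cov = Sig - K %*% t(B))
  }
  sm <- cond(seq_len(n))
  filt_mean <- matrix(0, d, n)
  filt_cov <- vector("list", n)
  for (t in seq_len(n)) {
    ct <- cond(seq_len(t))
    filt_mean[, t] <- ct$mean[idx(t)]
    filt_cov[[t]] <- ct$cov[idx(t), idx(t)]
  }
  R <- chol(Sy)
  z <- backsolve(R, ytilde - muy, transpose = TRUE)
  ll <- -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))

  list(smooth_mean = matrix(sm$mean, d, n),
       smooth_cov = lapply(seq_len(n), function(t) sm$cov[idx(t), idx(t)]),
       lag1 = lapply(2:n, function(t) sm$cov[idx(t), idx(t - 1L)]),
       filt_mean = filt_mean, filt_cov = filt_cov, loglik = ll)
}

# a reproducible random PSD matrix with the magnitude of a weekly evolution
# covariance
random_psd <- function(d, scale = 0.05) {
  A <- matrix(rnorm(d * d), d, d)
  scale * crossprod(A) / d
}

# Exact marginal log-likelihood of a scalar local-level Poisson model with
# n = 3 by dense product (trapezoid) quadrature over the 3-d latent state.
poisson_loglik_quadrature <- function(y, offs, m0, C0, W, ngrid = 1201L,
                                      half_width = 9) {
  stopifnot(length(y) == 3L)
  sdm <- sqrt(C0 + 3 * W) + 1
  centers <- log((y + 0.5) / offs)
  lo <- min(centers, m0) - half_width * sdm
  hi <- max(centers, m0) + half_width * sdm
  g <- seq(lo, hi, length.out = ngrid)
  h <- g[2L] - g[1L]
  wts <- rep(h, ngrid); wts[c(1L, ngrid)] <- h / 2
  pobs <- function(t, th) dpois(y[t], offs[t] * exp(th))
  sw <- sqrt(W)
  # integrate theta3 | theta2, then theta2 | theta1, then theta1
  g3 <- as.numeric((pobs(3L, g) * wts) %*% outer(g, g, function(a, b) dnorm(a - b, 0, sw)))
  g2 <- as.numeric((pobs(2L, g) * g3 * wts) %*% outer(g, g, function(a, b) dnorm(a - b, 0, sw)))
  lik <- sum(wts * dnorm(g, m0, sqrt(C0 + W)) * pobs(1L, g) * g2)
  log(lik)
}

# Joint log density of (theta_{1:n}, y) for the Poisson DGLM, as a function
# of the stacked state path (theta_0 marginalized analytically).
joint_logpost <- function(theta_vec, series, spec, W) {
  d <- spec$state_dim
  n <- series$n
  Th <- matrix(theta_vec, d, n)
  G <- spec$G
  Fmat <- spec$design(seq_len(n) - 1)
  P1 <- G %*% spec$C0 %*% t(G) + W
  lp <- mvn_logd(Th[, 1L], as.numeric(G %*% spec$m0), P1)
  for (t in 2:n)
    lp <- lp + mvn_logd(Th[, t], as.numeric(G %*% Th[, t - 1L]), W)
  eta <- rowSums(Fmat * t(Th))
  mu <- series$offsets * exp(eta)
  lp + sum(dpois(series$counts, mu, log = TRUE))
}

mvn_logd <- function(x, mean, Sigma) {
  R <- chol(Sigma)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

# central finite-difference gradient
fd_gradient <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# simple simulated series from a static Poisson GLM on the seasonal design
simulate_static_glm <- function(n, beta, offsets, seed,
                                period = 365.25 / 7) {
  tt <- seq_len(n)
  phase <- tt - 1
  X <- cbind(1, tt, build_design(phase, period)[, 3:6])
  eta <- as.numeric(X %*% beta)
  withr_seed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  y <- withr_seed(seed, rpois(n, offsets * exp(eta)))
  list(series = weekly_series(as.Date("1980-01-01") + 7 * (tt - 1L), y, offsets),
       X = X, eta = eta)
}

# linear Gaussian observation fixture: a state path from W(phi) observed
# through the seasonal design with known Gaussian noise
simulate_gaussian_obs <- function(n, phi, v = 0.05, seed = 1,
                                  theta0 = c(1, 0, 0.1, 0, 0.05, 0),
                                  spec = dglm_spec()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  W <- build_W(phi)
  e <- eigen(W, symmetric = TRUE)
  Wsq <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  th <- theta0
  S <- matrix(0, n, 6)
  for (t in 1:n) {
    th <- as.numeric(spec$G %*% th) + as.numeric(Wsq %*% rnorm(6))
    S[t, ] <- th
  }
  Fmat <- build_design(0:(n - 1), spec$period)
  yt <- rowSums(Fmat * S) + rnorm(n, 0, sqrt(v))
  list(obs = gaussian_obs(yt, rep(v, n)), states = S,
       series = weekly_series(as.Date("1980-01-01") + 7 * (0:(n - 1)),
                              rep(1, n), rep(1, n)))
}
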