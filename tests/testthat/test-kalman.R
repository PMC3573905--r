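# local-level reduction used by several conjugate-update checks
local_level_spec <- function(m0 = 0, C0 = 1) {
  dglm_spec(period = 52, m0 = m0, C0 = matrix(C0), G = matrix(1),
            design = function(t) matrix(1, length(t), 1))
}

test_that("filter reproduces conjugate normal updates on a local level", {
  spec <- local_level_spec()
  f1 <- kalman_filter(gaussian_obs(2, 1), spec, matrix(0))
  expect_equal(f1$m[1, 1], 1)
  expect_equal(f1$C[1, 1, 1], 0.5)
  f2 <- kalman_filter(gaussian_obs(c(2, 2), c(1, 1)), spec, matrix(0))
  expect_equal(f2$m[1, 2], 4 / 3)  # three unit-precision sources
  expect_equal(f2$C[1, 1, 2], 1 / 3)
})

test_that("Gaussian log-likelihood matches the prediction-error density", {
  spec <- local_level_spec()
  expect_equal(gaussian_loglik(gaussian_obs(2, 1), spec, matrix(0)),
               -0.5 * log(4 * pi) - 1)
  # observation at the prior predictive mean maximizes the contribution
  expect_equal(gaussian_loglik(gaussian_obs(0, 1), spec, matrix(0)),
               -0.5 * log(2 * pi * 2))
})

test_that("filter, smoother, lag-one covariances and loglik match direct joint-Gaussian conditioning", {
  spec <- dglm_spec()
  for (seed in c(42, 99)) {
    set.seed(seed)
    for (n in 3:5) {
      W <- random_psd(6, 0.05)
      vt <- runif(n, 0.2, 1)
      yt <- rnorm(n)
      Fmat <- build_design(0:(n - 1), spec$period)
      o <- joint_gaussian_oracle(Fmat, spec$G, W, spec$m0, spec$C0, vt, yt)
      f <- kalman_filter(gaussian_obs(yt, vt), spec, W)
      s <- kalman_smoother(f)
      expect_equal(f$m, o$filt_mean, tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(s$shat, o$smooth_mean, tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
      for (t in seq_len(n)) {
        expect_equal(f$C[, , t], o$filt_cov[[t]], tolerance = 1e-8,
                     ignore_attr = TRUE)
        expect_equal(s$Shat[, , t], o$smooth_cov[[t]], tolerance = 1e-8,
                     ignore_attr = TRUE)
      }
      for (t in 2:n)
        expect_equal(s$lag1[, , t], o$lag1[[t - 1]], tolerance = 1e-8,
                     ignore_attr = TRUE)
    }
  }
})

test_that("smoothing under W = 0 collapses to a static coefficient fit", {
  spec <- dglm_spec(C0 = diag(10, 6))
  set.seed(5)
  n <- 30
  yt <- rnorm(n, 1, 0.5)
  f <- kalman_filter(gaussian_obs(yt, rep(0.3, n)), spec, matrix(0, 6, 6))
  s <- kalman_smoother(f)
  # smoothed moments at t = n equal the filtered moments
  expect_equal(s$shat[, n], f$m[, n])
  expect_equal(s$Shat[, , n], f$C[, , n])
  # seasonal coefficients are constant over t and equal to the final filter
  for (j in 3:6)
    expect_equal(s$shat[j, ], rep(f$m[j, n], n), tolerance = 1e-9)
  # the trend block back-propagates deterministically: level_t = level_n - (n-t) slope
  expect_equal(s$shat[2, ], rep(f$m[2, n], n), tolerance = 1e-9)
  expect_equal(s$shat[1, ], f$m[1, n] - (n - seq_len(n)) * f$m[2, n],
               tolerance = 1e-8)
})

test_that("covariances stay PSD and smoothing never inflates variances", {
  spec <- dglm_spec()
  set.seed(7)
  n <- 40
  W <- random_psd(6, 0.02)
  f <- kalman_filter(gaussian_obs(rnorm(n), runif(n, 0.1, 0.6)), spec, W)
  s <- kalman_smoother(f)
  for (t in seq_len(n)) {
    expect_true(validate_psd(f$C[, , t], tol = 1e-9))
    expect_true(validate_psd(s$Shat[, , t], tol = 1e-9))
    expect_true(all(diag(f$C[, , t]) <= diag(f$R[, , t]) + 1e-12))
    expect_true(all(diag(s$Shat[, , t]) <= diag(f$C[, , t]) + 1e-10))
  }
  expect_true(all(f$q > 0))
})

test_that("missing observations are handled as prediction-only steps", {
  spec <- dglm_spec()
  set.seed(13)
  n <- 12
  W <- random_psd(6, 0.05)
  vt <- runif(n, 0.2, 0.8)
  yt <- rnorm(n)
  ytm <- yt; ytm[5] <- NA
  f <- kalman_filter(gaussian_obs(ytm, vt), spec, W)
  expect_equal(f$m[, 5], f$a[, 5])
  expect_true(is.na(f$e[5]))
  # equivalent to conditioning only on the observed subset
  Fmat <- build_design(0:(n - 1), spec$period)
  o <- joint_gaussian_oracle(Fmat, spec$G, W, spec$m0, spec$C0, vt, yt)
  # oracle on the reduced problem: drop week 5 from the observation stack
  keep <- setdiff(seq_len(n), 5)
  s <- kalman_smoother(f)
  # smoothed mean at n must match a filter run on the kept observations only
  f2 <- kalman_filter(gaussian_obs(ifelse(seq_len(n) %in% keep, yt, NA), vt),
                      spec, W)
  expect_equal(f$m[, n], f2$m[, n])
  expect_equal(sum(!is.na(f$e)), n - 1L)
})

test_that("log-likelihood is invariant under a consistent state permutation", {
  set.seed(3)
  n <- 8
  perm <- c(2, 1, 4, 6, 3, 5)
  P <- diag(6)[perm, ]
  spec <- dglm_spec()
  W <- random_psd(6, 0.05)
  vt <- runif(n, 0.2, 1)
  yt <- rnorm(n)
  spec_p <- dglm_spec(period = spec$period,
                      m0 = as.numeric(P %*% spec$m0),
                      C0 = P %*% spec$C0 %*% t(P),
                      G = P %*% spec$G %*% t(P),
                      design = function(t) build_design(t, spec$period) %*% t(P))
  ll1 <- gaussian_loglik(gaussian_obs(yt, vt), spec, W)
  ll2 <- gaussian_loglik(gaussian_obs(yt, vt), spec_p, P %*% W %*% t(P))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("invalid observation variances are rejected at construction", {
  expect_error(gaussian_obs(c(1, 2), c(1, 0)), "strictly positive")
  expect_error(gaussian_obs(c(1, 2), c(1, Inf)), "strictly positive")
  expect_error(gaussian_obs(c(1, Inf), c(1, 1)), "finite")
})
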