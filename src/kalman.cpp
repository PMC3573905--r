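// Kalman recursions for a linear Gaussian state space model with a single
// (possibly missing) observation per time step.  All heavy loops used by the
// EM and importance-sampling routines live here; the R layer owns validation
// and model structure.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat symm(const mat& A) { return 0.5 * (A + A.t()); }

// Filter (and optionally RTS smoother with lag-one covariances).
// y: length-n observations (NA -> prediction-only step), v: observation
// variances, Fmat: n x d design (row t), G: d x d transition, W: d x d
// evolution covariance, m0/C0: initial moments.
// Smoothed output columns/slices are indexed 0..n with 0 = time zero.
// [[Rcpp::export]]
Rcpp::List cpp_kf(const arma::vec& y, const arma::vec& v,
                  const arma::mat& Fmat, const arma::mat& G,
                  const arma::mat& W, const arma::vec& m0,
                  const arma::mat& C0, const bool smooth) {
  const uword n = y.n_elem;
  const uword d = m0.n_elem;

  mat a(d, n), m(d, n);
  cube Rc(d, d, n), Cc(d, d, n);
  vec e(n), q(n);
  e.fill(datum::nan);
  q.fill(datum::nan);
  double ll = 0.0;

  vec mprev = m0;
  mat Cprev = C0;
  const mat Id = eye(d, d);

  for (uword t = 0; t < n; ++t) {
    const vec at = G * mprev;
    const mat Rt = symm(G * Cprev * G.t() + W);
    a.col(t) = at;
    Rc.slice(t) = Rt;
    if (Rcpp::NumericVector::is_na(y(t))) {
      m.col(t) = at;
      Cc.slice(t) = Rt;
    } else {
      const vec Ft = Fmat.row(t).t();
      const vec RF = Rt * Ft;
      const double qt = dot(Ft, RF) + v(t);
      if (!std::isfinite(qt) || qt <= 0.0)
        Rcpp::stop("degenerate innovation variance at t = %d", (int)(t + 1));
      const double et = y(t) - dot(Ft, at);
      const vec K = RF / qt;
      m.col(t) = at + K * et;
      // Joseph form keeps the filtered covariance PSD
      const mat ImKF = Id - K * Ft.t();
      Cc.slice(t) = symm(ImKF * Rt * ImKF.t() + (K * K.t()) * v(t));
      e(t) = et;
      q(t) = qt;
      ll += -0.5 * (std::log(2.0 * datum::pi * qt) + et * et / qt);
    }
    mprev = m.col(t);
    Cprev = Cc.slice(t);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("a") = a, Rcpp::Named("R") = Rc, Rcpp::Named("m") = m,
      Rcpp::Named("C") = Cc, Rcpp::Named("e") = e, Rcpp::Named("q") = q,
      Rcpp::Named("loglik") = ll);

  if (smooth) {
    mat s(d, n + 1);
    cube S(d, d, n + 1), L(d, d, n);
    s.col(n) = m.col(n - 1);
    S.slice(n) = Cc.slice(n - 1);
    for (uword tau = n; tau >= 1; --tau) {
      const vec mf = (tau >= 2) ? vec(m.col(tau - 2)) : m0;
      const mat Cf = (tau >= 2) ? mat(Cc.slice(tau - 2)) : C0;
      const mat Rt = Rc.slice(tau - 1);
      mat Jt;  // R^{-1} G Cf, then transposed to Cf G' R^{-1}
      const bool ok = solve(Jt, Rt, G * Cf);
      if (!ok) Rcpp::stop("singular predicted covariance at t = %d", (int)tau);
      const mat J = Jt.t();
      s.col(tau - 1) = mf + J * (s.col(tau) - a.col(tau - 1));
      S.slice(tau - 1) = symm(Cf + J * (S.slice(tau) - Rt) * J.t());
      // Cov(theta_tau, theta_{tau-1} | all data)
      L.slice(tau - 1) = S.slice(tau) * J.t();
    }
    out["shat"] = s;
    out["Shat"] = S;
    out["lag1"] = L;
  }
  return out;
}

// Average one-step state prediction error second moment, the unconstrained
// EM update of W: (1/n) sum_t E[(theta_t - G theta_{t-1})(...)' | data].
// shat: d x (n+1) smoothed means (col 0 = time zero), Shat: matching
// covariances, lag1: slice t-1 = Cov(theta_t, theta_{t-1} | data).
// [[Rcpp::export]]
arma::mat cpp_em_vhat(const arma::mat& shat, const arma::cube& Shat,
                      const arma::cube& lag1, const arma::mat& G) {
  const uword d = shat.n_rows;
  const uword n = Shat.n_slices - 1;
  mat V(d, d, fill::zeros);
  for (uword tau = 1; tau <= n; ++tau) {
    const mat Ett = Shat.slice(tau) + shat.col(tau) * shat.col(tau).t();
    const mat Et1 = lag1.slice(tau - 1) + shat.col(tau) * shat.col(tau - 1).t();
    const mat E11 = Shat.slice(tau - 1) + shat.col(tau - 1) * shat.col(tau - 1).t();
    V += Ett - Et1 * G.t() - G * Et1.t() + G * E11 * G.t();
  }
  return symm(V) / (double)n;
}

static mat rnorm_mat(uword r, uword c) {
  mat Z(r, c);
  for (uword j = 0; j < c; ++j)
    for (uword i = 0; i < r; ++i) Z(i, j) = norm_rand();
  return Z;
}

// Smoothed means of the linear predictor for many observation columns that
// share the same variance structure: the gain (K) and smoothing (J) matrices
// are computed once and applied to all columns.
static mat smooth_eta_many(const mat& Y, const vec& v, const mat& Fmat,
                           const mat& G, const mat& W, const vec& m0,
                           const mat& C0) {
  const uword n = Y.n_rows;
  const uword M = Y.n_cols;
  const uword d = m0.n_elem;

  mat K(d, n);
  cube J(d, d, n > 1 ? n - 1 : 1);
  {
    mat Cprev = C0;
    for (uword t = 0; t < n; ++t) {
      const mat Rt = symm(G * Cprev * G.t() + W);
      const vec Ft = Fmat.row(t).t();
      const vec RF = Rt * Ft;
      const double qt = dot(Ft, RF) + v(t);
      if (!std::isfinite(qt) || qt <= 0.0)
        Rcpp::stop("degenerate innovation variance at t = %d", (int)(t + 1));
      const vec Kt = RF / qt;
      K.col(t) = Kt;
      if (t >= 1) {
        mat Jt;
        if (!solve(Jt, Rt, G * Cprev))
          Rcpp::stop("singular predicted covariance at t = %d", (int)(t + 1));
        J.slice(t - 1) = Jt.t();  // C_{t-1} G' R_t^{-1}
      }
      const mat ImKF = eye(d, d) - Kt * Ft.t();
      Cprev = symm(ImKF * Rt * ImKF.t() + (Kt * Kt.t()) * v(t));
    }
  }

  cube Mm(d, M, n);
  {
    mat mprev = repmat(m0, 1, M);
    for (uword t = 0; t < n; ++t) {
      const mat at = G * mprev;
      const rowvec et = Y.row(t) - Fmat.row(t) * at;
      Mm.slice(t) = at + K.col(t) * et;
      mprev = Mm.slice(t);
    }
  }

  mat Eta(n, M);
  mat s = Mm.slice(n - 1);
  Eta.row(n - 1) = Fmat.row(n - 1) * s;
  for (uword t2 = n - 1; t2 >= 1; --t2) {
    const uword t = t2 - 1;
    s = Mm.slice(t) + J.slice(t) * (s - G * Mm.slice(t));
    Eta.row(t) = Fmat.row(t) * s;
  }
  return Eta;
}

// Importance-sampling log-weights for the exact likelihood of the Poisson
// model, via the mean-correction simulation smoother applied to the
// approximating Gaussian model (pseudo-observations ytilde, variances vtilde).
// Draws use R's RNG.  Returns ndraw (or 2*ndraw with antithetic pairing)
// log-weights log p(y|theta) - log g(ytilde|theta) along each draw.
// [[Rcpp::export]]
Rcpp::List cpp_is_weights(const arma::vec& ycount, const arma::vec& offs,
                          const arma::vec& ytilde, const arma::vec& vtilde,
                          const arma::mat& Fmat, const arma::mat& G,
                          const arma::mat& W, const arma::vec& m0,
                          const arma::mat& C0, const arma::mat& Wsqrt,
                          const arma::mat& C0sqrt, const int ndraw,
                          const bool antithetic) {
  const uword n = ycount.n_elem;
  const uword d = m0.n_elem;
  const uword M = (uword)ndraw;

  const mat eta_obs = smooth_eta_many(mat(ytilde), vtilde, Fmat, G, W, m0, C0);

  // unconditional draws from the state model plus Gaussian pseudo-noise
  mat etap(n, M), yp(n, M);
  {
    mat th = repmat(m0, 1, M) + C0sqrt * rnorm_mat(d, M);
    const vec sv = sqrt(vtilde);
    for (uword t = 0; t < n; ++t) {
      th = G * th + Wsqrt * rnorm_mat(d, M);
      etap.row(t) = Fmat.row(t) * th;
      yp.row(t) = etap.row(t) + sv(t) * rnorm_mat(1, M);
    }
  }
  const mat etahat_p = smooth_eta_many(yp, vtilde, Fmat, G, W, m0, C0);

  const uword Mtot = antithetic ? 2 * M : M;
  mat draws(n, Mtot);
  draws.cols(0, M - 1) = repmat(eta_obs, 1, M) + etap - etahat_p;
  if (antithetic)
    draws.cols(M, 2 * M - 1) = 2.0 * repmat(eta_obs, 1, M) - draws.cols(0, M - 1);

  vec logw(Mtot, fill::zeros);
  vec lgam(n), cg(n);
  for (uword t = 0; t < n; ++t) {
    lgam(t) = std::lgamma(ycount(t) + 1.0);
    cg(t) = 0.5 * std::log(2.0 * datum::pi * vtilde(t));
  }
  for (uword j = 0; j < Mtot; ++j) {
    double acc = 0.0;
    for (uword t = 0; t < n; ++t) {
      const double eta = draws(t, j);
      const double logmu = std::log(offs(t)) + eta;
      // Poisson log density minus Gaussian pseudo log density
      acc += ycount(t) * logmu - std::exp(logmu) - lgam(t);
      const double r = ytilde(t) - eta;
      acc += cg(t) + 0.5 * r * r / vtilde(t);
    }
    logw(j) = acc;
  }

  return Rcpp::List::create(Rcpp::Named("logw") = logw,
                            Rcpp::Named("eta_smoothed") = vec(eta_obs.col(0)));
}

// Iterated extended Kalman smoothing for the Poisson observation model,
// fused with the EM moment computation.  Linearizes around eta, smooths,
// and repeats until the sup-norm change in eta is below tol; then runs one
// covariance smoothing pass at the converged linearization to produce the
// Gaussian log-likelihood, the smoothed means, and the unconstrained EM
// update Vhat.
// [[Rcpp::export]]
Rcpp::List cpp_mode_em(const arma::vec& y, const arma::vec& offs,
                       const arma::mat& Fmat, const arma::mat& G,
                       const arma::mat& W, const arma::vec& m0,
                       const arma::mat& C0, const arma::vec& eta0,
                       const double tol, const int maxit,
                       const bool want_vhat) {
  const uword n = y.n_elem;
  const uword d = m0.n_elem;
  vec eta = eta0;
  vec ytilde(n), vtilde(n);
  const mat Id = eye(d, d);

  mat K(d, n), a(d, n), m(d, n);
  cube Cc(d, d, n), Rc(d, d, n);
  double ll = 0.0;
  bool converged = false;
  int iter = 0;

  auto linearize = [&]() {
    for (uword t = 0; t < n; ++t) {
      const double mu = offs(t) * std::exp(eta(t));
      if (!std::isfinite(mu) || mu <= 0.0)
        Rcpp::stop("numerical range error in linearization at t = %d", (int)(t + 1));
      ytilde(t) = eta(t) + (y(t) - mu) / mu;
      vtilde(t) = 1.0 / mu;
    }
  };

  auto pass = [&]() {
    // filter
    vec mprev = m0;
    mat Cprev = C0;
    ll = 0.0;
    for (uword t = 0; t < n; ++t) {
      const vec at = G * mprev;
      const mat Rt = symm(G * Cprev * G.t() + W);
      const vec Ft = Fmat.row(t).t();
      const vec RF = Rt * Ft;
      const double qt = dot(Ft, RF) + vtilde(t);
      if (!std::isfinite(qt) || qt <= 0.0)
        Rcpp::stop("degenerate innovation variance at t = %d", (int)(t + 1));
      const double et = ytilde(t) - dot(Ft, at);
      const vec Kt = RF / qt;
      a.col(t) = at;
      Rc.slice(t) = Rt;
      K.col(t) = Kt;
      m.col(t) = at + Kt * et;
      const mat ImKF = Id - Kt * Ft.t();
      Cc.slice(t) = symm(ImKF * Rt * ImKF.t() + (Kt * Kt.t()) * vtilde(t));
      mprev = m.col(t);
      Cprev = Cc.slice(t);
      ll += -0.5 * (std::log(2.0 * datum::pi * qt) + et * et / qt);
    }
  };

  vec eta_new(n);
  while (iter < maxit) {
    ++iter;
    linearize();
    pass();
    // smoothed means only
    vec s = m.col(n - 1);
    eta_new(n - 1) = dot(Fmat.row(n - 1).t(), s);
    for (uword t2 = n - 1; t2 >= 1; --t2) {
      const uword t = t2 - 1;  // smooth time t+1 -> t (0-based obs index)
      const mat Cf = Cc.slice(t);
      const mat Rt = Rc.slice(t + 1);
      mat Jt;
      if (!solve(Jt, Rt, G * Cf))
        Rcpp::stop("singular predicted covariance at t = %d", (int)(t + 2));
      const mat J = Jt.t();
      s = m.col(t) + J * (s - a.col(t + 1));
      eta_new(t) = dot(Fmat.row(t).t(), s);
    }
    const double delta = max(abs(eta_new - eta));
    eta = eta_new;
    if (delta < tol) { converged = true; break; }
  }

  // the arrays from the last pass correspond to a linearization within tol
  // of the converged mode; reuse them instead of re-running the filter
  if (iter == 0) { linearize(); pass(); }
  mat shat(d, n + 1);
  Rcpp::List out;
  if (want_vhat) {
    // fused backward pass: smoothed covariances are consumed on the fly to
    // accumulate the EM moment matrix, so no cubes are materialized
    mat V(d, d, fill::zeros);
    mat S_next = Cc.slice(n - 1);
    shat.col(n) = m.col(n - 1);
    for (uword tau = n; tau >= 1; --tau) {
      const vec mf = (tau >= 2) ? vec(m.col(tau - 2)) : m0;
      const mat Cf = (tau >= 2) ? mat(Cc.slice(tau - 2)) : C0;
      const mat Rt = Rc.slice(tau - 1);
      mat Jt;
      if (!solve(Jt, Rt, G * Cf))
        Rcpp::stop("singular predicted covariance at t = %d", (int)tau);
      const mat J = Jt.t();
      shat.col(tau - 1) = mf + J * (shat.col(tau) - a.col(tau - 1));
      const mat S_cur = symm(Cf + J * (S_next - Rt) * J.t());
      const mat L = S_next * J.t();  // Cov(theta_tau, theta_{tau-1})
      const vec st = shat.col(tau);
      const vec st1 = shat.col(tau - 1);
      const mat Ett = S_next + st * st.t();
      const mat Et1 = L + st * st1.t();
      const mat E11 = S_cur + st1 * st1.t();
      V += Ett - Et1 * G.t() - G * Et1.t() + G * E11 * G.t();
      S_next = S_cur;
    }
    V = symm(V) / (double)n;
    out = Rcpp::List::create(
        Rcpp::Named("eta") = eta, Rcpp::Named("iterations") = iter,
        Rcpp::Named("converged") = converged, Rcpp::Named("loglik") = ll,
        Rcpp::Named("vhat") = V, Rcpp::Named("shat") = shat);
  } else {
    out = Rcpp::List::create(
        Rcpp::Named("eta") = eta, Rcpp::Named("iterations") = iter,
        Rcpp::Named("converged") = converged, Rcpp::Named("loglik") = ll);
  }
  return out;
}
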