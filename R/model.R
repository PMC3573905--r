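#' Weekly count series with person-time offsets
#'
#' Container for a weekly-aggregated event count time series.  Offsets are
#' person-time at risk expressed in units of 100 person-years per week, so
#' that fitted rates read directly as incidence rates per 100 person-years.
#'
#' @param start_dates `Date` vector, the start date of each 7-day bin;
#'   must increase in exact steps of 7 days.
#' @param counts non-negative integer event counts per week.
#' @param offsets positive person-time at risk per week (100 person-year
#'   units).
#' @return An object of class `weekly_series` with elements `start_dates`,
#'   `counts`, `offsets` and `n`.
#' @export
weekly_series <- function(start_dates, counts, offsets) {
  start_dates <- as.Date(start_dates)
  n <- length(counts)
  if (n < 2L)
    stop("a weekly series needs at least 2 weeks")
  if (length(start_dates) != n || length(offsets) != n)
    stop("start_dates, counts and offsets must have equal length")
  if (anyNA(start_dates))
    stop("start_dates contains missing or unparseable dates")
  dd <- diff(as.integer(start_dates))
  if (any(dd != 7L)) {
    i <- which(dd != 7L)[1L]
    stop(sprintf("dates must advance by exactly 7 days; violated between rows %d and %d (%s -> %s)",
                 i, i + 1L, start_dates[i], start_dates[i + 1L]))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad))
    stop(sprintf("counts must be non-negative integers; first violation at row %d", bad[1L]))
  bad <- which(!is.finite(offsets) | offsets <= 0)
  if (length(bad))
    stop(sprintf("offsets must be positive and finite; first violation at row %d", bad[1L]))
  structure(list(start_dates = start_dates,
                 counts = as.numeric(counts),
                 offsets = as.numeric(offsets),
                 n = n),
            class = "weekly_series")
}

#' @export
print.weekly_series <- function(x, ...) {
  cat(sprintf("weekly_series: %d weeks, %s to %s\n", x$n,
              format(x$start_dates[1L]), format(x$start_dates[x$n])))
  cat(sprintf("  counts: median %.0f, range [%d, %d]\n",
              stats::median(x$counts), min(x$counts), max(x$counts)))
  cat(sprintf("  offsets (100 person-years/week): range [%.3g, %.3g]\n",
              min(x$offsets), max(x$offsets)))
  invisible(x)
}

#' Evolution covariance hyperparameters
#'
#' The eight variance/covariance parameters of the structured evolution
#' covariance `W`: `phi1` variance of the level, `phi2` variance of the
#' slope, `phi3` level-slope covariance, `phi4`/`phi5` shared variance of the
#' annual/semiannual sinusoid coefficient pair, `phi6`/`phi7` covariance
#' within each pair, `phi8` common covariance between the two pairs.
#'
#' @param phi numeric vector of length 8 in the order above.
#' @return A named numeric vector of class `hyperparams`.
#' @export
hyperparams <- function(phi) {
  phi <- as.numeric(phi)
  if (length(phi) != 8L || anyNA(phi) || any(!is.finite(phi)))
    stop("phi must be a finite numeric vector of length 8")
  if (any(phi[c(1L, 2L, 4L, 5L)] < 0))
    stop("variance hyperparameters phi1, phi2, phi4, phi5 must be non-negative")
  structure(setNames(phi, .phi_names), class = "hyperparams")
}

#' Model specification for the seasonal DGLM
#'
#' Defines the state space structure: a six-dimensional state
#' `(level, slope, a1, b1, a2, b2)` with local-linear-trend transition and
#' identity evolution of the sinusoid coefficients, design vector
#' `F_t = (1, 0, cos, sin, cos2, sin2)` evaluated at week index `t`
#' (0 at the first week of the series), and initial moments `m0`, `C0`.
#' Custom `G`/`design` allow reduced toy models in tests and examples.
#'
#' @param period weeks per year; default `365.25/7`.
#' @param m0 initial state mean.
#' @param C0 initial state covariance (symmetric PSD).
#' @param G optional transition matrix overriding the standard structure.
#' @param design optional function `t -> matrix(length(t), d)` overriding the
#'   standard design.
#' @return An object of class `dglm_spec`.
#' @export
dglm_spec <- function(period = 365.25 / 7, m0 = rep(0, 6),
                      C0 = diag(100, 6), G = NULL, design = NULL) {
  if (!is.finite(period) || period <= 0) stop("period must be positive")
  d <- length(m0)
  C0 <- as.matrix(C0)
  if (!all(dim(C0) == d)) stop("C0 must be a square matrix matching length(m0)")
  if (max(abs(C0 - t(C0))) > 1e-8 * max(1, max(abs(C0))))
    stop("C0 must be symmetric")
  if (is.null(G)) {
    if (d != 6L) stop("the standard model has state dimension 6; supply G and design for other dimensions")
    G <- build_transition()
  } else {
    G <- as.matrix(G)
    if (!all(dim(G) == d)) stop("G must be d x d")
  }
  if (is.null(design)) {
    if (d != 6L) stop("supply a design function for non-standard state dimensions")
    design <- function(t) build_design(t, period)
  }
  structure(list(period = period, state_dim = d, m0 = as.numeric(m0),
                 C0 = C0, G = G, design = design),
            class = "dglm_spec")
}

#' @export
print.dglm_spec <- function(x, ...) {
  cat(sprintf("dglm_spec: state dimension %d, period %.4f weeks/year\n",
              x$state_dim, x$period))
  invisible(x)
}

#' Design vector of the seasonal DGLM
#'
#' `F_t = (1, 0, cos(2*pi*t/P), sin(2*pi*t/P), cos(4*pi*t/P), sin(4*pi*t/P))`:
#' the level loads directly, the slope only through the transition, and the
#' two sinusoid pairs carry the annual and semiannual harmonics.
#'
#' @param t week index (vectorized); phase zero at `t = 0`.
#' @param period weeks per year.
#' @return A `length(t) x 6` matrix with rows `F_t`.
#' @export
build_design <- function(t, period) {
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) || period <= 0)
    stop("invalid period: must be a positive finite scalar")
  if (anyNA(t) || any(!is.finite(t)))
    stop("invalid week index: must be finite")
  w <- 2 * pi * t / period
  cbind(1, 0, cos(w), sin(w), cos(2 * w), sin(2 * w),
        deparse.level = 0)
}

#' Transition matrix of the seasonal DGLM
#'
#' Local linear trend block `[[1, 1], [0, 1]]` (the level gains the slope at
#' each step) and identity on the four sinusoid coefficients, whose periodic
#' shape is carried by the design vector.
#'
#' @return The 6 x 6 transition matrix.
#' @export
build_transition <- function() {
  G <- diag(6)
  G[1L, 2L] <- 1
  dimnames(G) <- list(.state_names, .state_names)
  G
}

#' Structured evolution covariance W(phi)
#'
#' Block diagonal: an unconstrained 2 x 2 trend block
#' `[[phi1, phi3], [phi3, phi2]]`, and a 4 x 4 seasonal block with equal
#' variances within each sinusoid pair (`phi4`, `phi5`), within-pair
#' covariances `phi6`, `phi7`, and a common cross-pair covariance `phi8`.
#'
#' @param phi length-8 hyperparameter vector (see [hyperparams()]).
#' @return A symmetric 6 x 6 matrix.
#' @export
build_W <- function(phi) {
  phi <- as.numeric(phi)
  if (length(phi) != 8L) stop("phi must have length 8")
  W <- matrix(0, 6, 6, dimnames = list(.state_names, .state_names))
  W[1L, 1L] <- phi[1L]
  W[2L, 2L] <- phi[2L]
  W[1L, 2L] <- W[2L, 1L] <- phi[3L]
  W[3L, 3L] <- W[4L, 4L] <- phi[4L]
  W[5L, 5L] <- W[6L, 6L] <- phi[5L]
  W[3L, 4L] <- W[4L, 3L] <- phi[6L]
  W[5L, 6L] <- W[6L, 5L] <- phi[7L]
  W[3L:4L, 5L:6L] <- phi[8L]
  W[5L:6L, 3L:4L] <- phi[8L]
  W
}

#' Read hyperparameters back from a structured W
#'
#' Inverse of [build_W()] for matrices of the constrained form; tied entries
#' are averaged, so for an unconstrained symmetric matrix this is the
#' projection onto the structure used in the EM M-step.
#'
#' @param W symmetric 6 x 6 matrix.
#' @return A `hyperparams` vector.
#' @export
phi_from_W <- function(W) {
  W <- as.matrix(W)
  if (!all(dim(W) == 6L)) stop("W must be 6 x 6")
  phi <- c(W[1L, 1L], W[2L, 2L], (W[1L, 2L] + W[2L, 1L]) / 2,
           (W[3L, 3L] + W[4L, 4L]) / 2, (W[5L, 5L] + W[6L, 6L]) / 2,
           (W[3L, 4L] + W[4L, 3L]) / 2, (W[5L, 6L] + W[6L, 5L]) / 2,
           mean(W[3L:4L, 5L:6L]))
  structure(setNames(phi, .phi_names), class = "hyperparams")
}

#' Check a covariance matrix for positive semidefiniteness
#'
#' @param W symmetric matrix.
#' @param tol tolerance, relative to the largest diagonal entry.
#' @return `TRUE` iff the smallest eigenvalue is at least `-tol * scale`.
#' @export
validate_psd <- function(W, tol = 1e-12) {
  W <- as.matrix(W)
  scale <- max(abs(diag(W)), 1e-300)
  if (max(abs(W - t(W))) > 1e-8 * max(scale, 1))
    stop("invalid covariance: matrix is not symmetric")
  ev <- eigen((W + t(W)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) >= -tol * scale
}

# coerce phi (hyperparams / length-8 vector) or a full matrix to W,
# checking dimension against the spec
.as_W <- function(phi, spec) {
  W <- if (is.matrix(phi)) phi else build_W(phi)
  if (!all(dim(W) == spec$state_dim))
    stop("W dimension does not match the model specification")
  if (!validate_psd(W, tol = 1e-10))
    stop("invalid covariance: W(phi) is not positive semidefinite")
  W
}

# symmetric matrix square root (handles singular W)
.mat_sqrt <- function(W) {
  e <- eigen((W + t(W)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Serialize a model specification to YAML
#'
#' Writes period, state dimension, initial moments and the state ordering.
#' Only standard-structure specifications (default `G` and design) round-trip.
#'
#' @param spec a [dglm_spec()].
#' @param path output file.
#' @export
spec_to_yaml <- function(spec, path) {
  yaml::write_yaml(list(period = spec$period,
                        state_dim = spec$state_dim,
                        state_names = .state_names,
                        m0 = spec$m0,
                        C0 = lapply(seq_len(nrow(spec$C0)), function(i) spec$C0[i, ])),
                   path)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path file written by [spec_to_yaml()].
#' @return A [dglm_spec()].
#' @export
spec_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  C0 <- do.call(rbind, x$C0)
  dglm_spec(period = x$period, m0 = unlist(x$m0), C0 = C0)
}
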