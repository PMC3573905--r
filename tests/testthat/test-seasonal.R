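P <- 365.25 / 7

test_that("seasonal curve evaluates the two-harmonic sum", {
  expect_true(all(seasonal_curve(rep(0, 6), P)$s == 0))
  cur <- seasonal_curve(c(0, 0, 1, 0, 0, 0), P, grid_size = 4)
  expect_equal(cur$s[1], 1)                    # d = 0
  expect_equal(cur$s[3], -1, tolerance = 1e-12)  # d = P/2
  expect_equal(seasonal_curve(c(0, 0, 0.1, 0, 0.05, 0), P)$s[1], 0.15)
})

test_that("PTT ratio matches the single-cosine closed form", {
  expect_equal(ptt_ratio(rep(0, 6), P), 1.0)
  expect_equal(ptt_ratio(c(0, 0, 0.1, 0, 0, 0), P), exp(0.2),
               tolerance = 1e-6)
  # phase rotation leaves the amplitude unchanged
  expect_equal(ptt_ratio(c(0, 0, 0.06, 0.08, 0, 0), P),
               ptt_ratio(c(0, 0, 0.1, 0, 0, 0), P), tolerance = 1e-8)
})

test_that("PTT is monotone in the seasonal scale and matches a brute-force grid", {
  th <- c(0, 0, 0.08, -0.03, 0.02, 0.04)
  # scaling all four coefficients by c scales log PTT exactly by c
  for (cc in c(0.5, 2, 3)) {
    expect_equal(log(ptt_ratio(c(0, 0, cc * th[3:6]), P)),
                 cc * log(ptt_ratio(th, P)), tolerance = 1e-9)
  }
  # exhaustive fine grid oracle
  d <- seq(0, P, length.out = 1e5 + 1)[1:1e5]
  s <- as.numeric(build_design(d, P)[, 3:6] %*% th[3:6])
  expect_equal(ptt_ratio(th, P), exp(max(s) - min(s)), tolerance = 1e-7)
})

test_that("peak and trough days follow the cosine and sine extremes", {
  pt <- peak_trough_times(c(0, 0, 0.1, 0, 0, 0), P)
  expect_equal(pt$peak_day, 0, tolerance = 1e-6)
  expect_equal(pt$trough_day, 7 * P / 2, tolerance = 1e-4)
  pt2 <- peak_trough_times(c(0, 0, 0, 0.1, 0, 0), P)
  expect_equal(pt2$peak_day, 7 * P / 4, tolerance = 1e-4)
  # flat curve: undefined markers
  ptf <- peak_trough_times(rep(0, 6), P)
  expect_true(is.na(ptf$peak_day) && is.na(ptf$trough_day))
  # mixed two-harmonic case against the exhaustive grid
  th <- c(0, 0, 0.07, 0.02, -0.03, 0.01)
  d <- seq(0, P, length.out = 1e5 + 1)[1:1e5]
  s <- as.numeric(build_design(d, P)[, 3:6] %*% th[3:6])
  pt3 <- peak_trough_times(th, P)
  expect_equal(pt3$peak_day, 7 * d[which.max(s)], tolerance = 1e-2)
  expect_equal(pt3$trough_day, 7 * d[which.min(s)], tolerance = 1e-2)
})

test_that("percent deviation is anchored at the annual median", {
  expect_true(all(percent_deviation(rep(0, 6), P)$pct == 0))
  th <- c(0, 0, 0.1, 0, 0, 0)
  pd <- percent_deviation(th, P)
  f <- exp(seasonal_curve(th, P)$s)
  expect_equal(max(pd$pct), 100 * (exp(0.1) / median(f) - 1), tolerance = 1e-9)
  # the curve peaks where the seasonal effect peaks
  pt <- peak_trough_times(th, P)
  expect_equal(7 * pd$d[which.max(pd$pct)], pt$peak_day, tolerance = 1e-2)
})

test_that("trend rates exponentiate the smoothed level with pointwise intervals", {
  sim <- stroke_af_scenario(seed = 12, n = 60)
  spec <- dglm_spec()
  it <- iterated_smoothing(sim$series, spec, build_W(sim$phi))
  sm <- it$smoother
  # synthetic smoother with known level and zero variance
  sm0 <- sm
  sm0$shat[1, ] <- log(4)
  sm0$Shat[1, 1, ] <- 0
  tr <- trend_rates(sm0, sim$series)
  expect_equal(tr$rate, rep(4, 60))
  expect_equal(tr$ci_low, tr$rate)
  expect_equal(tr$ci_high, tr$rate)
  tr2 <- trend_rates(sm, sim$series)
  expect_true(all(tr2$ci_low <= tr2$rate & tr2$rate <= tr2$ci_high))
})

test_that("the smoothed trend recovers the simulated trend mid-series", {
  sim <- stroke_af_scenario(seed = 21, n = 500)
  spec <- dglm_spec()
  it <- iterated_smoothing(sim$series, spec, build_W(sim$phi))
  tr <- trend_rates(it$smoother, sim$series)
  mid <- 126:375
  rel <- abs(tr$rate[mid] - exp(sim$states[mid, 1])) / exp(sim$states[mid, 1])
  expect_lt(mean(rel), 0.10)
})

test_that("a static fit has constant PTT while a dynamic fit varies", {
  simd <- stroke_af_scenario(seed = 8, n = 400)
  sims <- stroke_af_scenario(seed = 8, n = 400, dynamic_seasonal = FALSE)
  spec <- dglm_spec()
  ptt_d <- ptt_series(simd$states, spec$period)
  ptt_s <- ptt_series(sims$states, spec$period)
  expect_lt(diff(range(ptt_s)), 1e-10)
  expect_gt(diff(range(ptt_d)), 0.01)
  # the same contract holds for the fitted trajectories
  it_s <- iterated_smoothing(sims$series, spec, build_W(sims$phi))
  fit_ptt <- ptt_series(it_s$smoother, spec$period)
  expect_lt(diff(range(fit_ptt)), 1e-6)
})
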