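acq50 <- dsc_acquisition(te = 0.032, tr = 1.9, n_frames = 50, baseline = 1:8)
times50 <- (0:49) * 1.9

test_that("delta_r2star inverts the signal model and flags bad frames", {
  flat <- dsc_series(times50, rep(500, 50), acq50)
  expect_equal(delta_r2star(flat)$values, rep(0, 50))

  # bolus peak at t0 + alpha*beta = 19 + 5.7 = 24.7 s, on the frame grid
  x <- pwifet:::gamma_variate(times50, 19, 3, 1.9, 12)
  series <- dsc_series(times50, 800 * exp(-acq50$te * x), acq50)
  expect_equal(delta_r2star(series)$values, x, tolerance = 1e-12)
  expect_equal(max(delta_r2star(series)$values), 12, tolerance = 1e-12)

  bad <- dsc_series(times50, c(rep(500, 49), 500), acq50)
  bad$signal[23] <- -1
  expect_error(delta_r2star(bad), "frame\\(s\\) 23")
})

test_that("delta_r2star and downstream fits are scale equivariant", {
  sim <- gen_dsc_roi_curves(list(k1 = 1.3, k2 = 0.04), seed = 2)
  scaled <- sim
  scaled$tumor$signal <- sim$tumor$signal * 7.5
  scaled$reference$signal <- sim$reference$signal * 7.5
  f1 <- bw_fit(delta_r2star(sim$tumor), delta_r2star(sim$reference))
  f2 <- bw_fit(delta_r2star(scaled$tumor), delta_r2star(scaled$reference))
  expect_equal(f1$k1, f2$k1, tolerance = 1e-12)
  expect_equal(f1$k2, f2$k2, tolerance = 1e-12)
  r1 <- rcbv_roi(sim$tumor, sim$reference)
  r2 <- rcbv_roi(scaled$tumor, scaled$reference)
  expect_equal(r1$rcbv_max, r2$rcbv_max, tolerance = 1e-12)
})

test_that("reference_curve averages pointwise", {
  mk <- function(v) pwifet:::delta_r2_series(times50, v, acq50)
  a <- mk(seq_len(50)); b <- mk(rep(2, 50))
  expect_equal(reference_curve(list(a))$values, a$values)
  expect_equal(reference_curve(list(a, b))$values, (a$values + b$values) / 2)
  expect_error(reference_curve(list(a, b), include = c(FALSE, FALSE)),
               "no series")
  # law of large numbers: 100 noisy copies average close to the clean bolus
  clean <- pwifet:::gamma_variate(times50, 19, 3, 2.85, 10)
  set.seed(9)
  noisy <- lapply(1:100, function(i) mk(clean + rnorm(50, 0, 0.5)))
  expect_lt(max(abs(reference_curve(noisy)$values - clean)), 0.5 / 10 * 3)
})

test_that("bw_fit recovers an exactly generated leakage curve", {
  ref <- pwifet:::delta_r2_series(
    times50, pwifet:::gamma_variate(times50, 19, 3, 2.85, 10), acq50)
  R <- pwifet:::cumtrapz(times50, ref$values)
  tgt <- pwifet:::delta_r2_series(times50, 1.3 * ref$values - 0.04 * R, acq50)
  fit <- bw_fit(tgt, ref)
  expect_equal(fit$k1, 1.3, tolerance = 1e-8)
  expect_equal(fit$k2, 0.04, tolerance = 1e-8)
  expect_lt(fit$residual_sse, 1e-16)

  ident <- bw_fit(ref, ref)
  expect_equal(ident$k1, 1)
  expect_equal(ident$k2, 0, tolerance = 1e-12)
  expect_equal(ident$corrected$values, ref$values, tolerance = 1e-10)

  const <- pwifet:::delta_r2_series(times50, rep(0, 50), acq50)
  expect_error(bw_fit(tgt, const), "degenerate")
})

test_that("bw_fit equals a brute-force grid search on a small instance", {
  ref <- pwifet:::delta_r2_series(
    times50, pwifet:::gamma_variate(times50, 19, 3, 2.85, 10), acq50)
  R <- pwifet:::cumtrapz(times50, ref$values)
  set.seed(3)
  tgt <- pwifet:::delta_r2_series(
    times50, 1.2 * ref$values - 0.03 * R + rnorm(50, 0, 0.2), acq50)
  fit <- bw_fit(tgt, ref)
  k1g <- seq(fit$k1 - 0.05, fit$k1 + 0.05, length.out = 41)
  k2g <- seq(fit$k2 - 0.01, fit$k2 + 0.01, length.out = 41)
  sse <- outer(k1g, k2g, Vectorize(function(a, b)
    sum((tgt$values - a * ref$values + b * R)^2)))
  best <- which(sse == min(sse), arr.ind = TRUE)
  expect_equal(k1g[best[1]], fit$k1, tolerance = 0.05 / 40 * 1.5)
  expect_equal(k2g[best[2]], fit$k2, tolerance = 0.01 / 40 * 1.5)
})

test_that("noisy leakage fits recover K2 within Monte-Carlo tolerance", {
  ref <- pwifet:::delta_r2_series(
    times50, pwifet:::gamma_variate(times50, 19, 3, 2.85, 10), acq50)
  R <- pwifet:::cumtrapz(times50, ref$values)
  pk <- max(ref$values)
  set.seed(42)
  k2_hat <- replicate(200, {
    tgt <- pwifet:::delta_r2_series(
      times50, 1.3 * ref$values - 0.05 * R + rnorm(50, 0, 0.05 * pk), acq50)
    bw_fit(tgt, ref)$k2
  })
  expect_lt(abs(mean(k2_hat) - 0.05) / 0.05, 0.10)
  expect_gt(mean(abs(k2_hat - 0.05) / 0.05 < 0.10), 0.9)
})

test_that("positive K2 correction restores blood-volume area", {
  sim <- gen_dsc_roi_curves(list(k1 = 1.2, k2 = 0.05), seed = 5)
  tum <- delta_r2star(sim$tumor)
  fit <- bw_fit(tum, delta_r2star(sim$reference))
  expect_gte(cbv_integrate(fit$corrected), cbv_integrate(tum))
  # corrected area equals the true leakage-free area at zero noise
  expect_equal(cbv_integrate(fit$corrected), sim$truth$true_area,
               tolerance = 1e-9)
})

test_that("cbv_integrate matches analytic and dense-grid areas", {
  zero <- pwifet:::delta_r2_series(times50, rep(0, 50), acq50)
  expect_equal(cbv_integrate(zero), 0)
  const <- pwifet:::delta_r2_series(times50, rep(3, 50), acq50)
  expect_equal(cbv_integrate(const, window = 9:50),
               3 * (times50[50] - times50[9]))
  expect_error(cbv_integrate(const, window = 5L), "at least 2")
  # gamma-variate bolus: 50-frame trapezoid vs dense quadrature oracle
  f <- function(t) pwifet:::gamma_variate(t, 19, 3, 2.85, 10)
  coarse <- pwifet:::delta_r2_series(times50, f(times50), acq50)
  tt <- seq(times50[9], times50[50], length.out = 20000)
  dense <- pwifet:::trapz(tt, f(tt))
  expect_equal(cbv_integrate(coarse, window = 9:50), dense, tolerance = 0.005)
})

test_that("hotspot rCBV takes the top-k tumor mean over the reference ROI", {
  vals <- c(1, 1, 5, 5, 2, 2, 2, 2)
  tmask <- c(rep(TRUE, 4), rep(FALSE, 4))
  cmask <- !tmask
  res <- hotspot_rcbv(vals, tmask, cmask, k = 2)
  expect_equal(res$cbv_tumor, 5)
  expect_equal(res$cbv_reference, 2)
  expect_equal(res$rcbv_max, 2.5)

  uni <- hotspot_rcbv(rep(4, 40), rep(c(TRUE, FALSE), 20),
                      rep(c(FALSE, TRUE), 20), k = 10)
  expect_equal(uni$rcbv_max, 1)

  expect_error(hotspot_rcbv(vals, tmask, tmask, k = 2), "overlap")
  expect_error(hotspot_rcbv(vals, tmask, cmask, k = 5), "hotspot size")
  expect_error(hotspot_rcbv(-vals, tmask, cmask, k = 2), "non-physical")
})

test_that("full ROI pipeline recovers an engineered rCBV ratio", {
  sim <- gen_dsc_roi_curves(list(k1 = 2.90, k2 = 0.03), seed = 6)
  expect_equal(rcbv_roi(sim$tumor, sim$reference)$rcbv_max, 2.90,
               tolerance = 1e-6)
})
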