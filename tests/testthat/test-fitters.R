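test_that("rician_mean matches its limits and frozen Monte-Carlo value", {
  expect_equal(rician_mean(0, 1), sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(rician_mean(5, 1e-6), 5, tolerance = 1e-9)
  # frozen Monte-Carlo oracle (1e7 draws of |1 + g1 + i g2|): 1.5486
  expect_equal(rician_mean(1, 1), 1.5486, tolerance = 1e-4)
  expect_identical(rician_mean(c(0, 2), 0), c(0, 2))
  expect_error(rician_mean(-1, 1), "nonnegative")
  expect_error(rician_mean(1, -1), "nonnegative")
})

test_that("rician_mean is monotone in nu, always above nu, and smooth at the asymptotic switch", {
  nu <- seq(0, 10, by = 0.1)
  em <- rician_mean(nu, 1)
  expect_true(all(diff(em) > 0))
  expect_true(all(em > nu))
  # continuity across the closed-form / asymptotic boundary at nu/sigma = 40:
  # the jump between branches is below the next-order term ~ sigma^4/(8 nu^3)
  lo <- rician_mean(40 - 1e-7, 1)
  hi <- rician_mean(40 + 1e-7, 1)
  expect_lt(abs(hi - lo), 1e-5)
})

test_that("all four fitters recover noiseless curves to 1e-6 relative error", {
  maps <- random_truth_maps(12, seed = 11)
  ser <- image_series(decay_signal(maps$s0, maps$t, synth_sched), synth_sched)
  for (fitter in list(fit_loglin, fit_nlls, fit_nlls_bound, fit_nlls_rice)) {
    res <- fitter(ser)
    expect_lt(max(abs(res$map$t - maps$t) / maps$t), 1e-6)
    expect_lt(max(abs(res$map$s0 - maps$s0) / maps$s0), 1e-6)
    expect_true(all(res$map$t > 0))
  }
})

test_that("fit_loglin equals the closed-form two-point solution", {
  sch2 <- echo_schedule(c(0.4, 1))
  s1 <- 0.9; s2 <- 0.3
  ser <- image_series(array(c(s1, s2), c(1, 1, 2)), sch2)
  res <- fit_loglin(ser)
  t_closed <- (1 - 0.4) / log(s1 / s2)
  expect_equal(res$map$t[1, 1], t_closed, tolerance = 1e-12)
  expect_equal(res$map$s0[1, 1], s1 / exp(-0.4 / t_closed), tolerance = 1e-10)
})

test_that("fit_loglin tolerates nonpositive samples without crashing", {
  dat <- array(0.5, c(2, 2, 10))
  dat[1, 1, 8:10] <- 0  # hard zeros from magnitude floor subtraction
  ser <- image_series(dat, synth_sched)
  res <- fit_loglin(ser)
  expect_true(all(is.finite(res$map$s0)))
})

test_that("fit_nlls agrees with an independent LM implementation on noisy curves", {
  skip_if_not_installed("minpack.lm")
  maps <- random_truth_maps(4, seed = 21)
  rec <- synthesize_series_pair(maps$s0, maps$t, synth_sched,
                                sigma = 0.02, seed = 22)
  res <- fit_nlls(rec$series)
  eta <- synth_sched$eta
  for (i in 1:4) for (j in 1:4) {
    y <- rec$series$data[i, j, ]
    ll <- t2relax:::loglin_core(matrix(y, 1), eta)
    ref <- minpack.lm::nls.lm(
      par = c(s0 = unname(ll$s0), r = unname(ll$r)),
      fn = function(p) y - p[1] * exp(-eta * p[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14))
    pref <- coef(ref)
    expect_equal(res$map$s0[i, j], unname(pref[1]), tolerance = 1e-4)
    expect_equal(1 / res$map$t[i, j], unname(pref[2]), tolerance = 1e-4)
  }
})

test_that("bounded fit pins non-decaying curves at the slow-rate bound", {
  # flat noisy curve: no decay visible, so R hits its 0.25 floor (t = 4)
  dat <- array(rep(0.5, 10), c(1, 1, 10)) +
    array(with_seed_test(31, rnorm(10, 0, 0.01)), c(1, 1, 10))
  ser <- image_series(abs(dat), synth_sched)
  res <- fit_nlls_bound(ser)
  expect_equal(res$map$t[1, 1], 4, tolerance = 1e-6)
  # every output of a bounded fit satisfies the bounds
  rec <- synthesize_series_pair(matrix(runif(64), 8, 8),
                                matrix(runif(64, 0.045, 4), 8, 8),
                                synth_sched, sigma = 0.08, seed = 32)
  res2 <- fit_nlls_bound(rec$series)
  expect_true(all(res2$map$t >= 1 / 22 - 1e-9 & res2$map$t <= 4 + 1e-9))
  expect_true(all(res2$map$s0 >= 0 & res2$map$s0 <= 1000))
})

test_that("only the Rician fitter populates sigma_rice, and it recovers known noise", {
  maps <- random_truth_maps(10, seed = 41)
  rec <- synthesize_series_pair(maps$s0 * 0 + 0.8, maps$t, synth_sched,
                                sigma = 0.05, seed = 42)
  rice <- fit_nlls_rice(rec$series)
  expect_false(is.null(rice$map$sigma_rice))
  expect_null(fit_nlls(rec$series)$map$sigma_rice)
  expect_null(fit_loglin(rec$series)$map$sigma_rice)
  expect_null(fit_nlls_bound(rec$series)$map$sigma_rice)
  # the fitted noise level is in the right neighbourhood (median over pixels)
  expect_equal(median(rice$map$sigma_rice), 0.05, tolerance = 0.5)
})

test_that("low-SNR Rician bias is positive for NLLS and reduced by the Rician fitter", {
  # s0 low enough that the noise floor matters, as in low-SNR tissue
  # (about 6 dB, where T is still identifiable)
  n <- 50  # 2500 pixels
  s0 <- matrix(0.2, n, n); tt <- matrix(0.7, n, n)
  rec <- synthesize_series_pair(s0, tt, synth_sched, sigma = 0.05, seed = 51)
  nlls <- fit_nlls(rec$series)
  rice <- fit_nlls_rice(rec$series)
  err_nlls <- median(nlls$map$t - 0.7)
  err_rice <- median(rice$map$t - 0.7)
  expect_gt(err_nlls, 0)
  expect_lt(abs(err_rice), abs(err_nlls))
  # loglin overestimates T at low SNR too
  expect_gt(median(fit_loglin(rec$series)$map$t - 0.7), 0)
})

test_that("high-SNR NLLS bias vanishes (within 1 percent)", {
  n <- 40
  s0 <- matrix(1, n, n); tt <- matrix(0.7, n, n)
  rec <- synthesize_series_pair(s0, tt, synth_sched, sigma = 0.005, seed = 61)
  snr <- snr_db(1, 0.7, 0.005, synth_sched)
  expect_gt(snr, 35)
  res <- fit_nlls(rec$series)
  expect_lt(abs(median(res$map$t) - 0.7) / 0.7, 0.01)
})

test_that("estimate_sigma_map recovers the known noise level from residuals", {
  maps <- random_truth_maps(30, seed = 71)
  s0 <- maps$s0 * 0 + 0.9  # high SNR so the residual reflects sigma
  rec <- synthesize_series_pair(s0, maps$t, synth_sched, sigma = 0.05, seed = 72)
  fit <- fit_nlls(rec$series)
  sig <- estimate_sigma_map(rec$series, fit)
  expect_equal(dim(sig), c(30L, 30L))
  expect_lt(abs(median(sig) - 0.05) / 0.05, 0.15)
  # noiseless series -> zero residual everywhere
  clean <- image_series(decay_signal(s0, maps$t, synth_sched), synth_sched)
  fit0 <- fit_nlls(clean)
  expect_lt(max(estimate_sigma_map(clean, fit0)), 1e-7)
})
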