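test_that("echo schedule enforces the normalized-sampling invariants", {
  sch <- echo_schedule()
  expect_equal(sch$eta, (2:11) / 11)
  expect_equal(sch$n, 10L)
  expect_error(echo_schedule(c(0.5, 0.9)), "max\\(eta\\)")
  expect_error(echo_schedule(c(0, 0.5, 1)), "positive")
  expect_error(echo_schedule(c(0.5, 0.5, 1)), "ascending")
  phys <- echo_schedule(te_ms = seq(13.2, 145.2, by = 13.2))
  expect_equal(phys$eta[1], 0.0909, tolerance = 1e-3)
  expect_equal(phys$te_max_ms, 145.2)
})

test_that("decay_signal matches the closed-form exponential", {
  sch <- synth_sched
  # eta -> 0 limit is S0 by definition: check via the model at tiny eta
  s <- decay_signal(1, 0.7, echo_schedule(c(1e-9, 1)))
  expect_equal(s[1], 1.0, tolerance = 1e-6)
  # frozen closed-form values
  s <- decay_signal(0.5, 4, sch)
  expect_equal(s[10], 0.389400391536, tolerance = 1e-10)
  s <- decay_signal(1, 0.045, sch)
  expect_equal(s[10], 2.2336314e-10, tolerance = 1e-6)
  expect_error(decay_signal(1, 0, sch), "positive")
  expect_error(decay_signal(1, -1, sch), "positive")
})

test_that("decay_signal is monotone decreasing in eta and shapes correctly", {
  sch <- synth_sched
  s0 <- matrix(runif(36, 0.1, 1), 6, 6)
  tt <- matrix(runif(36, 0.1, 3), 6, 6)
  arr <- decay_signal(s0, tt, sch)
  expect_equal(dim(arr), c(6L, 6L, 10L))
  for (j in 2:10) expect_true(all(arr[, , j] < arr[, , j - 1]))
  expect_equal(arr[3, 4, 5], s0[3, 4] * exp(-sch$eta[5] / tt[3, 4]))
})

test_that("rician noise is zero-noise-exact, deterministic, and Rayleigh-consistent", {
  cl <- make_clean_series()
  out0 <- add_rician_noise(cl$series, noise_spec(0, seed = 1))
  expect_identical(out0$data, cl$series$data)
  a <- add_rician_noise(cl$series, noise_spec(0.05, seed = 42))
  b <- add_rician_noise(cl$series, noise_spec(0.05, seed = 42))
  expect_identical(a$data, b$data)
  c2 <- add_rician_noise(cl$series, noise_spec(0.05, seed = 43))
  expect_false(identical(a$data, c2$data))
  expect_error(noise_spec(-0.1), "nonnegative")
  # Monte-Carlo Rayleigh mean: zero signal, sigma = 0.05
  sig <- 0.05
  zero <- image_series(array(0, c(100, 100, 100)), echo_schedule(seq_len(100) / 100))
  noisy <- add_rician_noise(zero, noise_spec(sig, seed = 7))
  mc <- mean(noisy$data)
  expected <- sig * sqrt(pi / 2)
  se <- sig * sqrt(2 - pi / 2) / sqrt(1e6)
  expect_lt(abs(mc - expected), 3 * se)
})

test_that("rician noise mean matches the closed-form Rician mean across SNR", {
  # property: MC mean of |nu + complex noise| agrees with rician_mean
  sig <- 1
  n <- 1e6
  for (ratio in c(0, 0.5, 1, 2, 5)) {
    draws <- with_seed_test(100 + ratio * 10, {
      sqrt((ratio + rnorm(n, 0, sig))^2 + rnorm(n, 0, sig)^2)
    })
    se <- sd(draws) / sqrt(n)
    expect_lt(abs(mean(draws) - rician_mean(ratio, sig)), 3 * se)
  }
})

test_that("snr_db implements the L2-norm definition with its sentinels", {
  sch <- synth_sched
  # frozen: S0=1, T=4, sigma=0.001, N=10 -> 58.75 dB
  expect_equal(snr_db(1, 4, 0.001, sch), 58.75381, tolerance = 1e-5)
  # s0 = 0 pixels map to -Inf
  s0 <- matrix(c(0, 1, 0.5, 0), 2, 2)
  tt <- matrix(1, 2, 2)
  snr <- snr_db(s0, tt, 0.01, sch)
  expect_identical(snr[1, 1], -Inf)
  expect_identical(snr[2, 2], -Inf)
  expect_true(all(is.finite(snr[s0 > 0])))
  # doubling sigma drops SNR by exactly 20 log10(2)
  expect_equal(snr_db(1, 1, 0.02, sch) - snr_db(1, 1, 0.04, sch),
               20 * log10(2), tolerance = 1e-12)
  # monotone: decreasing in sigma, increasing in s0
  expect_gt(snr_db(1, 1, 0.01, sch), snr_db(1, 1, 0.011, sch))
  expect_gt(snr_db(0.9, 1, 0.01, sch), snr_db(0.8, 1, 0.01, sch))
  expect_error(snr_db(1, 1, 0, sch), "positive")
})

test_that("normalize_series scales to unit max and is idempotent", {
  cl <- make_clean_series()
  doubled <- image_series(cl$series$data * 2, cl$series$schedule)
  nrm <- normalize_series(doubled)
  expect_equal(max(nrm$data), 1.0)
  expect_true(nrm$normalized)
  expect_equal(nrm$data, doubled$data / max(doubled$data))
  again <- normalize_series(nrm)
  expect_identical(again$data, nrm$data)
  zero <- image_series(array(0, c(4, 4, 10)), synth_sched)
  expect_error(normalize_series(zero), "all-zero")
})

test_that("preprocess_series center-crops and discards the first echo", {
  sch11 <- echo_schedule((1:11) / 11)
  big <- image_series(array(runif(40 * 40 * 11), c(40, 40, 11)), sch11)
  out <- preprocess_series(big, crop = 16)
  expect_equal(dim(out$data), c(16L, 16L, 10L))
  expect_equal(out$schedule$eta, (2:11) / 11)
  # center crop with even excess: offset 12
  expect_equal(out$data[1, 1, 1], big$data[13, 13, 2])
  # crop is the identity at matching size; drop_first = FALSE is a no-op
  small <- image_series(array(runif(16 * 16 * 10), c(16, 16, 10)), synth_sched)
  idn <- preprocess_series(small, crop = 16, drop_first = FALSE)
  expect_identical(idn$data, small$data)
  expect_error(preprocess_series(small, crop = 32), "smaller than crop")
})
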