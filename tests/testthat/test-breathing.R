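test_that("micro-Doppler weights have the stated structure", {
  w_lit <- micro_doppler_weights(11, "literal")
  w_cen <- micro_doppler_weights(11, "centered")
  expect_equal(w_cen, -5:5)
  expect_equal(w_lit, w_cen + 1)
  expect_equal(w_cen[6], 0)        # zero-Doppler bin
  expect_equal(w_cen, -rev(w_cen)) # antisymmetric
  expect_error(micro_doppler_weights(10), "odd")
})

test_that("micro-Doppler extraction is linear and respects symmetry", {
  set.seed(1)
  d1 <- matrix(runif(11 * 8), 11, 8)
  d2 <- matrix(runif(11 * 8), 11, 8)
  s1 <- matrix_spectrogram(d1)
  s2 <- matrix_spectrogram(d2)
  s12 <- matrix_spectrogram(2 * d1 + 3 * d2)
  for (w in c("literal", "centered")) {
    psi1 <- extract_micro_doppler(s1, w)$psi
    psi2 <- extract_micro_doppler(s2, w)$psi
    psi12 <- extract_micro_doppler(s12, w)$psi
    expect_equal(psi12, 2 * psi1 + 3 * psi2, tolerance = 1e-12)
  }
  # all-zero spectrogram
  expect_true(all(extract_micro_doppler(
    matrix_spectrogram(matrix(0, 11, 5)))$psi == 0))
  # columns symmetric about zero Doppler vanish under centered weights
  sym <- matrix(rep(c(1, 2, 3, 4, 5, 9, 5, 4, 3, 2, 1), 4), 11, 4)
  expect_equal(extract_micro_doppler(matrix_spectrogram(sym),
                                     "centered")$psi,
               rep(0, 4), tolerance = 1e-12)
})

test_that("a simulated chest scene yields a breathing-rate spectral peak", {
  sc <- breathing_scene(chest = chest_motion_model(rate_bpm = 15), seed = 50)
  sp <- quiet_spectrogram(sc$ref, sc$surv, caf_config("breathing"))
  psi <- extract_micro_doppler(sp)
  est <- estimate_rate(sg_smooth(psi))
  expect_true(est$valid)
  expect_equal(est$rate_bpm, 15, tolerance = 1 / 15)  # within 1 bpm
  # dominant spectral peak at 0.25 Hz
  peak_hz <- est$spectrum$freq_hz[which.max(est$spectrum$magnitude)]
  expect_equal(peak_hz, 0.25, tolerance = 0.02)
})

test_that("SG smoothing reproduces polynomials exactly", {
  n <- 60
  tt <- seq(0, 11.8, by = 0.2)
  for (coef in list(c(2, 0, 0, 0), c(1, -2, 0.5, 0), c(0.3, 1, -0.2, 0.05))) {
    y <- coef[1] + coef[2] * tt + coef[3] * tt^2 + coef[4] * tt^3
    series <- structure(list(psi = y, frame_times_s = tt,
                             weights = NULL, smoothed = FALSE),
                        class = "micro_doppler_series")
    out <- sg_smooth(series, sg_filter_spec(window_s = 2, poly_order = 3))
    expect_lt(max(abs(out$psi - y)), 1e-9)
  }
  # constants pass unchanged (coefficients sum to 1)
  const <- structure(list(psi = rep(4.2, n), frame_times_s = tt,
                          weights = NULL, smoothed = FALSE),
                     class = "micro_doppler_series")
  expect_equal(sg_smooth(const)$psi, rep(4.2, n), tolerance = 1e-12)
})

test_that("SG smoothing halves the MSE of a noisy breathing tone", {
  set.seed(7)
  tt <- seq(0, 30, by = 0.2)
  clean <- sin(2 * pi * 0.25 * tt)
  noisy <- clean + rnorm(length(tt), sd = 1)  # 0 dB SNR
  series <- structure(list(psi = noisy, frame_times_s = tt,
                           weights = NULL, smoothed = FALSE),
                      class = "micro_doppler_series")
  sm <- sg_smooth(series)
  mse_raw <- mean((noisy - clean)^2)
  mse_sm <- mean((sm$psi - clean)^2)
  expect_lte(mse_sm, 0.5 * mse_raw)
  # smoothing moves the dominant peak by at most one FFT bin
  rate_raw <- estimate_rate(series)$rate_bpm
  rate_sm <- estimate_rate(sm)$rate_bpm
  expect_lt(abs(rate_raw - rate_sm), 0.5)
})

test_that("SG window must be shorter than the series", {
  short <- structure(list(psi = 1:5, frame_times_s = (1:5) * 0.2,
                          weights = NULL, smoothed = FALSE),
                     class = "micro_doppler_series")
  expect_error(sg_smooth(short, sg_filter_spec(window_s = 2)), "shorter")
})

test_that("rate estimation handles pure tones and degenerate input", {
  tt <- seq(0, 60, by = 0.2)
  tone <- structure(list(psi = sin(2 * pi * 0.25 * tt), frame_times_s = tt,
                         weights = NULL, smoothed = FALSE),
                    class = "micro_doppler_series")
  est <- estimate_rate(tone)
  expect_true(est$valid)
  expect_equal(est$rate_bpm, 15, tolerance = 0.05)

  dc <- structure(list(psi = rep(3, 301), frame_times_s = tt,
                       weights = NULL, smoothed = FALSE),
                  class = "micro_doppler_series")
  expect_false(estimate_rate(dc)$valid)
  expect_true(is.na(estimate_rate(dc)$rate_bpm))
})

test_that("belt evaluation recovers identity and anticorrelation", {
  tt <- seq(0, 30, by = 0.2)
  psi <- sin(2 * pi * 0.25 * tt) * 3 + 0.5
  series <- structure(list(psi = psi, frame_times_s = tt,
                           weights = NULL, smoothed = FALSE),
                      class = "micro_doppler_series")
  same <- data.frame(time_s = tt, value = psi)
  ev <- evaluate_against_reference(series, same)
  expect_equal(ev$r, 1, tolerance = 1e-12)
  expect_equal(ev$mse, 0, tolerance = 1e-12)
  flipped <- data.frame(time_s = tt, value = -psi)
  expect_equal(evaluate_against_reference(series, flipped)$r, -1,
               tolerance = 1e-12)
  apart <- data.frame(time_s = tt + 100, value = psi)
  expect_error(evaluate_against_reference(series, apart), "overlap")
})

test_that("a default facing-geometry scene correlates with the belt", {
  sc <- breathing_scene(seed = 51)
  sp <- quiet_spectrogram(sc$ref, sc$surv, caf_config("breathing"))
  sm <- sg_smooth(extract_micro_doppler(sp))
  ev <- evaluate_against_reference(sm, sc$truth$belt)
  expect_gt(ev$r, 0.8)
})
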