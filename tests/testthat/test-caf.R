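test_that("self-ambiguity peaks at the origin and matches the signal energy", {
  ref <- test_source(1, seed = 10)
  cfg <- caf_config("activity", max_delay_s = 10 / test_fs)
  self <- suppressWarnings(self_ambiguity(ref, cfg))
  pk <- arrayInd(which.max(Mod(self$values)), dim(self$values))
  expect_equal(self$delay_axis_s[pk[1]], 0)
  expect_equal(self$doppler_axis_hz[pk[2]], 0)
  # zero-Doppler row dominates
  i0 <- which.min(abs(self$doppler_axis_hz))
  expect_equal(max(Mod(self$values)), max(Mod(self$values[, i0])))
  # delay-0 peak equals the signal energy within 1%
  n_use <- ncol(self$values) * (round(test_fs) %/% ncol(self$values))
  energy <- sum(Mod(ref$samples[seq_len(n_use)])^2)
  expect_equal(Mod(self$values[1, i0]), energy, tolerance = 0.01)
})

test_that("self-ambiguity of a real-envelope source is Doppler symmetric", {
  spec <- scene_source_spec(test_fs)
  # binary +-1 chips give a real envelope
  ref <- generate_dsss_source(spec, 1, test_fs, seed = 1,
                              chip_phases = rep(c(0, pi), 200))
  self <- suppressWarnings(self_ambiguity(ref, caf_config("activity")))
  mags <- Mod(self$values[1, ])
  expect_equal(mags, rev(mags), tolerance = 1e-9)
})

test_that("batched CAF equals the direct double-loop oracle", {
  ref <- test_source(1, seed = 11)        # 2000 samples
  surv <- shifted_copy(ref, delay_samples = 12, doppler_hz = 7, gain = 0.7)
  cfg <- caf_config("activity", max_delay_s = 20 / test_fs)
  caf <- suppressWarnings(compute_caf(ref, surv, cfg))
  n_use <- (round(test_fs) %/% cfg$num_batches) * cfg$num_batches
  oracle <- caf_direct_oracle(ref$samples[seq_len(n_use)],
                              surv$samples[seq_len(n_use)],
                              0:20, caf$doppler_axis_hz, test_fs)
  expect_lt(max(Mod(caf$values - oracle)) / max(Mod(oracle)), 1e-6)

  pk <- arrayInd(which.max(Mod(caf$values)), dim(caf$values))
  expect_equal(pk[1] - 1, 12)
  expect_lte(abs(caf$doppler_axis_hz[pk[2]] - 7), doppler_bin_hz(cfg))
})

test_that("CAF peak localization holds across seeded noisy scenes", {
  cfg <- caf_config("activity", max_delay_s = 16 / test_fs)
  n_bad <- 0
  for (s in 1:25) {
    set.seed(s)
    d_true <- sample(0:16, 1)
    f_true <- sample(-50:50, 1)
    ref <- test_source(1, seed = 100 + s)
    surv <- shifted_copy(ref, d_true, f_true, gain = 1)
    p <- mean(Mod(surv$samples)^2)
    noisy <- simulate_scene(ref, list(), list(),
                            noise_power = snr_to_noise_power(p, 10),
                            seed = 200 + s)
    surv$samples <- surv$samples + noisy$samples
    caf <- suppressWarnings(compute_caf(ref, surv, cfg))
    pk <- arrayInd(which.max(Mod(caf$values)), dim(caf$values))
    if (abs(pk[1] - 1 - d_true) > 1 ||
        abs(caf$doppler_axis_hz[pk[2]] - f_true) > doppler_bin_hz(cfg)) {
      n_bad <- n_bad + 1
    }
  }
  expect_equal(n_bad, 0)
})

test_that("configuration invariants and errors are enforced", {
  cfg <- caf_config("activity")
  expect_equal(cfg$batch_len_s * cfg$num_batches, cfg$integration_time_s)
  expect_equal(doppler_bin_hz(cfg), 1)
  expect_equal(doppler_bin_hz(caf_config("breathing")), 0.5)
  # breathing mode resolves finer Doppler than activity mode
  expect_lt(doppler_bin_hz(caf_config("breathing")),
            doppler_bin_hz(caf_config("activity")))
  expect_error(caf_config("activity", num_batches = 10), "odd")
  expect_error(caf_config("activity", integration_time_s = -1), "positive")

  ref <- test_source(0.25, seed = 1)
  expect_error(compute_caf(ref, ref, caf_config("activity")), "exceeds")
  surv_other <- baseband_recording(ref$samples, 4000, ref$carrier_freq_hz,
                                   "surveillance")
  expect_error(compute_caf(ref, surv_other, cfg), "sample rate")
})

test_that("range resolution is c/2B", {
  cfg <- caf_config("activity", bandwidth_hz = 2e7)
  expect_equal(range_resolution_m(cfg), 7.5, tolerance = 1e-3)
})
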