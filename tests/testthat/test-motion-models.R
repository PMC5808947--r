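test_that("chest Doppler profile has the breathing period and peak", {
  chest <- chest_motion_model(rate_bpm = 15)
  path <- chest_motion_path(chest, f_c = 9.15e8)
  t <- seq(0, 8, by = 0.001)
  fd <- path$doppler_profile(t)
  # sign alternates with period 60/15 = 4 s
  crossings <- which(diff(sign(fd)) != 0)
  expect_equal(mean(diff(t[crossings])), 2.0, tolerance = 0.01)

  # peak Doppler in Hz: finite-difference oracle on the two-way path length
  disp <- chest_displacement(chest, t)
  lambda <- pdsense:::SPEED_OF_LIGHT / 9.15e8
  inst_hz_fd <- diff(2 * disp) / 0.001 / lambda
  peak_hz <- max(abs(fd * 9.15e8))
  expect_equal(peak_hz, max(abs(inst_hz_fd)), tolerance = 1e-4)
  # closed form: 2 g A omega f_c / c
  expect_equal(peak_hz,
               2 * 1 * 0.005 * 2 * pi * 15 / 60 * 9.15e8 /
                 pdsense:::SPEED_OF_LIGHT,
               tolerance = 1e-6)
})

test_that("chest model invariants are enforced", {
  expect_error(chest_motion_model(orientation_gain = 0), "orientation_gain")
  expect_error(chest_motion_model(rate_bpm = 0), "rate_bpm")
  expect_error(chest_motion_model(displacement_amp_m = 0), "displacement")
  expect_error(chest_motion_path(chest_motion_model(), range_m = 0), "range_m")
})

test_that("activity paths convert velocity to Doppler", {
  still <- activity_trajectory("walking")
  still$radial_velocity_profile <- function(t) numeric(length(t))
  p0 <- activity_path(still)
  expect_true(all(p0$doppler_profile(seq(0, 4, 0.1)) == 0))

  # constant 1 m/s: 2 v f_c / c ~ 6.1 Hz at 915 MHz
  traj <- activity_trajectory("walking")
  traj$radial_velocity_profile <- function(t) rep(1, length(t))
  p1 <- activity_path(traj, f_c = 9.15e8)
  expect_equal(p1$doppler_profile(1) * 9.15e8,
               2 * 9.15e8 / pdsense:::SPEED_OF_LIGHT,
               tolerance = 1e-9)
  expect_equal(round(p1$doppler_profile(1) * 9.15e8, 1), 6.1)

  expect_error(activity_trajectory("swimming"), "unknown activity")
})

test_that("sustained and transient activities have the stated durations", {
  t <- seq(0, 4, by = 0.005)
  active_span <- function(label) {
    v <- activity_trajectory(label)$radial_velocity_profile(t)
    on <- abs(v) > 0.05 * max(abs(v))
    diff(range(t[on]))
  }
  for (label in c("walking", "running", "jumping")) {
    expect_gte(active_span(label), 1)
  }
  for (label in c("standing", "sitting", "turning")) {
    expect_lt(active_span(label), 1)
  }
  # jumping has the widest Doppler excursion
  peaks <- vapply(pdsense:::ACTIVITY_LABELS, function(l) {
    max(abs(activity_trajectory(l)$radial_velocity_profile(t)))
  }, numeric(1))
  expect_equal(names(which.max(peaks)), "jumping")
})

test_that("the six activities have pairwise-distinguishable mean spectra", {
  cfg <- caf_config("activity")
  mean_specs <- lapply(pdsense:::ACTIVITY_LABELS, function(label) {
    sc <- activity_scene(label, seed = 21)
    sp <- quiet_spectrogram(sc$ref, sc$surv, cfg)
    m <- rowMeans(sp$D)
    m / sqrt(sum(m^2))
  })
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_lt(sum(mean_specs[[i]] * mean_specs[[j]]), 0.98,
                label = sprintf("mean-spectrum correlation %s vs %s",
                                pdsense:::ACTIVITY_LABELS[i],
                                pdsense:::ACTIVITY_LABELS[j]))
    }
  }
})

test_that("corpus design produces the full labelled grid", {
  co <- generate_experiment_corpus(seed = 5)
  expect_equal(nrow(co$manifest), 180)
  expect_equal(sort(unique(co$manifest$label)), sort(pdsense:::ACTIVITY_LABELS))
  expect_true(all(table(co$manifest$label, co$manifest$subject) == 10))

  co2 <- generate_experiment_corpus(activities = c("walking", "running"),
                                    repetitions = 1, subjects = 1, seed = 5)
  expect_equal(nrow(co2$manifest), 2)

  again <- generate_experiment_corpus(seed = 5)
  expect_identical(co$manifest, again$manifest)
  other <- generate_experiment_corpus(seed = 6)
  expect_false(identical(co$manifest, other$manifest))
})

test_that("corpus scenes are reproducible from the manifest", {
  co <- generate_experiment_corpus(repetitions = 1, subjects = 1, seed = 3)
  a <- corpus_scene(co, 2)
  b <- corpus_scene(co, 2)
  expect_identical(a$surv$samples, b$surv$samples)
  expect_equal(a$truth$label, co$manifest$label[2])
})
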