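test_that("windowing splits, pads and preserves energy", {
  d <- matrix(seq_len(11 * 8), 11, 8)
  sp <- matrix_spectrogram(d)  # 8 frames at 1 s hop
  w2 <- window_spectrogram(sp, 4)
  expect_length(w2, 2)
  expect_equal(w2[[1]]$D, d[, 1:4])
  w1 <- window_spectrogram(matrix_spectrogram(d[, 1:4]), 4)
  expect_length(w1, 1)
  expect_equal(w1[[1]]$D, d[, 1:4])
  # 10 frames -> 3 windows, third zero-padded; energy of full windows kept
  d10 <- matrix(runif(11 * 10), 11, 10)
  w3 <- window_spectrogram(matrix_spectrogram(d10), 4)
  expect_length(w3, 3)
  expect_equal(sum(w3[[1]]$D^2) + sum(w3[[2]]$D^2), sum(d10[, 1:8]^2))
  expect_equal(ncol(w3[[3]]$D), 4)
  expect_equal(w3[[3]]$D[, 3:4], matrix(0, 11, 2))
  expect_error(window_spectrogram(matrix_spectrogram(d[, 1:2, drop = FALSE]), 4),
               "shorter")
})

test_that("SVD features match rank structure and an eigen oracle", {
  u <- rnorm(11); u <- u / sqrt(sum(u^2))
  v <- rnorm(6); v <- v / sqrt(sum(v^2))
  sv <- svd_features(u %*% t(v), r = 5)
  expect_equal(sv, c(1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_equal(svd_features(matrix(0, 4, 4), r = 3), c(0, 0, 0))

  set.seed(3)
  d <- matrix(rnorm(32 * 32), 32, 32)
  s <- svd_features(d, r = 32)
  eig <- sort(eigen(d %*% t(d), symmetric = TRUE)$values, decreasing = TRUE)
  expect_equal(s^2, eig, tolerance = 1e-8)
  # determinism
  expect_identical(svd_features(d, r = 10), svd_features(d, r = 10))
})

test_that("PCA respects energy fraction, completeness and an oracle", {
  set.seed(4)
  wins <- lapply(1:6, function(i) matrix(rnorm(9 * 5), 9, 5))
  # complete basis preserves total variance
  b_full <- pca_basis(wins, pca_spec(energy_fraction = 1, max_components = 9))
  frames <- do.call(cbind, wins)
  centered <- frames - rowMeans(frames)
  proj <- crossprod(b_full$rotation, centered)
  expect_equal(sum(proj^2), sum(centered^2), tolerance = 1e-8)

  # rank-1 data needs one component for >= 90% energy
  u <- rnorm(9)
  wins1 <- lapply(1:4, function(i) u %*% t(rnorm(5)))
  b1 <- pca_basis(wins1)
  expect_equal(b1$L, 1)

  # projected variances equal covariance eigenvalues (brute-force oracle)
  b <- pca_basis(wins, pca_spec(energy_fraction = 1, max_components = 4))
  cov_oracle <- stats::cov(t(frames))
  eig_oracle <- sort(eigen(cov_oracle, symmetric = TRUE)$values,
                     decreasing = TRUE)
  proj_var <- apply(crossprod(b$rotation, centered), 1, stats::var)
  expect_equal(sort(proj_var, decreasing = TRUE), eig_oracle[1:4],
               tolerance = 1e-8)
})

test_that("the PCA basis is a function of the training windows only", {
  set.seed(5)
  train <- lapply(1:5, function(i) matrix(rnorm(9 * 4), 9, 4))
  test_w <- lapply(1:3, function(i) matrix(rnorm(9 * 4), 9, 4))
  b1 <- pca_basis(train)
  f1 <- extract_features(test_w, "PCA", basis = b1)
  # perturbing the test windows must not change the basis or training-side
  # statistics
  test_perturbed <- lapply(test_w, function(m) m + 100)
  b2 <- pca_basis(train)
  expect_identical(b1$rotation, b2$rotation)
  f2 <- extract_features(test_perturbed, "PCA", basis = b2)
  expect_false(identical(f1, f2))  # features do respond to their own input
  expect_error(pca_features(matrix(0, 7, 4), b1), "does not match")
})

test_that("physical features summarize tones and empty windows", {
  zero <- matrix_spectrogram(matrix(0, 11, 4))
  expect_equal(unname(physical_features(zero)), c(0, 0, 0, 0, 0, 1))

  tone <- matrix(0, 11, 4)
  tone[which(matrix_spectrogram(tone)$doppler_axis_hz == 3), ] <- 2
  sp <- matrix_spectrogram(tone)
  pf <- physical_features(sp)
  expect_equal(unname(pf["active_duration_s"]), 4)     # whole window
  expect_equal(unname(pf["doppler_bandwidth_hz"]), 1)  # one bin
  expect_equal(unname(pf["peak_pos_doppler_hz"]), 3)
  expect_equal(unname(pf["peak_neg_doppler_hz"]), 0)
  expect_gt(unname(pf["pos_neg_energy_ratio"]), 1e6)
})

test_that("walking outlasts sitting in the duration feature", {
  cfg <- caf_config("activity")
  longer <- 0
  n_pairs <- 6
  for (s in seq_len(n_pairs)) {
    walk <- activity_scene("walking", seed = 700 + s)
    sit <- activity_scene("sitting", seed = 800 + s)
    w_walk <- window_spectrogram(
      quiet_spectrogram(walk$ref, walk$surv, cfg), 4)[[1]]
    w_sit <- window_spectrogram(
      quiet_spectrogram(sit$ref, sit$surv, cfg), 4)[[1]]
    if (physical_features(w_walk)["active_duration_s"] >
        physical_features(w_sit)["active_duration_s"]) {
      longer <- longer + 1
    }
  }
  expect_equal(longer, n_pairs)
})

test_that("feature extraction is deterministic per window", {
  sc <- activity_scene("jumping", seed = 900)
  w <- window_spectrogram(quiet_spectrogram(sc$ref, sc$surv,
                                            caf_config("activity")), 4)[[1]]
  basis <- pca_basis(list(w))
  for (m in c("SVD", "PF")) {
    expect_identical(extract_features(list(w), m),
                     extract_features(list(w), m))
  }
  expect_identical(extract_features(list(w), "PCA", basis = basis),
                   extract_features(list(w), "PCA", basis = basis))
})
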