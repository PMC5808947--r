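# Well-separated Gaussian clusters: quick separable stand-in for radar
# feature vectors.
gaussian_features <- function(n_per_class, classes = 6, dim = 8, sep = 10,
                              seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(classes * dim), classes, dim) * sep
  x <- do.call(rbind, lapply(seq_len(classes), function(k) {
    matrix(rnorm(n_per_class * dim), n_per_class, dim) +
      matrix(centers[k, ], n_per_class, dim, byrow = TRUE)
  }))
  list(x = x, y = rep(letters[seq_len(classes)], each = n_per_class))
}

test_that("the ensemble holds one classifier per class pair", {
  g6 <- gaussian_features(4, classes = 6)
  m6 <- train_ovo_svm(g6$x, g6$y)
  expect_length(m6$classifiers, 15)
  g2 <- gaussian_features(4, classes = 2)
  m2 <- train_ovo_svm(g2$x, g2$y)
  expect_length(m2$classifiers, 1)
  g1 <- gaussian_features(4, classes = 1)
  expect_error(train_ovo_svm(g1$x, g1$y), "two classes")
})

test_that("separable clusters are classified perfectly, votes sum to 15", {
  g <- gaussian_features(6, classes = 6)
  m <- train_ovo_svm(g$x, g$y)
  pred <- predict(m, g$x)
  expect_equal(as.character(pred), g$y)  # training points recovered
  # every sample receives one vote from each of the 15 pairwise classifiers
  xs <- sweep(sweep(g$x, 2, m$center), 2, m$scale, "/")
  total_votes <- 0
  for (i in seq_along(m$classifiers)) {
    total_votes <- total_votes + length(predict(m$classifiers[[i]], xs))
  }
  expect_equal(total_votes, nrow(g$x) * 15)
})

test_that("a unanimous vote wins regardless of margins", {
  # place a point deep inside one cluster: all pairwise classifiers
  # involving that class vote for it
  g <- gaussian_features(6, classes = 4, sep = 20)
  m <- train_ovo_svm(g$x, g$y)
  probe <- g$x[1, , drop = FALSE] # deep in class "a"
  expect_equal(as.character(predict(m, probe)), "a")
})

test_that("feature-length mismatch is rejected", {
  g <- gaussian_features(4, classes = 3)
  m <- train_ovo_svm(g$x, g$y)
  expect_error(predict(m, g$x[, 1:3]), "feature length")
})

test_that("confusion matrices have consistent counts", {
  truth <- c("a", "a", "b", "b", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "a")
  cm <- confusion_matrix(truth, pred)
  expect_equal(rowSums(cm$counts), c(a = 2, b = 2, c = 2))
  expect_equal(cm$accuracy, 4 / 6)
  expect_equal(unname(cm$per_class_accuracy), c(0.5, 1, 0.5))
})

test_that("train==test on a separable corpus gives accuracy 1", {
  g <- gaussian_features(8, classes = 4)
  wins <- lapply(seq_len(nrow(g$x)), function(i) {
    matrix_spectrogram(matrix(abs(g$x[i, ]), ncol = 1))
  })
  # bypass radar features: classify the raw vectors through the protocol
  m <- train_ovo_svm(g$x, g$y)
  expect_equal(mean(predict(m, g$x) == g$y), 1)
})

test_that("shuffled labels collapse accuracy to chance", {
  g <- gaussian_features(12, classes = 6)
  set.seed(42)
  y_shuf <- sample(g$y)
  accs <- numeric(5)
  for (i in 1:5) {
    set.seed(i)
    idx <- sample(nrow(g$x))
    tr <- idx[1:48]
    te <- idx[49:72]
    m <- train_ovo_svm(g$x[tr, ], y_shuf[tr])
    accs[i] <- mean(predict(m, g$x[te, ]) == y_shuf[te])
  }
  # chance level 1/6; binomial 3 sigma over 5 x 24 trials ~ 0.10
  expect_lt(abs(mean(accs) - 1 / 6), 0.12)
})

test_that("split evaluation is leakage-free and reports sane accuracy", {
  co <- generate_experiment_corpus(repetitions = 4, seed = 77)
  cw <- suppressWarnings(corpus_windows(co))
  res <- evaluate_splits(cw$windows, cw$labels, n_train_per_class = 8,
                         n_test_per_class = 4, repeats = 3,
                         method = "PCA", seed = 1)
  expect_gte(res$accuracy, 0.8)
  expect_equal(sum(res$confusion$counts), 6 * 4)
  expect_equal(unname(rowSums(res$confusion$counts)), rep(4, 6))
  expect_error(
    evaluate_splits(cw$windows, cw$labels, n_train_per_class = 12,
                    method = "PCA"),
    "not enough")
})

test_that("inter-subject evaluation yields one entry per subject", {
  co <- generate_experiment_corpus(repetitions = 3, seed = 78)
  cw <- suppressWarnings(corpus_windows(co))
  isj <- evaluate_inter_subject(cw$windows, cw$labels, cw$subjects,
                                method = "PF")
  expect_equal(nrow(isj$per_subject), 3)
  expect_equal(sort(isj$per_subject$subject), c("1", "2", "3"))
  expect_true(all(isj$per_subject$accuracy >= 0 &
                    isj$per_subject$accuracy <= 1))
  expect_error(evaluate_inter_subject(cw$windows[1:6], cw$labels[1:6],
                                      rep("1", 6)),
               "two subjects")
})
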