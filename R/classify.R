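#' Train a one-against-one SVM ensemble
#'
#' Builds one binary soft-margin SVM (libsvm via \pkg{e1071}) for every
#' unordered pair of classes -- `K (K - 1) / 2` classifiers, 15 for the six
#' monitored activities -- on features standardized by the training-set
#' statistics.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (character or factor).
#' @param C Soft-margin penalty parameter (default 1).
#' @param kernel `"linear"` (default; the pairwise subproblems are small) or
#'   `"radial"`.
#' @return An object of class `ovo_svm`: the pairwise classifiers, class
#'   levels, penalty, kernel and standardization constants.
#' @export
train_ovo_svm <- function(x, y, C = 1, kernel = c("linear", "radial")) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(y)
  classes <- levels(y)
  if (length(classes) < 2) {
    stop("need at least two classes to train a classifier", call. = FALSE)
  }
  counts <- table(y)
  if (any(counts < 2)) {
    stop("need at least two samples per class", call. = FALSE)
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, "/")

  pairs <- utils::combn(classes, 2, simplify = FALSE)
  classifiers <- lapply(pairs, function(p) {
    idx <- y %in% p
    e1071::svm(xs[idx, , drop = FALSE], droplevels(y[idx]),
               kernel = kernel, cost = C, scale = FALSE,
               type = "C-classification")
  })
  structure(
    list(classifiers = classifiers, pairs = pairs, classes = classes,
         C = C, kernel = kernel, center = center, scale = scale_,
         n_features = ncol(x)),
    class = "ovo_svm"
  )
}

#' @export
print.ovo_svm <- function(x, ...) {
  cat(sprintf("<ovo_svm: %d classes, %d pairwise classifiers (%s kernel, C = %g)>\n",
              length(x$classes), length(x$classifiers), x$kernel, x$C))
  invisible(x)
}

#' Predict activity labels by pairwise majority vote
#'
#' Every pairwise classifier casts one vote per sample; the predicted class
#' is the one with the most votes. Ties are broken by the largest summed
#' signed decision margin accumulated over the pairwise classifiers.
#'
#' @param object An [train_ovo_svm()] model.
#' @param newdata Feature matrix with the training feature length.
#' @param ... Unused.
#' @return Factor of predicted labels with the model's class levels.
#' @export
predict.ovo_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    stop("feature length (", ncol(newdata), ") does not match the model (",
         object$n_features, ")", call. = FALSE)
  }
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  n <- nrow(xs)
  k <- length(object$classes)
  votes <- matrix(0L, n, k, dimnames = list(NULL, object$classes))
  margin <- matrix(0, n, k, dimnames = list(NULL, object$classes))
  for (i in seq_along(object$classifiers)) {
    clf <- object$classifiers[[i]]
    p <- object$pairs[[i]]
    pred <- stats::predict(clf, xs, decision.values = TRUE)
    dvm <- attr(pred, "decision.values")
    dv <- as.numeric(dvm)
    # the decision value is signed toward the first class of the "A/B" pair
    pair_names <- strsplit(colnames(dvm)[1], "/", fixed = TRUE)[[1]]
    first <- pair_names[1]
    second <- pair_names[2]
    vote_col <- match(as.character(pred), object$classes)
    idx <- cbind(seq_len(n), vote_col)
    votes[idx] <- votes[idx] + 1L
    margin[, first] <- margin[, first] + dv
    margin[, second] <- margin[, second] - dv
  }
  winners <- vapply(seq_len(n), function(i) {
    best <- which(votes[i, ] == max(votes[i, ]))
    if (length(best) > 1) {
      best <- best[which.max(margin[i, best])]
    }
    object$classes[best]
  }, character(1))
  factor(winners, levels = object$classes)
}

#' Confusion matrix with per-class and overall accuracy
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param classes Class levels (default: union of both).
#' @return An object of class `confusion_matrix`: `counts[true, predicted]`,
#'   `per_class_accuracy`, `accuracy`.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- sort(union(unique(as.character(truth)),
                          unique(as.character(predicted))))
  }
  truth <- factor(as.character(truth), levels = classes)
  predicted <- factor(as.character(predicted), levels = classes)
  counts <- table(true = truth, predicted = predicted)
  rs <- rowSums(counts)
  per_class <- ifelse(rs > 0, diag(counts) / rs, NA_real_)
  structure(
    list(counts = unclass(counts),
         per_class_accuracy = per_class,
         accuracy = sum(diag(counts)) / sum(counts)),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix: overall accuracy %.3f>\n", x$accuracy))
  print(x$counts)
  invisible(x)
}

# Compute the feature matrix for one split, training the PCA basis (and any
# other training-dependent statistics) on the training rows only.
split_features <- function(windows, train_idx, test_idx, method,
                           pca = pca_spec(), r = 10) {
  basis <- if (method == "PCA") pca_basis(windows[train_idx], pca) else NULL
  list(
    train = extract_features(windows[train_idx], method, basis = basis, r = r),
    test = extract_features(windows[test_idx], method, basis = basis, r = r)
  )
}

#' Repeated stratified split evaluation
#'
#' The classification protocol of the activity study: per class,
#' `n_train_per_class` windows are drawn for training and
#' `n_test_per_class` (or all remaining) for testing; the draw is repeated
#' `repeats` times and the mean confusion matrix and accuracy are reported.
#' For PCA features the basis is retrained inside every split on its
#' training windows only.
#'
#' @param windows List of `doppler_spectrogram` windows.
#' @param labels Class label per window.
#' @param n_train_per_class Training windows per class (default 20).
#' @param n_test_per_class Test windows per class; `NULL` = all remaining.
#' @param repeats Number of random splits (default 10).
#' @param method Feature method, `"SVD"`, `"PCA"` or `"PF"`.
#' @param seed Integer seed for the split draws.
#' @param C,kernel SVM parameters, see [train_ovo_svm()].
#' @param pca A [pca_spec()] for `method = "PCA"`.
#' @param r Singular-value count for `method = "SVD"`.
#' @return A list: `accuracy` (mean over repeats), `accuracy_sd`,
#'   `per_repeat`, `confusion` (mean counts [confusion_matrix()]).
#' @export
evaluate_splits <- function(windows, labels, n_train_per_class = 20,
                            n_test_per_class = 10, repeats = 10,
                            method = c("SVD", "PCA", "PF"), seed = 1L,
                            C = 1, kernel = "linear", pca = pca_spec(),
                            r = 10) {
  method <- match.arg(method)
  labels <- factor(labels)
  classes <- levels(labels)
  by_class <- split(seq_along(labels), labels)
  min_avail <- min(lengths(by_class))
  if (min_avail < n_train_per_class + 1) {
    stop("not enough windows per class for the requested split",
         call. = FALSE)
  }
  rng <- local_rng(seed)
  accs <- numeric(repeats)
  counts_sum <- NULL
  for (rep_i in seq_len(repeats)) {
    train_idx <- integer(0)
    test_idx <- integer(0)
    for (cl in classes) {
      pool <- by_class[[cl]]
      tr <- rng(function() sample(pool, n_train_per_class))
      rest <- setdiff(pool, tr)
      te <- if (is.null(n_test_per_class)) {
        rest
      } else {
        rng(function() sample(rest, min(n_test_per_class, length(rest))))
      }
      train_idx <- c(train_idx, tr)
      test_idx <- c(test_idx, te)
    }
    feats <- split_features(windows, train_idx, test_idx, method, pca, r)
    model <- train_ovo_svm(feats$train, labels[train_idx], C = C,
                           kernel = kernel)
    pred <- predict(model, feats$test)
    cm <- confusion_matrix(labels[test_idx], pred, classes)
    accs[rep_i] <- cm$accuracy
    counts_sum <- if (is.null(counts_sum)) cm$counts else counts_sum + cm$counts
  }
  mean_counts <- counts_sum / repeats
  rs <- rowSums(mean_counts)
  list(
    accuracy = mean(accs),
    accuracy_sd = stats::sd(accs),
    per_repeat = accs,
    confusion = structure(
      list(counts = mean_counts,
           per_class_accuracy = ifelse(rs > 0, diag(mean_counts) / rs,
                                       NA_real_),
           accuracy = sum(diag(mean_counts)) / sum(mean_counts)),
      class = "confusion_matrix"
    ),
    method = method,
    n_train_per_class = n_train_per_class
  )
}

#' Accuracy as a function of training-set size
#'
#' @inheritParams evaluate_splits
#' @param sizes Training windows per class to evaluate.
#' @return Data frame with columns `n_train_per_class`, `accuracy`,
#'   `accuracy_sd`.
#' @export
accuracy_vs_train_size <- function(windows, labels,
                                   sizes = c(10, 15, 20, 25),
                                   n_test_per_class = NULL, repeats = 10,
                                   method = "SVD", seed = 1L, ...) {
  rows <- lapply(sizes, function(s) {
    res <- evaluate_splits(windows, labels, n_train_per_class = s,
                           n_test_per_class = n_test_per_class,
                           repeats = repeats, method = method,
                           seed = fold_seed(seed, s), ...)
    data.frame(n_train_per_class = s, accuracy = res$accuracy,
               accuracy_sd = res$accuracy_sd)
  })
  do.call(rbind, rows)
}

#' Inter-subject (leave-one-subject-out) evaluation
#'
#' For every subject, trains on all other subjects' windows and tests on the
#' held-out subject -- classification of an unknown person from known
#' people.
#'
#' @inheritParams evaluate_splits
#' @param subjects Subject identifier per window.
#' @return A list: `per_subject` data frame (`subject`, `accuracy`, `n_test`)
#'   and `accuracy` (mean over subjects).
#' @export
evaluate_inter_subject <- function(windows, labels, subjects,
                                   method = c("SVD", "PCA", "PF"),
                                   C = 1, kernel = "linear",
                                   pca = pca_spec(), r = 10) {
  method <- match.arg(method)
  labels <- factor(labels)
  subjects <- as.character(subjects)
  uniq <- sort(unique(subjects))
  if (length(uniq) < 2) {
    stop("inter-subject evaluation needs at least two subjects",
         call. = FALSE)
  }
  rows <- lapply(uniq, function(s) {
    test_idx <- which(subjects == s)
    train_idx <- which(subjects != s)
    feats <- split_features(windows, train_idx, test_idx, method, pca, r)
    model <- train_ovo_svm(feats$train, labels[train_idx], C = C,
                           kernel = kernel)
    pred <- predict(model, feats$test)
    data.frame(subject = s,
               accuracy = mean(pred == labels[test_idx]),
               n_test = length(test_idx),
               stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject, accuracy = mean(per_subject$accuracy))
}

#' Spectrogram windows of a whole corpus
#'
#' Materializes every corpus recording, computes its CLEANed activity-mode
#' spectrogram and splits it into classification windows.
#'
#' @param corpus An [generate_experiment_corpus()] object.
#' @param cfg A [caf_config()] (default activity mode).
#' @param window_s Classification window length in seconds.
#' @param progress Print a dot every 20 recordings.
#' @return A list with `windows` (list of `doppler_spectrogram`s), `labels`,
#'   `subjects` (one entry per window).
#' @export
corpus_windows <- function(corpus, cfg = caf_config("activity"),
                           window_s = 4, progress = FALSE) {
  stopifnot(inherits(corpus, "activity_corpus"))
  windows <- list()
  labels <- character(0)
  subjects <- character(0)
  for (i in seq_len(nrow(corpus$manifest))) {
    sc <- corpus_scene(corpus, i)
    spec <- scene_spectrogram(sc$ref, sc$surv, cfg)
    wins <- window_spectrogram(spec, window_s = window_s)
    windows <- c(windows, wins)
    labels <- c(labels, rep(sc$truth$label, length(wins)))
    subjects <- c(subjects, rep(as.character(sc$truth$subject), length(wins)))
    if (progress && i %% 20 == 0) cat(".")
  }
  if (progress) cat("\n")
  list(windows = windows, labels = labels, subjects = subjects)
}
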