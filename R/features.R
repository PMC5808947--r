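#' Split a spectrogram into fixed-length windows
#'
#' Non-overlapping windows of `window_s` seconds of frames; a trailing
#' partial window is zero-padded to full length so every window has the same
#' frame count.
#'
#' @param spec A `doppler_spectrogram`.
#' @param window_s Window length in seconds (default 4, one activity
#'   observation).
#' @return A list of `doppler_spectrogram`s, one per window.
#' @export
window_spectrogram <- function(spec, window_s = 4) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  k <- ncol(spec$D)
  tt <- spec$frame_times_s
  hop <- if (k > 1) stats::median(diff(tt)) else spec$config$frame_hop_s
  frames_per_win <- max(1L, round(window_s / hop))
  if (k * hop < window_s - 1e-9) {
    stop("spectrogram (", signif(k * hop, 3), " s) shorter than one window (",
         window_s, " s)", call. = FALSE)
  }
  n_win <- ceiling(k / frames_per_win)
  lapply(seq_len(n_win), function(i) {
    idx <- ((i - 1) * frames_per_win + 1):min(i * frames_per_win, k)
    d <- spec$D[, idx, drop = FALSE]
    times <- tt[idx]
    if (length(idx) < frames_per_win) {
      pad <- frames_per_win - length(idx)
      d <- cbind(d, matrix(0, nrow(d), pad))
      times <- c(times, times[length(times)] + hop * seq_len(pad))
    }
    out <- spec
    out$D <- d
    out$frame_times_s <- times
    out
  })
}

#' PCA feature specification
#'
#' @param energy_fraction Fraction of total eigenvalue energy the retained
#'   components must reach (default 0.90).
#' @param max_components Upper bound on the number of retained components
#'   (default 10).
#' @return An object of class `pca_spec`.
#' @export
pca_spec <- function(energy_fraction = 0.90, max_components = 10) {
  if (energy_fraction <= 0 || energy_fraction > 1) {
    stop("energy_fraction must be in (0, 1]", call. = FALSE)
  }
  if (max_components < 1) stop("max_components must be >= 1", call. = FALSE)
  structure(list(energy_fraction = energy_fraction,
                 max_components = max_components),
            class = "pca_spec")
}

#' Singular-value features of a spectrogram window
#'
#' The leading `r` singular values of the window's magnitude matrix, in
#' descending order, zero-padded when the rank is below `r`.
#'
#' @param window A `doppler_spectrogram` window (or a plain matrix).
#' @param r Fixed feature length (default 10).
#' @return Numeric vector of length `r`.
#' @export
svd_features <- function(window, r = 10) {
  d <- if (inherits(window, "doppler_spectrogram")) window$D else window
  if (length(d) == 0) stop("empty spectrogram window", call. = FALSE)
  sv <- svd(d, nu = 0, nv = 0)$d
  out <- numeric(r)
  keep <- seq_len(min(r, length(sv)))
  out[keep] <- sv[keep]
  out
}

#' Train a PCA basis on the training windows
#'
#' Computes the eigenvectors of the covariance of the Doppler profiles
#' (frames as observations, Doppler bins as variables, frame means removed)
#' over the training windows only, and retains `L` components: the smallest
#' number reaching `energy_fraction` of the eigenvalue energy, capped at
#' `max_components`. Keeping the basis a function of the training split only
#' is what prevents test-set leakage.
#'
#' @param windows List of training windows (`doppler_spectrogram`s or
#'   matrices).
#' @param spec A [pca_spec()].
#' @return An object of class `pca_basis` with `rotation` (bins x L),
#'   `center`, `eigenvalues`, `L`.
#' @export
pca_basis <- function(windows, spec = pca_spec()) {
  stopifnot(inherits(spec, "pca_spec"))
  mats <- lapply(windows, function(w) {
    if (inherits(w, "doppler_spectrogram")) w$D else w
  })
  frames <- do.call(cbind, mats)  # bins x total frames
  center <- rowMeans(frames)
  centered <- frames - center
  cv <- tcrossprod(centered) / max(1, ncol(frames) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  evals <- pmax(eg$values, 0)
  energy <- cumsum(evals) / sum(evals)
  l <- min(which(energy >= spec$energy_fraction)[1], spec$max_components)
  structure(
    list(rotation = eg$vectors[, seq_len(l), drop = FALSE],
         center = center, eigenvalues = evals, L = l, spec = spec),
    class = "pca_basis"
  )
}

#' PCA features of a spectrogram window
#'
#' Projects the window's frame columns (center removed) onto the trained
#' basis and flattens the `L x frames` coefficient matrix to a fixed-length
#' vector.
#'
#' @param window A `doppler_spectrogram` window or matrix.
#' @param basis A [pca_basis()] trained on the training split.
#' @return Numeric vector of length `L * frames_per_window`.
#' @export
pca_features <- function(window, basis) {
  stopifnot(inherits(basis, "pca_basis"))
  d <- if (inherits(window, "doppler_spectrogram")) window$D else window
  if (nrow(d) != length(basis$center)) {
    stop("window Doppler dimension does not match the PCA basis",
         call. = FALSE)
  }
  as.numeric(crossprod(basis$rotation, d - basis$center))
}

#' Physical features of a spectrogram window
#'
#' Six interpretable micro-Doppler descriptors:
#' 1. active duration (seconds of frames whose power exceeds 10% of the
#'    window's maximum frame power),
#' 2. Doppler bandwidth (frequency extent of bins above 10% of the window's
#'    peak magnitude, in Hz),
#' 3. peak positive Doppler (Hz, 0 when no positive-Doppler bin is active),
#' 4. peak negative Doppler (Hz, signed, 0 when none),
#' 5. total spectrogram energy,
#' 6. positive/negative Doppler energy ratio (1 for an empty window).
#'
#' @param window A `doppler_spectrogram` window.
#' @param threshold_fraction Activity threshold relative to the window
#'   maximum (default 0.10).
#' @return Numeric vector of length 6.
#' @export
physical_features <- function(window, threshold_fraction = 0.10) {
  stopifnot(inherits(window, "doppler_spectrogram"))
  d <- window$D
  f <- window$doppler_axis_hz
  tt <- window$frame_times_s
  hop <- if (length(tt) > 1) stats::median(diff(tt)) else
    window$config$frame_hop_s
  nz <- f != 0
  dm <- d[nz, , drop = FALSE]
  fm <- f[nz]
  if (max(dm) == 0) {
    return(c(active_duration_s = 0, doppler_bandwidth_hz = 0,
             peak_pos_doppler_hz = 0, peak_neg_doppler_hz = 0,
             total_energy = 0, pos_neg_energy_ratio = 1))
  }
  fpow <- colSums(dm^2)
  active <- fpow > threshold_fraction * max(fpow)
  mask <- dm > threshold_fraction * max(dm)
  bins_hit <- which(apply(mask, 1, any))
  bin_hz <- doppler_bin_hz(window)
  bandwidth <- (max(bins_hit) - min(bins_hit) + 1) * bin_hz
  fhit <- fm[bins_hit]
  ep <- sum(dm[fm > 0, , drop = FALSE]^2)
  en <- sum(dm[fm < 0, , drop = FALSE]^2)
  c(
    active_duration_s = sum(active) * hop,
    doppler_bandwidth_hz = bandwidth,
    peak_pos_doppler_hz = if (any(fhit > 0)) max(fhit) else 0,
    peak_neg_doppler_hz = if (any(fhit < 0)) min(fhit) else 0,
    total_energy = sum(dm^2),
    pos_neg_energy_ratio = (ep + 1e-12) / (en + 1e-12)
  )
}

#' Feature matrix for a list of windows
#'
#' @param windows List of `doppler_spectrogram` windows.
#' @param method `"SVD"`, `"PCA"` or `"PF"`.
#' @param basis A [pca_basis()] (required for `"PCA"`).
#' @param r Singular-value count for `"SVD"`.
#' @return Numeric matrix, one row per window.
#' @export
extract_features <- function(windows, method = c("SVD", "PCA", "PF"),
                             basis = NULL, r = 10) {
  method <- match.arg(method)
  rows <- lapply(windows, function(w) {
    switch(method,
      SVD = svd_features(w, r = r),
      PCA = {
        if (is.null(basis)) {
          stop("PCA features need a basis trained on the training split",
               call. = FALSE)
        }
        pca_features(w, basis)
      },
      PF = physical_features(w)
    )
  })
  do.call(rbind, rows)
}
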