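#' Micro-Doppler weight vector
#'
#' Per-bin weights of the respiration statistic for an ascending, centered
#' Doppler axis with an odd number of bins `j = 2M + 1`.
#'
#' `"literal"` weights are the ceiling-ramp `ceil(j/2 - i)` of the original
#' statistic, oriented so positive-Doppler bins carry the larger weights:
#' they equal a centered antisymmetric ramp plus one, i.e. the asymmetry
#' between positive and negative Doppler *plus* the total column magnitude.
#' The magnitude term is dominated by the zero-Doppler bin, whose
#' interference between the static field and the chest echo is modulated at
#' first order by the chest displacement -- this is what makes the waveform
#' track a displacement reference. `"centered"` weights drop that term
#' (zero-Doppler bin weighted 0, antisymmetric about it) and isolate the pure
#' spectral asymmetry, a velocity-proportional signal.
#'
#' @param n_bins Odd number of Doppler bins.
#' @param type `"literal"` or `"centered"`.
#' @return Numeric weight vector of length `n_bins`.
#' @export
micro_doppler_weights <- function(n_bins, type = c("literal", "centered")) {
  type <- match.arg(type)
  if (n_bins %% 2 == 0) {
    stop("micro-Doppler extraction needs an odd number of Doppler bins",
         call. = FALSE)
  }
  m <- (n_bins - 1) %/% 2
  ramp <- seq(-m, m)
  switch(type, literal = ramp + 1, centered = ramp)
}

#' Extract the micro-Doppler respiration waveform
#'
#' Collapses each spectrogram frame to the center-weighted sum
#' `Psi(n) = sum_i D[i, n] w_i` with the weights of
#' [micro_doppler_weights()]. With literal weights, `Psi` oscillates at the
#' breathing rate (positive swing on inhale for the default facing geometry);
#' with centered weights it is the signed positive/negative Doppler asymmetry
#' and vanishes for columns symmetric about zero Doppler.
#'
#' @param spec A `doppler_spectrogram` from a static (breathing) segment.
#' @param weights `"literal"` (default) or `"centered"`, or a numeric vector
#'   of per-bin weights.
#' @return An object of class `micro_doppler_series`: `psi`,
#'   `frame_times_s`, `weights`, `smoothed` flag.
#' @export
extract_micro_doppler <- function(spec, weights = "literal") {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  if (ncol(spec$D) == 0) {
    stop("empty spectrogram", call. = FALSE)
  }
  w <- if (is.character(weights)) {
    micro_doppler_weights(nrow(spec$D), weights)
  } else {
    stopifnot(length(weights) == nrow(spec$D))
    weights
  }
  structure(
    list(
      psi = as.numeric(crossprod(spec$D, w)),
      frame_times_s = spec$frame_times_s,
      weights = w,
      smoothed = FALSE
    ),
    class = "micro_doppler_series"
  )
}

#' @export
print.micro_doppler_series <- function(x, ...) {
  cat(sprintf("<micro_doppler_series: %d frames, %s>\n", length(x$psi),
              if (x$smoothed) "smoothed" else "raw"))
  invisible(x)
}

#' Savitzky-Golay filter specification
#'
#' Moving least-squares polynomial smoother: within every window of
#' `2M + 1` samples a polynomial of degree `poly_order` is fit and evaluated
#' at the window center; near the edges the first/last window's polynomial is
#' evaluated at the off-center points. The central coefficient row sums to 1,
#' so constants pass unchanged, and any polynomial of degree `<= poly_order`
#' is reproduced exactly.
#'
#' @param window_s Window length in seconds (default 2, sized to smooth
#'   within one breathing cycle at 12-20 breaths/min while preserving peak
#'   shape).
#' @param poly_order Polynomial degree (default 3).
#' @return An object of class `sg_filter_spec`.
#' @export
sg_filter_spec <- function(window_s = 2, poly_order = 3) {
  if (window_s <= 0) stop("window_s must be positive", call. = FALSE)
  if (poly_order < 0 || poly_order != round(poly_order)) {
    stop("poly_order must be a non-negative integer", call. = FALSE)
  }
  structure(list(window_s = window_s, poly_order = poly_order),
            class = "sg_filter_spec")
}

# Realized odd window length in samples for a given frame rate.
sg_window_samples <- function(spec, rate_hz) {
  n <- max(spec$poly_order + 2, round(spec$window_s * rate_hz))
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

#' Savitzky-Golay smoothing of the respiration waveform
#'
#' @param series A `micro_doppler_series`.
#' @param spec An [sg_filter_spec()].
#' @return The smoothed `micro_doppler_series` (`smoothed = TRUE`).
#' @export
sg_smooth <- function(series, spec = sg_filter_spec()) {
  stopifnot(inherits(series, "micro_doppler_series"),
            inherits(spec, "sg_filter_spec"))
  n <- length(series$psi)
  rate <- series_rate_hz(series)
  win <- sg_window_samples(spec, rate)
  if (win >= n) {
    stop("SG window (", win, " samples) must be shorter than the series (",
         n, ")", call. = FALSE)
  }
  out <- series
  out$psi <- as.numeric(signal::sgolayfilt(series$psi, p = spec$poly_order,
                                           n = win))
  out$smoothed <- TRUE
  out
}

# Sampling rate of a micro-Doppler series (frames per second).
series_rate_hz <- function(series) {
  tt <- series$frame_times_s
  if (length(tt) > 1) 1 / stats::median(diff(tt)) else 1
}

#' Estimate the breathing rate by FFT
#'
#' Removes the mean, applies a zero-padded FFT to the waveform and returns
#' the frequency of the magnitude peak within the search band, in breaths
#' per minute. The estimate is flagged invalid when the series is constant
#' or the in-band spectrum is flat (no breathing peak to pick).
#'
#' @param series A `micro_doppler_series` (typically [sg_smooth()]ed).
#' @param band_bpm Search band in breaths/min, default 6-30 (covering the
#'   normal 12-20 range with margin).
#' @param pad_factor Zero-padding factor for the FFT grid.
#' @return An object of class `breathing_estimate`: `rate_bpm`, `valid`,
#'   `waveform` (the input series), `band_bpm`, plus the in-band spectrum.
#' @export
estimate_rate <- function(series, band_bpm = c(6, 30), pad_factor = 16) {
  stopifnot(inherits(series, "micro_doppler_series"))
  psi <- series$psi - mean(series$psi)
  n <- length(psi)
  rate <- series_rate_hz(series)
  if (n < 4 || rate * 60 / 2 < band_bpm[1]) {
    stop("series too short/slow for the requested band", call. = FALSE)
  }
  nfft <- pad_factor * 2^ceiling(log2(n))
  spec_mag <- Mod(stats::fft(c(psi, numeric(nfft - n))))[seq_len(nfft %/% 2)]
  freq_hz <- (seq_len(nfft %/% 2) - 1) * rate / nfft
  in_band <- freq_hz >= band_bpm[1] / 60 & freq_hz <= band_bpm[2] / 60
  band_mag <- spec_mag[in_band]
  band_freq <- freq_hz[in_band]
  valid <- stats::sd(psi) > 0 && length(band_mag) > 0 &&
    max(band_mag) > 1.05 * mean(band_mag)
  rate_bpm <- if (valid) band_freq[which.max(band_mag)] * 60 else NA_real_
  structure(
    list(
      rate_bpm = rate_bpm,
      valid = valid,
      band_bpm = band_bpm,
      waveform = series,
      spectrum = data.frame(freq_hz = band_freq, magnitude = band_mag)
    ),
    class = "breathing_estimate"
  )
}

#' @export
print.breathing_estimate <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<breathing_estimate: %.2f bpm>\n", x$rate_bpm))
  } else {
    cat("<breathing_estimate: invalid (no breathing peak in band)>\n")
  }
  invisible(x)
}

#' Evaluate the radar waveform against a chest-belt reference
#'
#' Resamples the micro-Doppler waveform down onto the belt's (slower) time
#' grid over the overlapping support, z-scores it, scales the belt to the
#' same zero-mean/unit-variance convention ("normalizing the belt to the
#' micro-Doppler signal"), and reports the Pearson correlation R and the
#' mean-square error of the aligned pair. On this normalized scale
#' `MSE = 2 (1 - R)`: 0 for a perfect match, 4 for perfect anticorrelation.
#'
#' @param series A `micro_doppler_series`.
#' @param belt Data frame with columns `time_s`, `value` (see
#'   [chest_belt_reference()]), or another `micro_doppler_series`.
#' @return A list with elements `r`, `mse`, and the aligned data frame
#'   (`time_s`, `radar`, `belt`).
#' @export
evaluate_against_reference <- function(series, belt) {
  stopifnot(inherits(series, "micro_doppler_series"))
  if (inherits(belt, "micro_doppler_series")) {
    belt <- data.frame(time_s = belt$frame_times_s, value = belt$psi)
  }
  stopifnot(is.data.frame(belt), all(c("time_s", "value") %in% names(belt)))
  t0 <- max(min(series$frame_times_s), min(belt$time_s))
  t1 <- min(max(series$frame_times_s), max(belt$time_s))
  if (t1 <= t0) {
    stop("radar waveform and belt reference do not overlap in time",
         call. = FALSE)
  }
  keep <- belt$time_s >= t0 & belt$time_s <= t1
  tt <- belt$time_s[keep]
  radar <- stats::approx(series$frame_times_s, series$psi, xout = tt)$y
  ref <- belt$value[keep]
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }
  rz <- zscore(radar)
  bz <- zscore(ref)
  r <- if (stats::sd(radar) == 0 || stats::sd(ref) == 0) {
    NA_real_
  } else {
    stats::cor(radar, ref)
  }
  list(
    r = r,
    mse = mean((rz - bz)^2),
    aligned = data.frame(time_s = tt, radar = rz, belt = bz)
  )
}
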