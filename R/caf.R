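#' Cross-ambiguity processing configuration
#'
#' Parameters of one CAF integration window. The Doppler bin width is the
#' reciprocal of the integration time `1/T`; the number of batches `n_b`
#' (odd, so one bin sits exactly at zero Doppler) sets the unambiguous
#' Doppler span `+/- (n_b - 1) / (2 T)`, i.e. the maximum detectable
#' velocity. Mode defaults:
#'
#' * `"activity"`: T = 1 s (1 Hz bins), span +/- 60 Hz, rectangular window,
#'   non-overlapping frames.
#' * `"breathing"`: T = 2 s (0.5 Hz bins, finer than activity mode), span
#'   +/- 5 Hz, Hann-tapered window, frame hop 0.25 s.
#'
#' @param mode `"activity"` or `"breathing"`.
#' @param integration_time_s Integration time T in seconds.
#' @param doppler_span_hz One-sided Doppler span in Hz.
#' @param max_delay_s Largest delay computed, in seconds (0 = the single
#'   direct-path range cell; indoor ranges are far below one delay bin).
#' @param num_batches Number of batches `n_b`; default the smallest odd value
#'   covering `doppler_span_hz`.
#' @param frame_hop_s Spectrogram frame hop in seconds; default `T` for
#'   activity mode (non-overlapping), 0.25 s for breathing mode.
#' @param window Integration-window taper, `"rect"` or `"hann"`.
#' @param bandwidth_hz Illuminator RF bandwidth used to report the range
#'   resolution `c / (2 B)`.
#'
#' @return An object of class `caf_config`.
#' @export
caf_config <- function(mode = c("activity", "breathing"),
                       integration_time_s = NULL,
                       doppler_span_hz = NULL,
                       max_delay_s = 0,
                       num_batches = NULL,
                       frame_hop_s = NULL,
                       window = NULL,
                       bandwidth_hz = 2e7) {
  mode <- match.arg(mode)
  if (is.null(integration_time_s)) {
    integration_time_s <- switch(mode, activity = 1, breathing = 2)
  }
  if (is.null(doppler_span_hz)) {
    doppler_span_hz <- switch(mode, activity = 60, breathing = 5)
  }
  if (is.null(window)) {
    window <- switch(mode, activity = "rect", breathing = "hann")
  }
  window <- match.arg(window, c("rect", "hann"))
  if (is.null(frame_hop_s)) {
    frame_hop_s <- switch(mode, activity = integration_time_s,
                          breathing = 0.25)
  }
  if (integration_time_s <= 0) {
    stop("integration_time_s must be positive", call. = FALSE)
  }
  if (doppler_span_hz <= 0) {
    stop("doppler_span_hz must be positive", call. = FALSE)
  }
  if (max_delay_s < 0) stop("max_delay_s must be >= 0", call. = FALSE)
  if (frame_hop_s <= 0) stop("frame_hop_s must be positive", call. = FALSE)
  if (is.null(num_batches)) {
    num_batches <- 2 * ceiling(doppler_span_hz * integration_time_s) + 1
  }
  if (num_batches < 1 || num_batches %% 2 == 0) {
    stop("num_batches must be a positive odd integer", call. = FALSE)
  }
  structure(
    list(
      mode = mode,
      integration_time_s = integration_time_s,
      doppler_span_hz = doppler_span_hz,
      max_delay_s = max_delay_s,
      num_batches = num_batches,
      batch_len_s = integration_time_s / num_batches,
      frame_hop_s = frame_hop_s,
      window = window,
      bandwidth_hz = bandwidth_hz
    ),
    class = "caf_config"
  )
}

#' @export
print.caf_config <- function(x, ...) {
  cat(sprintf("<caf_config: %s>\n", x$mode))
  cat(sprintf("  T = %.3g s (%d batches of %.3g s), Doppler bin %.3g Hz, span +/- %.3g Hz\n",
              x$integration_time_s, x$num_batches, x$batch_len_s,
              doppler_bin_hz(x), x$doppler_span_hz))
  cat(sprintf("  frame hop %.3g s, %s window, range resolution %.3g m\n",
              x$frame_hop_s, x$window, range_resolution_m(x)))
  invisible(x)
}

#' Doppler bin width of a configuration
#'
#' @param x A `caf_config`, `caf_map` or `doppler_spectrogram`.
#' @return The Doppler bin width `1/T` in Hz.
#' @export
doppler_bin_hz <- function(x) {
  cfg <- if (inherits(x, "caf_config")) x else x$config
  1 / cfg$integration_time_s
}

#' Range resolution of a configuration
#'
#' The usable range resolution of the passive radar, `c / (2 B)` for
#' illuminator bandwidth B (7.5 m at 20 MHz -- too coarse for indoor ranging,
#' which is why the pipeline works in Doppler).
#'
#' @param x A `caf_config`, `caf_map` or `doppler_spectrogram`.
#' @return Range resolution in meters.
#' @export
range_resolution_m <- function(x) {
  cfg <- if (inherits(x, "caf_config")) x else x$config
  SPEED_OF_LIGHT / (2 * cfg$bandwidth_hz)
}

# Integration-window taper.
caf_window <- function(type, n) {
  switch(type,
    rect = rep(1, n),
    hann = 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  )
}

#' Batched cross-ambiguity map of one integration window
#'
#' Correlates the surveillance channel against delayed copies of the
#' reference over a grid of delays and Doppler shifts:
#' `CAF(tau, f_d) = sum_t surv(t) conj(ref(t - tau)) exp(-2 pi i f_d t)`.
#' The sum is evaluated with the batching scheme -- the window is split into
#' `n_b` batches, an FFT across the batch index resolves the Doppler bins at
#' `1/T` spacing, and an intra-batch twiddle correction keeps the result
#' exactly equal to the direct double-loop evaluation of the ambiguity sum
#' (to machine precision), not just to within Doppler-quantization error.
#'
#' @param ref,surv Reference and surveillance [baseband_recording()]s,
#'   time-aligned with equal sample rates.
#' @param cfg A [caf_config()].
#' @param t_start_s Window start time within the recordings, seconds.
#' @return An object of class `caf_map`: complex `values`
#'   (delay x Doppler), `delay_axis_s`, `doppler_axis_hz` (centered,
#'   ascending, odd length), `frame_time_s` (window center) and `config`.
#' @export
compute_caf <- function(ref, surv, cfg, t_start_s = 0) {
  stopifnot(inherits(ref, "baseband_recording"),
            inherits(surv, "baseband_recording"),
            inherits(cfg, "caf_config"))
  if (ref$sample_rate_hz != surv$sample_rate_hz) {
    stop("ref and surv must share one sample rate", call. = FALSE)
  }
  fs <- ref$sample_rate_hz
  n_frame <- round(cfg$integration_time_s * fs)
  start <- round(t_start_s * fs)
  n_avail <- min(length(ref$samples), length(surv$samples))
  if (start + n_frame > n_avail) {
    stop("integration window exceeds the recording length", call. = FALSE)
  }
  n_b <- cfg$num_batches
  l_b <- n_frame %/% n_b
  if (l_b < 1) {
    stop("integration window shorter than the number of batches",
         call. = FALSE)
  }
  n_use <- l_b * n_b
  if (n_use != n_frame) {
    warning(sprintf("trimming %d samples so %d batches tile the window",
                    n_frame - n_use, n_b), call. = FALSE)
  }
  x <- ref$samples[(start + 1):(start + n_use)]
  y <- surv$samples[(start + 1):(start + n_use)]
  w <- caf_window(cfg$window, n_use)

  m_half <- (n_b - 1) %/% 2
  ms <- seq(-m_half, m_half)
  rows_q <- (ms %% n_b) + 1L
  # intra-batch twiddle: exp(-2 pi i m s / N) for s = 0..L_B-1
  tw <- exp(-2i * pi * outer(0:(l_b - 1), ms) / n_use)

  n_delay <- round(cfg$max_delay_s * fs)
  if (n_delay >= n_use) {
    stop("max_delay_s exceeds the integration window", call. = FALSE)
  }
  vals <- matrix(0i, nrow = n_delay + 1, ncol = n_b)
  for (d in 0:n_delay) {
    z <- complex(length.out = n_use)
    z[(d + 1):n_use] <- y[(d + 1):n_use] * Conj(x[seq_len(n_use - d)])
    z <- z * w
    zf <- stats::mvfft(t(matrix(z, nrow = l_b)))  # n_b x L_B, FFT over batches
    vals[d + 1, ] <- colSums(t(zf)[, rows_q, drop = FALSE] * tw)
  }

  structure(
    list(
      values = vals,
      delay_axis_s = (0:n_delay) / fs,
      doppler_axis_hz = ms * fs / n_use,
      frame_time_s = t_start_s + n_use / fs / 2,
      sample_rate_hz = fs,
      config = cfg
    ),
    class = "caf_map"
  )
}

#' @export
print.caf_map <- function(x, ...) {
  cat(sprintf("<caf_map: %d delay x %d Doppler bins at t = %.3g s>\n",
              nrow(x$values), ncol(x$values), x$frame_time_s))
  pk <- arrayInd(which.max(Mod(x$values)), dim(x$values))
  cat(sprintf("  peak at delay %.3g us, Doppler %.3g Hz\n",
              x$delay_axis_s[pk[1]] * 1e6, x$doppler_axis_hz[pk[2]]))
  invisible(x)
}

#' Self-ambiguity surface of the reference channel
#'
#' The CAF of the reference signal with itself; its zero-Doppler row is the
#' autocorrelation used by the CLEAN step to model the direct path and static
#' clutter.
#'
#' @inheritParams compute_caf
#' @return A `caf_map`.
#' @export
self_ambiguity <- function(ref, cfg, t_start_s = 0) {
  compute_caf(ref, ref, cfg, t_start_s = t_start_s)
}

#' CLEAN direct-signal cancellation
#'
#' Subtracts a scaled copy of the reference self-ambiguity surface from a CAF
#' map to suppress the direct path and static clutter concentrated on the
#' zero-Doppler line. The complex scale is the ratio of the two zero-Doppler
#' peaks, with the self surface shifted in delay so its peak aligns with the
#' direct-path delay of the CAF. Optionally iterated until the zero-Doppler
#' peak stops dropping.
#'
#' @param caf A `caf_map` from [compute_caf()].
#' @param self_caf The matching [self_ambiguity()] map (identical axes).
#' @param max_iter Maximum CLEAN iterations (default 1, classic single pass).
#' @param tol_db Stop iterating once the zero-Doppler peak drops by less than
#'   this many dB.
#' @return A `caf_map` with the scaled self surface removed.
#' @export
clean_caf <- function(caf, self_caf, max_iter = 1, tol_db = 0.1) {
  stopifnot(inherits(caf, "caf_map"), inherits(self_caf, "caf_map"))
  if (!isTRUE(all.equal(caf$delay_axis_s, self_caf$delay_axis_s)) ||
      !isTRUE(all.equal(caf$doppler_axis_hz, self_caf$doppler_axis_hz))) {
    stop("caf and self_caf axes do not match", call. = FALSE)
  }
  i0 <- which.min(abs(caf$doppler_axis_hz))
  vals <- caf$values
  s0 <- self_caf$values
  d0 <- which.max(Mod(s0[, i0]))
  if (Mod(s0[d0, i0]) == 0) {
    return(caf)  # nothing to subtract from an all-zero self surface
  }
  for (k in seq_len(max_iter)) {
    d1 <- which.max(Mod(vals[, i0]))
    peak_before <- Mod(vals[d1, i0])
    if (peak_before == 0) break
    alpha <- vals[d1, i0] / s0[d0, i0]
    shifted <- shift_rows(s0, d1 - d0)
    vals <- vals - alpha * shifted
    peak_after <- max(Mod(vals[, i0]))
    if (peak_after == 0) break
    if (20 * log10(peak_before / peak_after) < tol_db) break
  }
  out <- caf
  out$values <- vals
  out
}

# Shift matrix rows down by `by` (zero-filled); negative shifts up.
shift_rows <- function(m, by) {
  if (by == 0) return(m)
  out <- matrix(0i, nrow = nrow(m), ncol = ncol(m))
  if (by > 0 && by < nrow(m)) {
    out[(by + 1):nrow(m), ] <- m[seq_len(nrow(m) - by), ]
  } else if (by < 0 && -by < nrow(m)) {
    out[seq_len(nrow(m) + by), ] <- m[(-by + 1):nrow(m), ]
  }
  out
}
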