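# Shared fixture builders. All scenes here are small (seconds at 2 kHz) so
# the default test run stays fast; statistical checks use the seeds fixed
# below.

test_fs <- 2000

test_source <- function(duration_s = 1, seed = 1, fs = test_fs) {
  generate_dsss_source(scene_source_spec(fs), duration_s, fs, seed = seed)
}

# Surveillance channel that is an exact delayed/Doppler-shifted copy of the
# reference (bypasses simulate_scene for oracle-style tests).
shifted_copy <- function(ref, delay_samples = 0, doppler_hz = 0, gain = 1) {
  n <- length(ref$samples)
  s <- if (delay_samples > 0) {
    c(complex(length.out = delay_samples),
      ref$samples[seq_len(n - delay_samples)])
  } else {
    ref$samples
  }
  if (doppler_hz != 0) {
    t <- (seq_len(n) - 1) / ref$sample_rate_hz
    s <- s * exp(2i * pi * doppler_hz * t)
  }
  baseband_recording(gain * s, ref$sample_rate_hz, ref$carrier_freq_hz,
                     channel = "surveillance")
}

# Direct double-loop evaluation of the ambiguity sum (the independent
# oracle): CAF(tau, f) = sum_t y(t) conj(x(t - tau)) exp(-2 pi i f t / fs).
caf_direct_oracle <- function(x, y, delays, freqs_hz, fs) {
  n <- length(x)
  tt <- (0:(n - 1)) / fs
  out <- matrix(0i, length(delays), length(freqs_hz))
  for (di in seq_along(delays)) {
    d <- delays[di]
    z <- complex(length.out = n)
    z[(d + 1):n] <- y[(d + 1):n] * Conj(x[seq_len(n - d)])
    for (fi in seq_along(freqs_hz)) {
      out[di, fi] <- sum(z * exp(-2i * pi * freqs_hz[fi] * tt))
    }
  }
  out
}

# Tiny spectrogram built directly from a matrix (unit frame hop).
matrix_spectrogram <- function(d, bin_hz = 1, hop_s = 1,
                               mode = "activity") {
  m <- (nrow(d) - 1) / 2
  cfg <- caf_config(mode, integration_time_s = 1 / bin_hz,
                    doppler_span_hz = max(1, m * bin_hz),
                    frame_hop_s = hop_s)
  structure(
    list(D = d,
         doppler_axis_hz = seq(-m, m) * bin_hz,
         frame_times_s = (seq_len(ncol(d)) - 0.5) * hop_s,
         config = cfg),
    class = "doppler_spectrogram"
  )
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

quiet_spectrogram <- function(ref, surv, cfg, ...) {
  suppressWarnings(scene_spectrogram(ref, surv, cfg, ...))
}
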