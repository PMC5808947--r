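#' Propagation path specification
#'
#' One arrival path of the surveillance channel: a delayed, attenuated copy of
#' the illuminator signal with an optional time-varying Doppler shift. The
#' Doppler profile is *fractional* (dimensionless, approximately `2 v / c`);
#' the instantaneous shift in Hz is `carrier_freq_hz * f_d(t)`. Time-varying
#' profiles are realized by phase accumulation
#' `phi(t) = 2 pi f_c integral f_d dt`, which reduces to the constant-shift
#' narrowband model when `f_d` is constant.
#'
#' @param delay_s Path delay in seconds (>= 0). Rounded to whole samples at
#'   simulation time.
#' @param attenuation Linear path attenuation `A_p` (>= 0).
#' @param doppler_profile Either a single number (constant fractional Doppler)
#'   or a function `f(t)` of time in seconds returning the fractional Doppler.
#'   `NULL` means a static path (zero Doppler).
#' @param carrier_phase_rad Baseband carrier phase of the path in radians.
#'   `NULL` (default) uses the physical value `-2 pi f_c delay_s`, which at
#'   UHF carriers is effectively geometry-random; static clutter and the chest
#'   path set it explicitly.
#'
#' @return An object of class `path_spec`.
#' @export
path_spec <- function(delay_s = 0, attenuation = 1, doppler_profile = NULL,
                      carrier_phase_rad = NULL) {
  if (delay_s < 0) stop("delay_s must be >= 0", call. = FALSE)
  if (attenuation < 0) stop("attenuation must be >= 0", call. = FALSE)
  if (!is.null(doppler_profile) && !is.function(doppler_profile) &&
      !(is.numeric(doppler_profile) && length(doppler_profile) == 1)) {
    stop("doppler_profile must be NULL, a number, or a function of time",
         call. = FALSE)
  }
  structure(
    list(
      delay_s = delay_s,
      attenuation = attenuation,
      doppler_profile = doppler_profile,
      carrier_phase_rad = carrier_phase_rad
    ),
    class = "path_spec"
  )
}

#' @export
print.path_spec <- function(x, ...) {
  kind <- if (is.null(x$doppler_profile)) {
    "static"
  } else if (is.function(x$doppler_profile)) {
    "dynamic (profile)"
  } else {
    sprintf("constant f_d = %.3g", x$doppler_profile)
  }
  cat(sprintf("<path_spec: %s, delay %.3g us, attenuation %.3g>\n",
              kind, x$delay_s * 1e6, x$attenuation))
  invisible(x)
}

# Evaluate the fractional Doppler profile of a path on a time grid.
path_doppler <- function(path, t) {
  p <- path$doppler_profile
  if (is.null(p)) return(numeric(length(t)))
  if (is.function(p)) p(t) else rep(p, length(t))
}

#' Synthesize the surveillance channel of a scene
#'
#' Builds the surveillance recording as the sum over all propagation paths of
#' attenuated, delayed, Doppler-shifted copies of the reference signal plus
#' complex AWGN: each path contributes
#' `A_p * x(t - tau) * exp(j (phase + 2 pi f_c integral f_d dt))`.
#'
#' @param src Reference-channel [baseband_recording()].
#' @param static_paths List of static [path_spec()]s (direct path, clutter).
#' @param dynamic_paths List of [path_spec()]s with Doppler profiles (chest,
#'   body). A single `path_spec` is accepted for either argument.
#' @param noise_power Per-sample complex noise variance (0 = noiseless). See
#'   [snr_to_noise_power()] to derive it from an SNR.
#' @param seed Integer seed for the noise draw.
#'
#' @return A surveillance-channel [baseband_recording()] sharing the sample
#'   rate, carrier and start time of `src`.
#' @export
simulate_scene <- function(src, static_paths = list(), dynamic_paths = list(),
                           noise_power = 0, seed = 1L) {
  stopifnot(inherits(src, "baseband_recording"))
  if (src$channel != "reference") {
    stop("src must be a reference-channel recording", call. = FALSE)
  }
  if (inherits(static_paths, "path_spec")) static_paths <- list(static_paths)
  if (inherits(dynamic_paths, "path_spec")) dynamic_paths <- list(dynamic_paths)
  paths <- c(static_paths, dynamic_paths)
  fs <- src$sample_rate_hz
  fc <- src$carrier_freq_hz
  n <- length(src$samples)
  t <- (seq_len(n) - 1) / fs

  out <- complex(length.out = n)
  for (p in paths) {
    stopifnot(inherits(p, "path_spec"))
    d <- round(p$delay_s * fs)
    if (d >= n) {
      stop("path delay exceeds the recording duration", call. = FALSE)
    }
    delayed <- if (d > 0) {
      c(complex(length.out = d), src$samples[seq_len(n - d)])
    } else {
      src$samples
    }
    phase0 <- if (is.null(p$carrier_phase_rad)) {
      -2 * pi * fc * p$delay_s
    } else {
      p$carrier_phase_rad
    }
    fd <- path_doppler(p, t)
    if (any(fd != 0)) {
      # accumulated phase: 2 pi f_c * cumulative integral of f_d(t)
      phi <- 2 * pi * fc * (cumsum(fd) - fd[1]) / fs
      out <- out + p$attenuation * delayed * exp(1i * (phase0 + phi))
    } else if (phase0 != 0) {
      out <- out + p$attenuation * delayed * exp(1i * phase0)
    } else {
      out <- out + p$attenuation * delayed
    }
  }

  if (noise_power > 0) {
    rng <- local_rng(seed)
    w <- rng(function() {
      complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
    }) * sqrt(noise_power / 2)
    out <- out + w
  }

  baseband_recording(out, fs, fc, channel = "surveillance", seed = seed,
                     truth = src$truth)
}

#' Noise power for a target SNR
#'
#' @param signal_power Mean power of the signal component.
#' @param snr_db Target signal-to-noise ratio in dB.
#' @return The per-sample complex noise variance.
#' @export
snr_to_noise_power <- function(signal_power, snr_db) {
  signal_power / 10^(snr_db / 10)
}
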