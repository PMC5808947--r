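# Speed of light, m/s. Used for all Doppler <-> velocity conversions.
SPEED_OF_LIGHT <- 299792458

#' Illuminator (DSSS source) specification
#'
#' Describes the direct-sequence spread-spectrum signal transmitted by the
#' illuminator of opportunity: a stream of random-phase chips shaped by a
#' root-raised-cosine pulse, optionally carrying `num_bits` data-bit phases on
#' top of the spreading phases.
#'
#' @param carrier_freq_hz Carrier frequency in Hz (default 915 MHz, sub-1 GHz
#'   ISM band).
#' @param bandwidth_hz Nominal RF bandwidth B in Hz. The occupied bandwidth of
#'   the generated signal is approximately B when `chip_rate_hz` keeps its
#'   default of `bandwidth_hz / 1.25` (root-raised-cosine roll-off 0.25).
#' @param chip_rate_hz Spreading chip rate in Hz; must not exceed
#'   `bandwidth_hz`.
#' @param num_bits Number of data bits N (each bit adds a random phase shared
#'   by a block of chips). `NULL` means the bit structure is derived from the
#'   duration at generation time (one bit per 128 chips, at least one).
#' @param tx_power_dbm Transmit power in dBm; sets the RMS amplitude of the
#'   generated baseband signal (30 dBm = 1 W = unit RMS).
#' @param rrc_rolloff Root-raised-cosine roll-off factor in `[0, 1]`.
#'
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(carrier_freq_hz = 9.15e8,
                        bandwidth_hz = 2e7,
                        chip_rate_hz = bandwidth_hz / 1.25,
                        num_bits = NULL,
                        tx_power_dbm = 30,
                        rrc_rolloff = 0.25) {
  if (bandwidth_hz <= 0) {
    stop("bandwidth_hz must be positive", call. = FALSE)
  }
  if (chip_rate_hz <= 0 || chip_rate_hz > bandwidth_hz) {
    stop("chip_rate_hz must be in (0, bandwidth_hz]", call. = FALSE)
  }
  if (!is.null(num_bits) && (num_bits < 1 || num_bits != round(num_bits))) {
    stop("num_bits must be a positive integer or NULL", call. = FALSE)
  }
  if (carrier_freq_hz <= 0) {
    stop("carrier_freq_hz must be positive", call. = FALSE)
  }
  if (rrc_rolloff < 0 || rrc_rolloff > 1) {
    stop("rrc_rolloff must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      carrier_freq_hz = carrier_freq_hz,
      bandwidth_hz = bandwidth_hz,
      chip_rate_hz = chip_rate_hz,
      num_bits = num_bits,
      tx_power_dbm = tx_power_dbm,
      rrc_rolloff = rrc_rolloff
    ),
    class = "source_spec"
  )
}

#' @export
print.source_spec <- function(x, ...) {
  cat("<source_spec>\n")
  cat(sprintf("  carrier:   %.4g MHz\n", x$carrier_freq_hz / 1e6))
  cat(sprintf("  bandwidth: %.4g MHz (chip rate %.4g MHz, roll-off %.2f)\n",
              x$bandwidth_hz / 1e6, x$chip_rate_hz / 1e6, x$rrc_rolloff))
  cat(sprintf("  tx power:  %g dBm\n", x$tx_power_dbm))
  invisible(x)
}

#' Single-channel complex baseband recording
#'
#' Container for the IQ samples of one receive channel together with timing
#' and carrier metadata. Both channels of one scene share the sample rate and
#' start time (the receiver chains share one clock).
#'
#' @param samples Complex vector of baseband samples.
#' @param sample_rate_hz Sample rate in Hz.
#' @param carrier_freq_hz Carrier frequency the baseband is referred to, Hz.
#' @param channel `"reference"` or `"surveillance"`.
#' @param seed Integer seed the recording was generated from (NA for data not
#'   produced by the simulator).
#' @param truth Optional named list of ground-truth scene information
#'   (breathing rate, activity label, path geometry, ...).
#'
#' @return An object of class `baseband_recording` with fields `samples`,
#'   `sample_rate_hz`, `carrier_freq_hz`, `channel`, `duration_s`, `seed`,
#'   `truth`.
#' @export
baseband_recording <- function(samples, sample_rate_hz, carrier_freq_hz,
                               channel = c("reference", "surveillance"),
                               seed = NA_integer_, truth = list()) {
  channel <- match.arg(channel)
  if (sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  samples <- as.complex(samples)
  structure(
    list(
      samples = samples,
      sample_rate_hz = sample_rate_hz,
      carrier_freq_hz = carrier_freq_hz,
      channel = channel,
      duration_s = length(samples) / sample_rate_hz,
      seed = seed,
      truth = truth
    ),
    class = "baseband_recording"
  )
}

#' @export
print.baseband_recording <- function(x, ...) {
  cat(sprintf("<baseband_recording: %s>\n", x$channel))
  cat(sprintf("  %d samples @ %.4g kHz (%.3g s), carrier %.4g MHz\n",
              length(x$samples), x$sample_rate_hz / 1e3, x$duration_s,
              x$carrier_freq_hz / 1e6))
  if (length(x$truth)) {
    cat("  truth:", paste(names(x$truth), collapse = ", "), "\n")
  }
  invisible(x)
}

# Root-raised-cosine filter taps (closed form), unit-energy normalized.
# span_chips: one-sided span in chips; sps: samples per chip.
rrc_taps <- function(rolloff, sps, span_chips = 6) {
  t <- seq(-span_chips, span_chips, by = 1 / sps) # in chip units
  b <- rolloff
  h <- numeric(length(t))
  for (k in seq_along(t)) {
    ti <- t[k]
    if (abs(ti) < 1e-12) {
      h[k] <- 1 - b + 4 * b / pi
    } else if (b > 0 && abs(abs(4 * b * ti) - 1) < 1e-9) {
      h[k] <- (b / sqrt(2)) * ((1 + 2 / pi) * sin(pi / (4 * b)) +
                                 (1 - 2 / pi) * cos(pi / (4 * b)))
    } else {
      h[k] <- (sin(pi * ti * (1 - b)) + 4 * b * ti * cos(pi * ti * (1 + b))) /
        (pi * ti * (1 - (4 * b * ti)^2))
    }
  }
  h / sqrt(sum(h^2))
}

#' Generate the reference-channel DSSS baseband signal
#'
#' Produces the illuminator waveform as a random-phase chip sequence shaped by
#' a root-raised-cosine pulse. Identical `(spec, duration_s, sample_rate_hz,
#' seed)` always yield identical samples.
#'
#' @param spec A [source_spec()].
#' @param duration_s Recording duration in seconds (> 0).
#' @param sample_rate_hz Receiver sample rate in Hz; must be at least the chip
#'   rate so the chip stream is representable. The effective chip rate is
#'   rounded to an integer number of samples per chip.
#' @param seed Integer seed for the chip and data-bit phases.
#' @param chip_phases Optional numeric vector overriding the random chip
#'   phases (radians), recycled/truncated to the number of chips. Useful for
#'   deterministic test waveforms (e.g. an all-zero phase pulse train).
#'
#' @return A reference-channel [baseband_recording()].
#' @export
generate_dsss_source <- function(spec, duration_s, sample_rate_hz,
                                 seed = 1L, chip_phases = NULL) {
  stopifnot(inherits(spec, "source_spec"))
  if (duration_s <= 0) {
    stop("duration_s must be positive", call. = FALSE)
  }
  if (sample_rate_hz <= 0) {
    stop("sample_rate_hz must be positive", call. = FALSE)
  }
  if (sample_rate_hz < spec$chip_rate_hz) {
    stop("sample_rate_hz must be >= chip_rate_hz of the source", call. = FALSE)
  }
  n_samples <- round(sample_rate_hz * duration_s)
  sps <- max(1L, round(sample_rate_hz / spec$chip_rate_hz))
  n_chips <- ceiling(n_samples / sps) + 1L

  rng <- local_rng(seed)
  if (is.null(chip_phases)) {
    phases <- rng(function() stats::runif(n_chips, 0, 2 * pi))
  } else {
    phases <- rep_len(chip_phases, n_chips)
  }
  n_bits <- spec$num_bits
  if (is.null(n_bits)) n_bits <- max(1L, n_chips %/% 128L)
  if (n_bits > 1) {
    bit_phases <- rng(function() stats::runif(n_bits, 0, 2 * pi))
    bit_of_chip <- pmin(n_bits, 1L + (seq_len(n_chips) - 1L) %/%
                          ceiling(n_chips / n_bits))
    phases <- phases + bit_phases[bit_of_chip]
  }

  # impulse train at chip instants, shaped by the RRC pulse
  x <- complex(length.out = n_chips * sps)
  x[seq(1L, n_chips * sps, by = sps)] <- exp(1i * phases)
  h <- rrc_taps(spec$rrc_rolloff, sps)
  shaped <- conv_full(x, h)
  # align so sample 1 sits at the peak of the first chip pulse
  offset <- (length(h) - 1L) %/% 2L
  shaped <- shaped[(offset + 1L):(offset + n_samples)]

  amp <- 10^((spec$tx_power_dbm - 30) / 20)
  rms <- sqrt(mean(Mod(shaped)^2))
  if (rms > 0) shaped <- shaped * (amp / rms)

  baseband_recording(shaped, sample_rate_hz, spec$carrier_freq_hz,
                     channel = "reference", seed = seed,
                     truth = list(chip_rate_hz = sample_rate_hz / sps,
                                  bandwidth_hz = spec$bandwidth_hz))
}

# Full linear convolution via FFT (complex-safe).
conv_full <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nfft <- stats::nextn(n, 2)
  X <- stats::fft(c(x, complex(length.out = nfft - length(x))))
  H <- stats::fft(c(as.complex(h), complex(length.out = nfft - length(h))))
  out <- stats::fft(X * H, inverse = TRUE) / nfft
  out[seq_len(n)]
}

# Run `fn` under a private RNG stream seeded by `seed`, restoring the global
# RNG state afterwards. Returns a function so several draws can share the
# stream sequentially.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  function(fn) {
    outer <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    assign(".Random.seed", state, globalenv())
    out <- fn()
    state <<- get(".Random.seed", globalenv())
    if (is.null(outer)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", outer, globalenv())
    }
    out
  }
}

#' Occupied bandwidth of a recording
#'
#' Computes the two-sided bandwidth containing a given fraction of the total
#' power, from the periodogram of the samples (frequencies sorted by power,
#' accumulated until the fraction is reached; the reported value is the width
#' of the smallest centered interval covering them).
#'
#' @param rec A [baseband_recording()].
#' @param fraction Power fraction, default 0.99.
#' @return Bandwidth in Hz.
#' @export
occupied_bandwidth <- function(rec, fraction = 0.99) {
  stopifnot(inherits(rec, "baseband_recording"))
  n <- length(rec$samples)
  p <- Mod(stats::fft(rec$samples))^2
  f <- (seq_len(n) - 1) / n
  f[f >= 0.5] <- f[f >= 0.5] - 1
  f <- f * rec$sample_rate_hz
  ord <- order(abs(f))
  csum <- cumsum(p[ord]) / sum(p)
  k <- which(csum >= fraction)[1]
  2 * abs(f[ord][k])
}
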