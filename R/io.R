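IQ_FORMAT_VERSION <- "1.0"

#' Write a baseband recording to an IQ container
#'
#' Samples are stored as interleaved 32-bit little-endian floats
#' (real, imag, real, imag, ...) in `<path>.iq`, with a JSON sidecar
#' `<path>.json` holding the metadata and scene truth.
#'
#' @param rec A [baseband_recording()].
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "baseband_recording"))
  iq <- as.numeric(rbind(Re(rec$samples), Im(rec$samples)))
  con <- file(paste0(path, ".iq"), "wb")
  on.exit(close(con))
  writeBin(iq, con, size = 4, endian = "little")
  sidecar <- list(
    format_version = IQ_FORMAT_VERSION,
    channel = rec$channel,
    sample_rate_hz = rec$sample_rate_hz,
    carrier_freq_hz = rec$carrier_freq_hz,
    duration_s = rec$duration_s,
    n_samples = length(rec$samples),
    seed = rec$seed,
    truth = serializable_truth(rec$truth)
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# Drop non-serializable truth entries (functions, models) for the sidecar.
serializable_truth <- function(truth) {
  keep <- Filter(function(v) {
    is.numeric(v) || is.character(v) || is.logical(v) || is.data.frame(v)
  }, truth)
  keep
}

#' Read a baseband recording from an IQ container
#'
#' @param path Path without extension, as given to [write_recording()].
#' @return A [baseband_recording()].
#' @export
read_recording <- function(path) {
  json_path <- paste0(path, ".json")
  iq_path <- paste0(path, ".iq")
  if (!file.exists(json_path)) {
    stop("missing sidecar: ", json_path, call. = FALSE)
  }
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (field in c("channel", "sample_rate_hz", "carrier_freq_hz",
                  "n_samples")) {
    if (is.null(meta[[field]])) {
      stop("sidecar is missing required field '", field, "'", call. = FALSE)
    }
  }
  expected_bytes <- meta$n_samples * 2 * 4
  actual_bytes <- file.info(iq_path)$size
  if (is.na(actual_bytes) || actual_bytes != expected_bytes) {
    stop("IQ file size (", actual_bytes, " bytes) does not match the ",
         "sidecar sample count (expected ", expected_bytes, " bytes)",
         call. = FALSE)
  }
  con <- file(iq_path, "rb")
  on.exit(close(con))
  raw_iq <- readBin(con, what = "numeric", n = meta$n_samples * 2,
                    size = 4, endian = "little")
  samples <- complex(real = raw_iq[c(TRUE, FALSE)],
                     imaginary = raw_iq[c(FALSE, TRUE)])
  truth <- if (is.null(meta$truth)) list() else as.list(meta$truth)
  baseband_recording(samples, meta$sample_rate_hz, meta$carrier_freq_hz,
                     channel = meta$channel,
                     seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                     truth = truth)
}

#' Write a Doppler spectrogram as CSV
#'
#' Rows are Doppler bins (first column `doppler_hz`), remaining columns are
#' frames labelled with their center times.
#'
#' @param spec A `doppler_spectrogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(spec, path) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  df <- data.frame(doppler_hz = spec$doppler_axis_hz,
                   spec$D, check.names = FALSE)
  names(df)[-1] <- sprintf("t%.6g", spec$frame_times_s)
  extra <- sprintf("# integration_time_s=%.10g frame_hop_s=%.10g mode=%s bandwidth_hz=%.10g",
                   spec$config$integration_time_s, spec$config$frame_hop_s,
                   spec$config$mode, spec$config$bandwidth_hz)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(extra, con)
  utils::write.csv(format(df, digits = 17, trim = TRUE), con,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Doppler spectrogram from CSV
#'
#' @param path CSV path produced by [write_spectrogram()].
#' @return A `doppler_spectrogram`.
#' @export
read_spectrogram <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) {
    stop("not a spectrogram CSV (missing parameter header line)",
         call. = FALSE)
  }
  kv <- strsplit(trimws(sub("^#", "", header)), " ")[[1]]
  params <- stats::setNames(
    lapply(kv, function(s) strsplit(s, "=", fixed = TRUE)[[1]][2]),
    vapply(kv, function(s) strsplit(s, "=", fixed = TRUE)[[1]][1], "")
  )
  df <- utils::read.csv(path, skip = 1, check.names = FALSE)
  cfg <- caf_config(mode = params$mode,
                    integration_time_s = as.numeric(params$integration_time_s),
                    frame_hop_s = as.numeric(params$frame_hop_s),
                    bandwidth_hz = as.numeric(params$bandwidth_hz))
  structure(
    list(
      D = as.matrix(df[, -1, drop = FALSE]),
      doppler_axis_hz = df$doppler_hz,
      frame_times_s = as.numeric(sub("^t", "", names(df)[-1])),
      config = cfg
    ),
    class = "doppler_spectrogram"
  )
}

#' Write a corpus manifest as CSV
#'
#' @param corpus An [generate_experiment_corpus()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corpus_manifest <- function(corpus, path) {
  stopifnot(inherits(corpus, "activity_corpus"))
  m <- corpus$manifest
  m$file <- sprintf("scene_%03d", m$id)
  utils::write.csv(m[, c("file", "label", "subject", "repetition", "seed",
                         "speed_scale", "tempo_scale")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write the breathing-branch waveforms as CSV
#'
#' @param raw,smoothed `micro_doppler_series` before/after smoothing.
#' @param belt Optional belt data frame aligned by
#'   [evaluate_against_reference()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_breathing_csv <- function(raw, smoothed, belt = NULL, path) {
  df <- data.frame(time_s = raw$frame_times_s, psi_raw = raw$psi,
                   psi_smoothed = smoothed$psi)
  if (!is.null(belt)) {
    df$belt_resampled <- stats::approx(belt$time_s, belt$value,
                                       xout = df$time_s, rule = 2)$y
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
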