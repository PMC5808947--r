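#' Assemble a Doppler spectrogram from CAF frames
#'
#' For each CAF frame, takes the Doppler profile (column of magnitudes) at
#' the delay bin containing the frame's global maximum -- the strongest range
#' cell -- and stacks the profiles over frames.
#'
#' @param frames A list of `caf_map`s with common axes (one per frame,
#'   ordered in time).
#' @return An object of class `doppler_spectrogram`: non-negative matrix `D`
#'   (Doppler bin x frame), `doppler_axis_hz`, `frame_times_s`, `config`.
#' @export
build_spectrogram <- function(frames) {
  if (length(frames) == 0) {
    stop("cannot build a spectrogram from zero CAF frames", call. = FALSE)
  }
  ax <- frames[[1]]$doppler_axis_hz
  for (f in frames) {
    stopifnot(inherits(f, "caf_map"))
    if (!isTRUE(all.equal(f$doppler_axis_hz, ax))) {
      stop("CAF frames have mismatching Doppler axes", call. = FALSE)
    }
  }
  cols <- vapply(frames, function(f) {
    mag <- Mod(f$values)
    d_star <- arrayInd(which.max(mag), dim(mag))[1]
    mag[d_star, ]
  }, numeric(length(ax)))
  structure(
    list(
      D = matrix(cols, nrow = length(ax)),
      doppler_axis_hz = ax,
      frame_times_s = vapply(frames, `[[`, numeric(1), "frame_time_s"),
      config = frames[[1]]$config
    ),
    class = "doppler_spectrogram"
  )
}

#' @export
print.doppler_spectrogram <- function(x, ...) {
  cat(sprintf("<doppler_spectrogram: %d Doppler bins x %d frames>\n",
              nrow(x$D), ncol(x$D)))
  cat(sprintf("  Doppler +/- %.3g Hz (bin %.3g Hz), t = %.3g .. %.3g s\n",
              max(x$doppler_axis_hz), doppler_bin_hz(x),
              min(x$frame_times_s), max(x$frame_times_s)))
  invisible(x)
}

#' Doppler spectrogram of a scene
#'
#' Convenience driver: slides the integration window over the recording pair
#' at the configured frame hop, computes the batched CAF of every window,
#' optionally CLEANs each frame against the window's own self-ambiguity, and
#' assembles the spectrogram.
#'
#' Activity mode CLEANs by default (weak moving echoes must be revealed under
#' the direct path); breathing mode does not, because the micro-Doppler
#' statistic reads the respiration-induced modulation of the zero-Doppler
#' interference that CLEAN would null out.
#'
#' @param ref,surv The scene's recordings.
#' @param cfg A [caf_config()].
#' @param clean Logical; `NULL` means `TRUE` for activity mode, `FALSE` for
#'   breathing mode.
#' @param t_start_s,t_end_s Time span to process (defaults to the whole
#'   recording).
#' @return A `doppler_spectrogram`.
#' @export
scene_spectrogram <- function(ref, surv, cfg, clean = NULL,
                              t_start_s = 0, t_end_s = NULL) {
  stopifnot(inherits(cfg, "caf_config"))
  if (is.null(clean)) clean <- cfg$mode == "activity"
  if (is.null(t_end_s)) {
    t_end_s <- min(ref$duration_s, surv$duration_s)
  }
  t_frame <- cfg$integration_time_s
  if (t_end_s - t_start_s < t_frame) {
    stop("recording span shorter than one integration window", call. = FALSE)
  }
  starts <- seq(t_start_s, t_end_s - t_frame + 1e-9, by = cfg$frame_hop_s)
  seen_trim <- FALSE
  frames <- withCallingHandlers(
    lapply(starts, function(s) {
      caf <- compute_caf(ref, surv, cfg, t_start_s = s)
      if (clean) {
        caf <- clean_caf(caf, self_ambiguity(ref, cfg, t_start_s = s))
      }
      caf
    }),
    warning = function(w) {
      # every frame trims identically; report it once
      if (grepl("trimming", conditionMessage(w))) {
        if (seen_trim) invokeRestart("muffleWarning")
        seen_trim <<- TRUE
      }
    }
  )
  build_spectrogram(frames)
}

#' Motion indicator: segment a recording into static and moving periods
#'
#' Computes the per-frame Doppler power (sum of squared magnitudes over the
#' non-zero-Doppler bins, so the static direct-path residual does not
#' contribute) and thresholds it at `threshold_fraction` of the trace
#' amplitude, `min + f (max - min)`, evaluated over a rolling context window.
#' Contiguous frames of equal state are merged into segments that tile the
#' processed time span.
#'
#' The amplitude reference (max - min) is taken from the trace itself, so the
#' indicator segments a session that contains both states. A session known to
#' hold a single state has no internal contrast; for that case pass
#' `reference_range`, the power levels of a calibration context (e.g. pooled
#' over a measurement campaign, the fixed reference line of the deployed
#' system).
#'
#' @param spec A `doppler_spectrogram`.
#' @param threshold_fraction Fraction of the power-trace amplitude used as
#'   the moving/static reference level (default 0.10).
#' @param context_s Width of the rolling min/max context in seconds (default
#'   30; traces shorter than this use their global amplitude).
#' @param reference_range Optional `c(lo, hi)` external amplitude reference
#'   overriding the rolling context.
#' @return An object of class `motion_segments`: data frame `segments` with
#'   columns `start_s`, `end_s`, `state` (`"static"`/`"moving"`), plus the
#'   per-frame `power` trace and threshold parameters.
#' @export
motion_indicator <- function(spec, threshold_fraction = 0.10,
                             context_s = 30, reference_range = NULL) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  power <- doppler_power(spec)
  k <- length(power)
  tt <- spec$frame_times_s
  hop <- if (k > 1) stats::median(diff(tt)) else spec$config$frame_hop_s
  moving <- logical(k)
  if (!is.null(reference_range)) {
    thr <- reference_range[1] +
      threshold_fraction * (reference_range[2] - reference_range[1])
    moving <- power > thr
  } else {
    half <- max(1L, round(context_s / hop / 2))
    for (i in seq_len(k)) {
      win <- max(1L, i - half):min(k, i + half)
      lo <- min(power[win])
      hi <- max(power[win])
      moving[i] <- power[i] > lo + threshold_fraction * (hi - lo)
    }
  }
  runs <- rle(moving)
  ends_idx <- cumsum(runs$lengths)
  starts_idx <- c(1L, utils::head(ends_idx, -1) + 1L)
  t_half <- spec$config$integration_time_s / 2
  left_edge <- function(i) if (i == 1) tt[1] - t_half else (tt[i - 1] + tt[i]) / 2
  right_edge <- function(i) if (i == k) tt[k] + t_half else (tt[i] + tt[i + 1]) / 2
  segments <- data.frame(
    start_s = vapply(starts_idx, left_edge, numeric(1)),
    end_s = vapply(ends_idx, right_edge, numeric(1)),
    state = ifelse(runs$values, "moving", "static"),
    stringsAsFactors = FALSE
  )
  structure(
    list(segments = segments, power = power, frame_times_s = tt,
         threshold_fraction = threshold_fraction),
    class = "motion_segments"
  )
}

#' Per-frame Doppler power of a spectrogram
#'
#' Sum of squared magnitudes over the non-zero-Doppler bins of each frame
#' (the zero-Doppler bin is excluded so the static direct-path residual does
#' not contribute).
#'
#' @param spec A `doppler_spectrogram`.
#' @return Numeric vector, one power value per frame.
#' @export
doppler_power <- function(spec) {
  stopifnot(inherits(spec, "doppler_spectrogram"))
  nz <- spec$doppler_axis_hz != 0
  colSums(spec$D[nz, , drop = FALSE]^2)
}

# Scale-free motion check for a set of frames: ratio of mean to median
# non-zero-Doppler bin power. Noise-like frames give ~1-2; a Doppler ridge
# concentrates energy in few bins and pushes the ratio far above. Used by the
# pipeline to assign a state to segments when no external reference level is
# available.
segment_motion_ratio <- function(spec, frame_idx) {
  nz <- spec$doppler_axis_hz != 0
  p <- spec$D[nz, frame_idx, drop = FALSE]^2
  med <- stats::median(p)
  if (med <= 0) return(if (mean(p) > 0) Inf else 1)
  mean(p) / med
}

#' @export
print.motion_segments <- function(x, ...) {
  cat(sprintf("<motion_segments: %d segment(s)>\n", nrow(x$segments)))
  for (i in seq_len(nrow(x$segments))) {
    cat(sprintf("  %6.2f .. %6.2f s  %s\n", x$segments$start_s[i],
                x$segments$end_s[i], x$segments$state[i]))
  }
  invisible(x)
}
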