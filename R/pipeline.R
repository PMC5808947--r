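#' Pipeline configuration bundle
#'
#' Collects the per-stage configurations of the end-to-end pipeline:
#' activity- and breathing-mode CAF settings, motion-indicator threshold,
#' Savitzky-Golay smoothing, rate search band, feature/classifier settings.
#'
#' @param activity_cfg,breathing_cfg [caf_config()]s for the two modes.
#' @param threshold_fraction Motion-indicator reference fraction.
#' @param sg [sg_filter_spec()] for the breathing branch.
#' @param band_bpm Breathing-rate search band.
#' @param window_s Activity classification window length, seconds.
#' @param feature_method Default feature method for the activity branch.
#' @param svm_C,svm_kernel SVM parameters.
#' @param min_breathing_segment_s Static segments shorter than this are
#'   skipped with a warning (not enough support for rate estimation).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(activity_cfg = caf_config("activity"),
                            breathing_cfg = caf_config("breathing"),
                            threshold_fraction = 0.10,
                            sg = sg_filter_spec(),
                            band_bpm = c(6, 30),
                            window_s = 4,
                            feature_method = "SVD",
                            svm_C = 1,
                            svm_kernel = "linear",
                            min_breathing_segment_s = 10) {
  stopifnot(inherits(activity_cfg, "caf_config"),
            inherits(breathing_cfg, "caf_config"),
            inherits(sg, "sg_filter_spec"))
  if (doppler_bin_hz(breathing_cfg) >= doppler_bin_hz(activity_cfg)) {
    stop("breathing mode must have finer Doppler resolution than activity mode",
         call. = FALSE)
  }
  structure(
    list(activity_cfg = activity_cfg, breathing_cfg = breathing_cfg,
         threshold_fraction = threshold_fraction, sg = sg,
         band_bpm = band_bpm, window_s = window_s,
         feature_method = feature_method, svm_C = svm_C,
         svm_kernel = svm_kernel,
         min_breathing_segment_s = min_breathing_segment_s),
    class = "pipeline_config"
  )
}

#' Run the full sensing pipeline on one scene
#'
#' Computes the activity-mode spectrogram of the whole recording, segments
#' it with the motion indicator (each segment's state is validated with a
#' scale-free Doppler-concentration check so single-state recordings route
#' correctly), then processes every static segment with the breathing branch
#' (micro-Doppler extraction, SG smoothing, FFT rate estimate, belt
#' evaluation when the scene truth carries one) and every moving segment
#' with the activity branch (classification windows and features; labels
#' when a trained model is supplied).
#'
#' @param ref,surv The scene's recordings.
#' @param config A [pipeline_config()].
#' @param model Optional [train_ovo_svm()] model for labelling moving
#'   segments.
#' @param out_dir Optional directory; when given, spectrograms, waveforms
#'   and the run log are written there.
#' @return A list of class `pipeline_result`: `segments`, `breathing` (list
#'   of per-segment results), `activity` (windows/features/labels per moving
#'   segment), `log`.
#' @export
run_pipeline <- function(ref, surv, config = pipeline_config(),
                         model = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t_total <- system.time({
    log <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("pdsense")),
                parameters = list(
                  activity_T_s = config$activity_cfg$integration_time_s,
                  breathing_T_s = config$breathing_cfg$integration_time_s,
                  threshold_fraction = config$threshold_fraction,
                  window_s = config$window_s,
                  feature_method = config$feature_method),
                warnings = character(0), stages = list())
    result <- list(segments = NULL, breathing = list(), activity = list())

    stage <- function(name, expr) {
      t <- system.time(v <- tryCatch(expr, error = function(e) {
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }))
      log$stages[[name]] <<- unname(t["elapsed"])
      v
    }

    spec_act <- stage("activity_spectrogram", {
      scene_spectrogram(ref, surv, config$activity_cfg)
    })
    segs <- stage("motion_indicator", {
      motion_indicator(spec_act, config$threshold_fraction)
    })

    # validate each segment's state with the scale-free concentration check
    seg_df <- segs$segments
    for (i in seq_len(nrow(seg_df))) {
      idx <- which(segs$frame_times_s >= seg_df$start_s[i] &
                     segs$frame_times_s <= seg_df$end_s[i])
      if (length(idx) == 0) next
      ratio <- segment_motion_ratio(spec_act, idx)
      seg_df$state[i] <- if (ratio > 5) "moving" else "static"
    }
    # merge adjacent segments that ended up with one state
    seg_df <- merge_segments(seg_df)
    segs$segments <- seg_df
    result$segments <- segs

    dur <- min(ref$duration_s, surv$duration_s)
    for (i in seq_len(nrow(seg_df))) {
      t0 <- max(0, seg_df$start_s[i])
      t1 <- min(dur, seg_df$end_s[i])
      if (seg_df$state[i] == "static") {
        if (t1 - t0 < config$min_breathing_segment_s) {
          msg <- sprintf("static segment %.1f-%.1f s shorter than %g s; skipped",
                         t0, t1, config$min_breathing_segment_s)
          warning(msg, call. = FALSE)
          log$warnings <- c(log$warnings, msg)
          next
        }
        br <- stage(sprintf("breathing_%d", i), {
          spec_b <- scene_spectrogram(ref, surv, config$breathing_cfg,
                                      t_start_s = t0, t_end_s = t1)
          raw <- extract_micro_doppler(spec_b)
          smoothed <- sg_smooth(raw, config$sg)
          est <- estimate_rate(smoothed, band_bpm = config$band_bpm)
          belt_eval <- NULL
          if (!is.null(ref$truth$belt)) {
            belt_eval <- evaluate_against_reference(smoothed, ref$truth$belt)
          }
          list(segment = c(t0, t1), raw = raw, smoothed = smoothed,
               estimate = est, belt_eval = belt_eval)
        })
        result$breathing[[length(result$breathing) + 1]] <- br
      } else {
        act <- stage(sprintf("activity_%d", i), {
          idx <- which(spec_act$frame_times_s >= t0 &
                         spec_act$frame_times_s <= t1)
          sub <- spec_act
          sub$D <- spec_act$D[, idx, drop = FALSE]
          sub$frame_times_s <- spec_act$frame_times_s[idx]
          wins <- window_spectrogram(sub, window_s = config$window_s)
          feats <- if (config$feature_method == "PCA") {
            extract_features(wins, "PCA", basis = pca_basis(wins))
          } else {
            extract_features(wins, config$feature_method)
          }
          labels <- if (!is.null(model)) {
            as.character(predict(model, feats))
          } else {
            NULL
          }
          list(segment = c(t0, t1), windows = wins, features = feats,
               labels = labels)
        })
        result$activity[[length(result$activity) + 1]] <- act
      }
    }
  })
  log$elapsed_s <- unname(t_total["elapsed"])
  result$log <- log

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_spectrogram(spec_act, file.path(out_dir, "spectrogram_activity.csv"))
    utils::write.csv(seg_df, file.path(out_dir, "segments.csv"),
                     row.names = FALSE)
    for (i in seq_along(result$breathing)) {
      br <- result$breathing[[i]]
      belt <- ref$truth$belt
      write_breathing_csv(br$raw, br$smoothed, belt,
                          file.path(out_dir, sprintf("breathing_%d.csv", i)))
      summary <- list(rate_bpm = br$estimate$rate_bpm,
                      valid = br$estimate$valid,
                      r = if (!is.null(br$belt_eval)) br$belt_eval$r else NULL,
                      mse = if (!is.null(br$belt_eval)) br$belt_eval$mse else NULL)
      jsonlite::write_json(summary,
                           file.path(out_dir, sprintf("breathing_%d.json", i)),
                           auto_unbox = TRUE, digits = NA, null = "null")
    }
    jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  structure(result, class = "pipeline_result")
}

# Merge adjacent segments sharing a state.
merge_segments <- function(df) {
  if (nrow(df) < 2) return(df)
  keep <- list(df[1, ])
  for (i in 2:nrow(df)) {
    last <- keep[[length(keep)]]
    if (df$state[i] == last$state) {
      last$end_s <- df$end_s[i]
      keep[[length(keep)]] <- last
    } else {
      keep[[length(keep) + 1]] <- df[i, ]
    }
  }
  out <- do.call(rbind, keep)
  rownames(out) <- NULL
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$segments)
  if (length(x$breathing)) {
    for (br in x$breathing) {
      cat(sprintf("  breathing %.1f-%.1f s: ", br$segment[1], br$segment[2]))
      if (br$estimate$valid) {
        cat(sprintf("%.2f bpm", br$estimate$rate_bpm))
      } else {
        cat("invalid estimate")
      }
      if (!is.null(br$belt_eval)) cat(sprintf(" (R = %.3f)", br$belt_eval$r))
      cat("\n")
    }
  }
  for (a in x$activity) {
    cat(sprintf("  activity %.1f-%.1f s: %d window(s)%s\n",
                a$segment[1], a$segment[2], length(a$windows),
                if (!is.null(a$labels)) {
                  paste0(", labels: ", paste(a$labels, collapse = ", "))
                } else {
                  ""
                }))
  }
  invisible(x)
}
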