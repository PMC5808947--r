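# Derive a deterministic sub-seed below 2^31 from a base seed and an index.
fold_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}

#' Desk-scale illuminator spec for simulated scenes
#'
#' A [source_spec()] whose chip rate fits the scene sample rate (four samples
#' per chip), used by the scene-level generators. The full-rate 20 MHz default
#' of [source_spec()] is kept for bandwidth-level work; scenes only need the
#' waveform's correlation properties, not its absolute bandwidth.
#'
#' @param sample_rate_hz Scene sample rate in Hz.
#' @param carrier_freq_hz Carrier frequency in Hz.
#' @return A [source_spec()].
#' @export
scene_source_spec <- function(sample_rate_hz, carrier_freq_hz = 9.15e8) {
  chip <- sample_rate_hz / 4
  source_spec(
    carrier_freq_hz = carrier_freq_hz,
    bandwidth_hz = 1.25 * chip,
    chip_rate_hz = chip
  )
}

#' Simulated chest-belt reference waveform
#'
#' The ground-truth respiration reference used for evaluation: the chest-wall
#' displacement waveform sampled at the belt rate, plus optional sensor noise.
#'
#' @param chest A [chest_motion_model()].
#' @param duration_s Duration in seconds.
#' @param rate_hz Belt sample rate in Hz (chest belts are slow sensors).
#' @param noise_sd Standard deviation of additive sensor noise, in meters.
#' @param seed Seed for the noise draw.
#' @return A data frame with columns `time_s` and `value`, with the true rate
#'   attached as attribute `rate_bpm`.
#' @export
chest_belt_reference <- function(chest, duration_s, rate_hz = 5,
                                 noise_sd = 0, seed = 1L) {
  t <- seq(0, duration_s, by = 1 / rate_hz)
  v <- chest_displacement(chest, t)
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    v <- v + rng(function() stats::rnorm(length(t), sd = noise_sd))
  }
  out <- data.frame(time_s = t, value = v)
  attr(out, "rate_bpm") <- chest$rate_bpm
  out
}

# Static background: unit direct path plus `n_clutter` weaker reflections
# with geometry-random carrier phases.
static_background <- function(n_clutter, rng) {
  paths <- list(path_spec(delay_s = 0, attenuation = 1, carrier_phase_rad = 0))
  if (n_clutter > 0) {
    atts <- rng(function() stats::runif(n_clutter, 0.05, 0.25))
    phases <- rng(function() stats::runif(n_clutter, 0, 2 * pi))
    for (k in seq_len(n_clutter)) {
      paths[[k + 1]] <- path_spec(delay_s = 0, attenuation = atts[k],
                                  carrier_phase_rad = phases[k])
    }
  }
  paths
}

#' Simulate a breathing scene
#'
#' Generates the paired reference/surveillance recordings of a static scene
#' containing a breathing person: DSSS illuminator, unit direct path, a few
#' static clutter paths, the chest path, and AWGN at the requested SNR
#' (referred to the direct-path power).
#'
#' @param chest A [chest_motion_model()]; default 15 bpm sinusoid, 5 mm.
#' @param duration_s Scene length in seconds (default 30, the length of the
#'   reference measurement protocol).
#' @param range_m Chest-to-antenna distance in meters.
#' @param snr_db Surveillance-channel SNR in dB relative to the direct path.
#' @param sample_rate_hz Scene sample rate in Hz.
#' @param n_clutter Number of static clutter paths.
#' @param phase_jitter_rad Half-width of the uniform jitter applied to the
#'   chest path's quadrature carrier phase (inter-scene geometry variation).
#' @param belt_rate_hz Chest-belt sample rate for the bundled reference.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#'
#' @return A list of class `radar_scene` with elements `ref`, `surv` (both
#'   [baseband_recording()]) and `truth` (rate, chest model, belt waveform,
#'   label `"breathing"`).
#' @export
breathing_scene <- function(chest = chest_motion_model(),
                            duration_s = 30, range_m = 0.4, snr_db = 30,
                            sample_rate_hz = 2000, n_clutter = 2,
                            phase_jitter_rad = pi / 6,
                            belt_rate_hz = 5, seed = 1L) {
  spec <- scene_source_spec(sample_rate_hz)
  ref <- generate_dsss_source(spec, duration_s, sample_rate_hz,
                              seed = fold_seed(seed, 1))
  rng <- local_rng(fold_seed(seed, 2))
  statics <- static_background(n_clutter, rng)
  jit <- if (phase_jitter_rad > 0) {
    rng(function() stats::runif(1, -phase_jitter_rad, phase_jitter_rad))
  } else {
    0
  }
  chest_path <- chest_motion_path(chest, range_m = range_m,
                                  f_c = spec$carrier_freq_hz,
                                  carrier_phase_rad = -pi / 2 + jit)
  p_direct <- mean(Mod(ref$samples)^2)
  surv <- simulate_scene(ref, statics, chest_path,
                         noise_power = snr_to_noise_power(p_direct, snr_db),
                         seed = fold_seed(seed, 3))
  belt <- chest_belt_reference(chest, duration_s, rate_hz = belt_rate_hz,
                               seed = fold_seed(seed, 4))
  truth <- list(label = "breathing", rate_bpm = chest$rate_bpm,
                chest = chest, range_m = range_m, belt = belt,
                snr_db = snr_db, seed = seed)
  ref$truth <- truth
  surv$truth <- truth
  structure(list(ref = ref, surv = surv, truth = truth),
            class = "radar_scene")
}

#' Simulate an activity scene
#'
#' Paired reference/surveillance recordings of a moving person performing one
#' of the six monitored activities, over the same static background model as
#' [breathing_scene()].
#'
#' @param traj An [activity_trajectory()] or an activity label (a trajectory
#'   with default parameters is built from it).
#' @param duration_s Scene length in seconds (default 4, one classification
#'   window).
#' @param snr_db Surveillance SNR in dB relative to the direct path.
#' @param sample_rate_hz Scene sample rate in Hz.
#' @param n_clutter Number of static clutter paths.
#' @param seed Integer seed.
#' @return A list of class `radar_scene` with `ref`, `surv`, `truth` (label).
#' @export
activity_scene <- function(traj, duration_s = 4, snr_db = 20,
                           sample_rate_hz = 2000, n_clutter = 2, seed = 1L) {
  if (is.character(traj)) {
    traj <- activity_trajectory(traj, duration_s = duration_s)
  }
  stopifnot(inherits(traj, "activity_trajectory"))
  spec <- scene_source_spec(sample_rate_hz)
  ref <- generate_dsss_source(spec, duration_s, sample_rate_hz,
                              seed = fold_seed(seed, 1))
  rng <- local_rng(fold_seed(seed, 2))
  statics <- static_background(n_clutter, rng)
  phase <- rng(function() stats::runif(1, 0, 2 * pi))
  body <- activity_path(traj, f_c = spec$carrier_freq_hz,
                        carrier_phase_rad = phase)
  p_direct <- mean(Mod(ref$samples)^2)
  surv <- simulate_scene(ref, statics, body,
                         noise_power = snr_to_noise_power(p_direct, snr_db),
                         seed = fold_seed(seed, 3))
  truth <- list(label = traj$label, trajectory = traj, snr_db = snr_db,
                seed = seed)
  ref$truth <- truth
  surv$truth <- truth
  structure(list(ref = ref, surv = surv, truth = truth),
            class = "radar_scene")
}

#' @export
print.radar_scene <- function(x, ...) {
  cat(sprintf("<radar_scene: %s, %.3g s @ %.4g kHz>\n",
              x$truth$label, x$ref$duration_s,
              x$ref$sample_rate_hz / 1e3))
  invisible(x)
}

#' Generate the labelled activity corpus
#'
#' Builds the experiment design of the activity study: every activity repeated
#' `repetitions` times by each of `subjects` subjects (default 6 x 10 x 3 =
#' 180 labelled recordings). Each subject carries random speed/tempo
#' multipliers (inter-subject variation) and each repetition a smaller jitter.
#' Recordings are materialized on demand with [corpus_scene()] so that the
#' corpus object itself stays small; the manifest (file-less equivalent of a
#' recording list) is a data frame with one row per recording.
#'
#' @param activities Character vector of activity labels.
#' @param repetitions Repetitions per activity per subject.
#' @param subjects Number of subjects.
#' @param duration_s,sample_rate_hz,snr_db Scene parameters, see
#'   [activity_scene()].
#' @param seed Integer seed; the full corpus is a pure function of it.
#'
#' @return An object of class `activity_corpus` with elements `manifest`
#'   (columns `id`, `label`, `subject`, `repetition`, `seed`, `speed_scale`,
#'   `tempo_scale`) and the scene parameters.
#' @export
generate_experiment_corpus <- function(activities = ACTIVITY_LABELS,
                                       repetitions = 10, subjects = 3,
                                       duration_s = 4, sample_rate_hz = 2000,
                                       snr_db = 20, seed = 1L) {
  if (repetitions < 1 || subjects < 1 || length(activities) < 1) {
    stop("activities, repetitions and subjects must be positive",
         call. = FALSE)
  }
  if (!all(activities %in% ACTIVITY_LABELS)) {
    stop("unknown activity label(s): ",
         paste(setdiff(activities, ACTIVITY_LABELS), collapse = ", "),
         call. = FALSE)
  }
  rng <- local_rng(fold_seed(seed, 0))
  subj_speed <- rng(function() stats::rnorm(subjects, 1, 0.08))
  subj_tempo <- rng(function() stats::rnorm(subjects, 1, 0.10))
  grid <- expand.grid(repetition = seq_len(repetitions),
                      label = activities,
                      subject = seq_len(subjects),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  rep_jitter <- rng(function() stats::rnorm(n, 1, 0.03))
  manifest <- data.frame(
    id = seq_len(n),
    label = grid$label,
    subject = grid$subject,
    repetition = grid$repetition,
    seed = vapply(seq_len(n), function(i) fold_seed(seed, 10 + i), integer(1)),
    speed_scale = subj_speed[grid$subject] * rep_jitter,
    tempo_scale = subj_tempo[grid$subject],
    stringsAsFactors = FALSE
  )
  structure(
    list(manifest = manifest, duration_s = duration_s,
         sample_rate_hz = sample_rate_hz, snr_db = snr_db, seed = seed),
    class = "activity_corpus"
  )
}

#' Materialize one corpus recording
#'
#' @param corpus An [generate_experiment_corpus()] result.
#' @param i Row index into the manifest.
#' @return The [activity_scene()] for that row.
#' @export
corpus_scene <- function(corpus, i) {
  stopifnot(inherits(corpus, "activity_corpus"))
  row <- corpus$manifest[i, ]
  traj <- activity_trajectory(row$label, duration_s = corpus$duration_s,
                              speed_scale = row$speed_scale,
                              tempo_scale = row$tempo_scale)
  sc <- activity_scene(traj, duration_s = corpus$duration_s,
                       snr_db = corpus$snr_db,
                       sample_rate_hz = corpus$sample_rate_hz,
                       seed = row$seed)
  sc$truth$subject <- row$subject
  sc$truth$repetition <- row$repetition
  sc
}

#' @export
print.activity_corpus <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<activity_corpus: %d recordings (%d activities x %d reps x %d subjects)>\n",
    nrow(m), length(unique(m$label)), max(m$repetition), max(m$subject)))
  invisible(x)
}
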