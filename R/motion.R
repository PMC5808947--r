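#' Chest motion model for respiration
#'
#' Describes the periodic chest-wall displacement during breathing. The radial
#' displacement seen by the radar is `orientation_gain * displacement(t)`;
#' `orientation_gain = 1` models a subject facing the surveillance antenna,
#' smaller values model oblique orientations.
#'
#' @param rate_bpm Breathing rate in breaths per minute (normal range 12-20).
#' @param displacement_amp_m Chest-wall displacement amplitude in meters
#'   (default 5 mm).
#' @param waveform `"sinusoid"` or `"asymmetric"` (faster inhale, slower
#'   exhale, modeled as a phase-skewed sinusoid).
#' @param orientation_gain Radial projection factor in (0, 1].
#'
#' @return An object of class `chest_motion_model`.
#' @export
chest_motion_model <- function(rate_bpm = 15,
                               displacement_amp_m = 0.005,
                               waveform = c("sinusoid", "asymmetric"),
                               orientation_gain = 1) {
  waveform <- match.arg(waveform)
  if (rate_bpm <= 0) stop("rate_bpm must be positive", call. = FALSE)
  if (displacement_amp_m <= 0) {
    stop("displacement_amp_m must be positive", call. = FALSE)
  }
  if (orientation_gain <= 0 || orientation_gain > 1) {
    stop("orientation_gain must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      rate_bpm = rate_bpm,
      displacement_amp_m = displacement_amp_m,
      waveform = waveform,
      orientation_gain = orientation_gain
    ),
    class = "chest_motion_model"
  )
}

#' Chest-wall displacement waveform
#'
#' @param chest A [chest_motion_model()].
#' @param t Time vector in seconds.
#' @return Displacement in meters at the requested times (radial component,
#'   including the orientation gain). Positive = toward the antenna (inhale).
#' @export
chest_displacement <- function(chest, t) {
  w <- 2 * pi * chest$rate_bpm / 60
  base <- switch(chest$waveform,
    sinusoid = sin(w * t),
    # phase-skewed sinusoid: steeper rise (inhale), slower fall (exhale)
    asymmetric = sin(w * t + 0.35 * sin(w * t))
  )
  chest$orientation_gain * chest$displacement_amp_m * base
}

#' Propagation path of the breathing chest
#'
#' Converts a chest motion model into a dynamic [path_spec()]. The fractional
#' Doppler is the derivative of the two-way radial path length over the
#' carrier wavelength, expressed fractionally: `f_d(t) = 2 v_r(t) / c`, so the
#' instantaneous shift in Hz is `f_c f_d(t)` and alternates sign between
#' inhale and exhale. The peak shift for a sinusoid displacement is
#' `(2 g A 2 pi rate / 60) f_c / c`.
#'
#' @param chest A [chest_motion_model()].
#' @param range_m Distance chest to surveillance antenna in meters (> 0); sets
#'   the path attenuation (`0.1` at 40 cm, inverse-square two-way scaling).
#' @param f_c Carrier frequency in Hz.
#' @param carrier_phase_rad Baseband carrier phase of the chest path relative
#'   to the aggregate static field. Default `-pi / 2`, the quadrature
#'   (optimum-demodulation) point at which the zero-Doppler interference
#'   modulation is linear in displacement; `0` or `pi` are the classic null
#'   points of CW Doppler monitoring.
#' @return A [path_spec()] whose Doppler profile alternates sign at the
#'   breathing rate.
#' @export
chest_motion_path <- function(chest, range_m = 0.4, f_c = 9.15e8,
                              carrier_phase_rad = -pi / 2) {
  stopifnot(inherits(chest, "chest_motion_model"))
  if (range_m <= 0) stop("range_m must be positive", call. = FALSE)
  w <- 2 * pi * chest$rate_bpm / 60
  g <- chest$orientation_gain
  amp <- chest$displacement_amp_m
  velocity <- switch(chest$waveform,
    sinusoid = function(t) g * amp * w * cos(w * t),
    asymmetric = function(t) {
      g * amp * w * cos(w * t + 0.35 * sin(w * t)) * (1 + 0.35 * cos(w * t))
    }
  )
  att <- 0.1 * (0.4 / range_m)^2
  path_spec(
    delay_s = 2 * range_m / SPEED_OF_LIGHT,
    attenuation = att,
    doppler_profile = function(t) 2 * velocity(t) / SPEED_OF_LIGHT,
    carrier_phase_rad = carrier_phase_rad
  )
}

ACTIVITY_LABELS <- c("walking", "running", "jumping",
                     "standing", "sitting", "turning")

#' Whole-body activity trajectory
#'
#' Radial-velocity template for one of six monitored activities of daily
#' living. Walking/running/jumping are sustained (>= 1 s of motion); standing
#' up, sitting down and turning are short transients (< 1 s of motion). The
#' templates are synthetic stand-ins for measured body motion: a gait-modulated
#' trapezoid for walking, a faster/stronger variant for running, a biphasic
#' up-down profile with the widest Doppler excursion for jumping, and short
#' monotone or biphasic transients for the remaining three.
#'
#' @param label One of `"walking"`, `"running"`, `"jumping"`, `"standing"`,
#'   `"sitting"`, `"turning"`.
#' @param duration_s Total trajectory duration in seconds.
#' @param speed_scale Multiplier on the template velocity (inter-subject
#'   variation).
#' @param tempo_scale Multiplier on gait/transient rates.
#'
#' @return An object of class `activity_trajectory` with a
#'   `radial_velocity_profile` function of time (m/s, positive = toward the
#'   antenna).
#' @export
activity_trajectory <- function(label, duration_s = 4,
                                speed_scale = 1, tempo_scale = 1) {
  if (!label %in% ACTIVITY_LABELS) {
    stop("unknown activity label: ", label, call. = FALSE)
  }
  if (duration_s <= 0) stop("duration_s must be positive", call. = FALSE)
  s <- speed_scale
  q <- tempo_scale
  ramp <- function(t, t0, t1, rise = 0.4) {
    # trapezoid envelope on [t0, t1]
    pmax(0, pmin(1, (t - t0) / rise, (t1 - t) / rise))
  }
  v <- switch(label,
    walking = function(t) {
      s * ramp(t, 0.3, duration_s - 0.3) *
        (1.2 + 0.35 * sin(2 * pi * 1.8 * q * t))
    },
    running = function(t) {
      s * ramp(t, 0.2, duration_s - 0.2, rise = 0.25) *
        (2.4 + 0.7 * sin(2 * pi * 2.9 * q * t))
    },
    jumping = function(t) {
      # repeated up/down pairs, widest excursion
      s * 3.6 * ramp(t, 0.2, duration_s - 0.2, rise = 0.2) *
        sin(2 * pi * 1.1 * q * t)
    },
    standing = function(t) {
      # single rise transient, < 1 s
      s * 0.9 * exp(-((t - 0.8) / (0.18 / q))^2)
    },
    sitting = function(t) {
      -s * 0.8 * exp(-((t - 0.8) / (0.22 / q))^2)
    },
    turning = function(t) {
      # short biphasic twist
      s * 0.5 * sin(2 * pi * 1.6 * q * (t - 0.55)) *
        exp(-((t - 0.8) / (0.25 / q))^2)
    }
  )
  structure(
    list(
      label = label,
      duration_s = duration_s,
      radial_velocity_profile = v
    ),
    class = "activity_trajectory"
  )
}

#' Propagation path of a moving person
#'
#' Converts an activity trajectory into a dynamic [path_spec()] with
#' fractional Doppler `2 v(t) / c` (shift in Hz: `2 v(t) f_c / c`, about
#' 6.1 Hz per m/s at 915 MHz).
#'
#' @param traj An [activity_trajectory()].
#' @param f_c Carrier frequency in Hz.
#' @param range_m Person-to-antenna range in meters (attenuation scale only).
#' @param carrier_phase_rad Path carrier phase (default 0).
#' @return A [path_spec()].
#' @export
activity_path <- function(traj, f_c = 9.15e8, range_m = 2,
                          carrier_phase_rad = 0) {
  stopifnot(inherits(traj, "activity_trajectory"))
  v <- traj$radial_velocity_profile
  path_spec(
    delay_s = 2 * range_m / SPEED_OF_LIGHT,
    attenuation = 0.3,
    doppler_profile = function(t) 2 * v(t) / SPEED_OF_LIGHT,
    carrier_phase_rad = carrier_phase_rad
  )
}
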