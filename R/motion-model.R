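# Kinematic model of the mechanical thorax phantom: a marker on an arm that
# rotates at constant angular speed from 0 to 90 degrees and back, holding a
# "respiratory pause" at each extremum.  Displacement along the motion axis is
# therefore a quarter-sine rise, a plateau, a mirrored fall and a baseline
# plateau -- the plateau-topped waveform produced by the stepper-driven rig
# this module emulates.

#' Breathing motion parameters
#'
#' Parameter set for the modified-sine motion law used by the digital phantom:
#' a quarter-sine rise over half of the free-breathing time, a pause at full
#' inhale, a mirrored quarter-sine fall and a pause at full exhale.
#'
#' @param frequency_bpm Breathing frequency in breaths per minute. Must be
#'   positive; 30 bpm corresponds to 0.5 Hz.
#' @param amplitude_mm Peak displacement in millimetres (>= 0).
#' @param pause_s Duration in seconds of the respiratory pause held at each
#'   extremum (>= 0). The cycle period `60 / frequency_bpm` must exceed
#'   `2 * pause_s` so that some time is left for actual motion.
#' @param n_cycles Optional number of cycles, used by helpers that derive a
#'   default sequence duration.
#' @param phase_offset_s Start offset in seconds; the cycle is evaluated at
#'   `t + phase_offset_s`.
#'
#' @return An object of class `motion_params`.
#' @seealso [modified_sine_displacement()], [peak_speed()]
#' @export
#' @examples
#' p <- motion_params(frequency_bpm = 30, amplitude_mm = 50, pause_s = 0.33)
#' modified_sine_displacement(c(0, 0.335, 0.67), p)
motion_params <- function(frequency_bpm, amplitude_mm, pause_s = 0,
                          n_cycles = NULL, phase_offset_s = 0) {
  stopifnot(is.numeric(frequency_bpm), length(frequency_bpm) == 1L,
            is.numeric(amplitude_mm), length(amplitude_mm) == 1L,
            is.numeric(pause_s), length(pause_s) == 1L,
            is.numeric(phase_offset_s), length(phase_offset_s) == 1L)
  if (!is.finite(frequency_bpm) || frequency_bpm <= 0)
    stop("'frequency_bpm' must be a positive finite number")
  if (!is.finite(amplitude_mm) || amplitude_mm < 0)
    stop("'amplitude_mm' must be non-negative")
  if (!is.finite(pause_s) || pause_s < 0)
    stop("'pause_s' must be non-negative")
  period_s <- 60 / frequency_bpm
  if (period_s <= 2 * pause_s)
    stop("cycle period 60/frequency_bpm must exceed 2 * pause_s")
  if (!is.null(n_cycles)) {
    stopifnot(is.numeric(n_cycles), length(n_cycles) == 1L, n_cycles > 0)
  }
  structure(
    list(frequency_bpm = frequency_bpm,
         amplitude_mm = amplitude_mm,
         pause_s = pause_s,
         n_cycles = n_cycles,
         phase_offset_s = phase_offset_s,
         period_s = period_s),
    class = "motion_params")
}

#' @export
print.motion_params <- function(x, ...) {
  cat(sprintf(
    "Modified-sine motion: %.3g bpm (T = %.3g s), amplitude %.3g mm, pause %.3g s\n",
    x$frequency_bpm, x$period_s, x$amplitude_mm, x$pause_s))
  cat(sprintf("Design-envelope peak speed 2fa = %.3g mm/s\n", peak_speed(x)))
  invisible(x)
}

#' Modified-sine displacement of the phantom
#'
#' Displacement of the phantom marker along its motion axis at time `t`.
#' Within each cycle of period `T = 60/frequency_bpm` the marker rises as
#' `a * sin(theta)` with `theta` growing linearly from 0 to pi/2 over
#' `r = (T - 2 * pause_s) / 2` seconds, holds at `a` for `pause_s`, falls along
#' the mirrored quarter-sine, and holds at 0 for `pause_s`. The output is
#' always in `[0, amplitude_mm]` and the function is continuous and exactly
#' periodic.
#'
#' @param t Time(s) in seconds, non-negative; vectorized.
#' @param params A [motion_params()] object.
#'
#' @return Displacement in millimetres, same length as `t`.
#' @export
modified_sine_displacement <- function(t, params) {
  stopifnot(inherits(params, "motion_params"), is.numeric(t))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative")
  a <- params$amplitude_mm
  T <- params$period_s
  p <- params$pause_s
  r <- (T - 2 * p) / 2
  tt <- (t + params$phase_offset_s) %% T
  d <- numeric(length(tt))
  rise <- tt < r
  d[rise] <- a * sin(pi / 2 * tt[rise] / r)
  hold <- tt >= r & tt < r + p
  d[hold] <- a
  fall <- tt >= r + p & tt < 2 * r + p
  d[fall] <- a * sin(pi / 2 * (2 * r + p - tt[fall]) / r)
  # remaining samples lie in the exhale pause and stay at 0
  d
}

#' Worst-case design speed 2fa
#'
#' The design-envelope bound on marker speed, `2 * f * a` with the breathing
#' frequency `f` expressed in Hz. It is the mean speed of a full excursion
#' (amplitude `a` covered twice per cycle) and is used to label scenarios
#' against the tracking design envelope; the instantaneous peak of the
#' modified-sine law is higher by a factor `(pi/2) / (1 - 2 * pause_s / T)`.
#'
#' @param params A [motion_params()] object.
#' @return Speed in mm/s.
#' @export
#' @examples
#' peak_speed(motion_params(30, 50)) # 50 mm/s = 5 cm/s
peak_speed <- function(params) {
  stopifnot(inherits(params, "motion_params"))
  2 * (params$frequency_bpm / 60) * params$amplitude_mm
}

#' Quantize displacement to a stepper grid
#'
#' Rounds displacement to the nearest multiple of `step_size_mm`, emulating
#' the granularity of the stepper motor that drives the physical phantom.
#' A step size of 0 disables quantization.
#'
#' @param displacement_mm Numeric displacement(s) in mm.
#' @param step_size_mm Step granularity in mm (>= 0).
#' @return Quantized displacement(s), same length as input.
#' @export
quantize_motion <- function(displacement_mm, step_size_mm) {
  stopifnot(is.numeric(displacement_mm), is.numeric(step_size_mm),
            length(step_size_mm) == 1L)
  if (!is.finite(step_size_mm) || step_size_mm < 0)
    stop("'step_size_mm' must be non-negative")
  if (step_size_mm == 0) return(displacement_mm)
  round(displacement_mm / step_size_mm) * step_size_mm
}

#' Piecewise breathing pattern
#'
#' Concatenates several [motion_params()] segments, each run for a whole
#' number of cycles, into one continuous breathing pattern (every segment
#' starts and ends at baseline, so the concatenation has no jumps). Time past
#' the final segment rests at baseline. Used to emulate volunteer recordings
#' in which amplitude and rate change every few breaths.
#'
#' @param ... [motion_params()] objects, each with `n_cycles` set.
#' @return An object of class `motion_pattern`.
#' @export
#' @examples
#' pat <- motion_pattern(
#'   motion_params(12, 20, 0.33, n_cycles = 2),
#'   motion_params(25, 5, 0.33, n_cycles = 4))
#' pattern_duration(pat)
motion_pattern <- function(...) {
  segments <- list(...)
  if (length(segments) == 1L && is.list(segments[[1L]]) &&
      !inherits(segments[[1L]], "motion_params"))
    segments <- segments[[1L]]
  if (length(segments) < 1L) stop("at least one segment is required")
  for (s in segments) {
    if (!inherits(s, "motion_params"))
      stop("all segments must be 'motion_params' objects")
    if (is.null(s$n_cycles))
      stop("every segment needs 'n_cycles' to fix its duration")
  }
  durations <- vapply(segments, function(s) s$n_cycles * s$period_s, 0)
  structure(list(segments = segments, durations = durations,
                 boundaries = cumsum(durations)),
            class = "motion_pattern")
}

#' Total duration of a breathing pattern
#' @param pattern A [motion_pattern()] object.
#' @return Duration in seconds.
#' @export
pattern_duration <- function(pattern) {
  stopifnot(inherits(pattern, "motion_pattern"))
  sum(pattern$durations)
}

#' Evaluate a motion law at given times
#'
#' Dispatches on the motion description: a single [motion_params()] cycle
#' model, a piecewise [motion_pattern()], or an arbitrary `function(t)`
#' returning millimetres.
#'
#' @param t Times in seconds (vectorized, >= 0).
#' @param motion A `motion_params`, `motion_pattern` or function.
#' @return Displacement in mm.
#' @export
motion_displacement <- function(t, motion) {
  if (inherits(motion, "motion_params"))
    return(modified_sine_displacement(t, motion))
  if (inherits(motion, "motion_pattern")) {
    if (any(!is.finite(t)) || any(t < 0))
      stop("'t' must be finite and non-negative")
    d <- numeric(length(t))
    starts <- c(0, motion$boundaries[-length(motion$boundaries)])
    for (i in seq_along(motion$segments)) {
      in_seg <- t >= starts[i] & t < motion$boundaries[i]
      if (any(in_seg))
        d[in_seg] <- modified_sine_displacement(t[in_seg] - starts[i],
                                                motion$segments[[i]])
    }
    return(d)  # past the last segment: baseline rest
  }
  if (is.function(motion)) return(motion(t))
  stop("'motion' must be motion_params, motion_pattern or a function(t)")
}

#' Peak amplitude of a motion description
#' @param motion A `motion_params`, `motion_pattern` or function evaluated on
#'   a dense grid as a fallback.
#' @param duration_s Grid length used for the function fallback.
#' @return Amplitude in mm.
#' @keywords internal
motion_amplitude <- function(motion, duration_s = 60) {
  if (inherits(motion, "motion_params")) return(motion$amplitude_mm)
  if (inherits(motion, "motion_pattern"))
    return(max(vapply(motion$segments, function(s) s$amplitude_mm, 0)))
  max(motion(seq(0, duration_s, by = 0.005)))
}
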