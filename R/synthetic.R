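# Synthetic tri-axial signal generation: sinusoidal movement content,
# piecewise-constant activity profiles with Gaussian noise, gravity as a
# +1 g DC offset on z, out-of-band tremor overlays, clipped to the +/-8 g
# sensor range of typical wrist-worn devices.

SENSOR_RANGE_G <- 8

#' Generate a sinusoidal tri-axial test signal
#'
#' Identical sinusoid on all three axes plus a constant 1 g gravity
#' component on the z axis. Deterministic.
#'
#' @param freq_hz sinusoid frequency in Hz; must be below `fs/2`.
#' @param amplitude_g amplitude in g (>= 0).
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds (> 0).
#' @param phase_rad initial phase in radians.
#' @return A [raw_accel()] in g.
#' @examples
#' gen_sinusoid(1, 0.5, fs = 100, duration_s = 60)
#' @export
gen_sinusoid <- function(freq_hz, amplitude_g, fs, duration_s,
                         phase_rad = 0) {
  if (freq_hz >= fs / 2)
    stop_invalid("freq_hz must be below Nyquist (", fs / 2, " Hz)")
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  if (amplitude_g < 0) stop_invalid("amplitude_g must be nonnegative")
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  s <- amplitude_g * sin(2 * pi * freq_hz * t + phase_rad)
  raw_accel(s, s, s + 1, fs = fs, units = "g")
}

#' Activity segment specification
#'
#' One piece of a piecewise-constant activity profile: sinusoidal movement
#' content at `carrier_hz` with amplitude `amplitude_g`, additive white
#' Gaussian noise of standard deviation `noise_sd_g`, distributed over the
#' axes by `axis_weights`.
#'
#' @param duration_s segment duration in seconds (> 0).
#' @param carrier_hz movement frequency in Hz.
#' @param amplitude_g movement amplitude in g (>= 0).
#' @param noise_sd_g noise standard deviation in g (>= 0).
#' @param axis_weights three nonnegative weights applied to the x, y, z
#'   movement component.
#' @return An object of class `activity_segment`.
#' @export
activity_segment <- function(duration_s, carrier_hz, amplitude_g,
                             noise_sd_g = 0, axis_weights = c(1, 1, 1)) {
  if (duration_s <= 0) stop_invalid("duration_s must be positive")
  if (amplitude_g < 0 || noise_sd_g < 0)
    stop_invalid("amplitude_g and noise_sd_g must be nonnegative")
  if (length(axis_weights) != 3L || any(axis_weights < 0))
    stop_invalid("axis_weights must be three nonnegative numbers")
  structure(list(duration_s = duration_s, carrier_hz = carrier_hz,
                 amplitude_g = amplitude_g, noise_sd_g = noise_sd_g,
                 axis_weights = axis_weights),
            class = "activity_segment")
}

#' Generate a piecewise-constant activity profile
#'
#' Concatenates [activity_segment()]s into one tri-axial recording: per
#' segment, a sinusoid at the segment's carrier frequency and amplitude on
#' each axis (weighted), plus seeded white Gaussian noise; 1 g gravity on z;
#' the result is clipped to the +/-8 g sensor range. Bit-reproducible for a
#' fixed seed.
#'
#' @param segments list of [activity_segment()]s (at least one).
#' @param fs sampling rate in Hz.
#' @param seed integer seed for the noise generator.
#' @return A [raw_accel()] in g.
#' @examples
#' segs <- list(activity_segment(60, 1, 0.1), activity_segment(60, 1, 0.5))
#' gen_profile(segs, fs = 30, seed = 1)
#' @export
gen_profile <- function(segments, fs, seed = 1L) {
  if (!is.list(segments) || length(segments) == 0L)
    stop_invalid("segments must be a non-empty list of activity_segment")
  if (inherits(segments, "activity_segment")) segments <- list(segments)
  ax <- ay <- az <- numeric(0)
  with_seed(seed, {
    for (seg in segments) {
      stopifnot(inherits(seg, "activity_segment"))
      if (seg$carrier_hz >= fs / 2)
        stop_invalid("segment carrier_hz must be below Nyquist")
      t <- seq(0, seg$duration_s - 1 / fs, by = 1 / fs)
      s <- seg$amplitude_g * sin(2 * pi * seg$carrier_hz * t)
      n <- length(t)
      noise <- function() if (seg$noise_sd_g > 0)
        stats::rnorm(n, 0, seg$noise_sd_g) else numeric(n)
      ax <- c(ax, seg$axis_weights[1] * s + noise())
      ay <- c(ay, seg$axis_weights[2] * s + noise())
      az <- c(az, seg$axis_weights[3] * s + noise())
    }
  })
  clip <- function(x) pmin(pmax(x, -SENSOR_RANGE_G), SENSOR_RANGE_G)
  raw_accel(clip(ax), clip(ay), clip(az + 1), fs = fs, units = "g")
}

#' Overlay an out-of-band tremor component
#'
#' Adds a sinusoid at `tremor_hz` (typically 4-6 Hz, outside the default
#' movement passband) to all three axes of an existing signal, for
#' demonstrating that narrowing the modifiable filter's upper cutoff removes
#' tremor-attributable counts.
#'
#' @param base a [raw_accel()].
#' @param tremor_hz tremor frequency in Hz; must be below `fs/2`.
#' @param amplitude_g tremor amplitude in g; 0 returns `base` unchanged.
#' @param phase_rad initial phase in radians.
#' @return A [raw_accel()] clipped to the +/-8 g sensor range.
#' @export
gen_tremor_overlay <- function(base, tremor_hz, amplitude_g,
                               phase_rad = 0) {
  stopifnot(inherits(base, "raw_accel"))
  if (tremor_hz >= base$fs / 2)
    stop_invalid("tremor_hz must be below Nyquist (", base$fs / 2, " Hz)")
  if (amplitude_g == 0) return(base)
  base <- to_g(base)
  t <- (seq_along(base$ax) - 1) / base$fs
  s <- amplitude_g * sin(2 * pi * tremor_hz * t + phase_rad)
  clip <- function(x) pmin(pmax(x, -SENSOR_RANGE_G), SENSOR_RANGE_G)
  raw_accel(clip(base$ax + s), clip(base$ay + s), clip(base$az + s),
            fs = base$fs, units = "g", start_time = base$start_time)
}
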