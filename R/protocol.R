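#' Recording protocol for a simulated IMU session
#'
#' Describes the structure and sensor characteristics of one recording:
#' an initial standstill (used downstream for gravity calibration), an
#' optional leading walk segment, an acceleration ramp into steady trot,
#' the steady trot itself, a deceleration ramp and optional trailing walk
#' segments.
#'
#' @param surface One of `"treadmill"`, `"soft"`, `"hard"`.
#' @param n_trot_strides Number of steady-state trot strides (>= 1).
#' @param walk_segments Numeric vector of walk durations in seconds; the
#'   first element precedes the trot, any further elements follow it.
#'   `numeric(0)` omits walking entirely.
#' @param ramp_strides Number of acceleration/deceleration strides flanking
#'   the steady trot, with stride duration interpolated linearly between
#'   the walk and trot values.
#' @param sample_rate Sampling frequency in Hz.
#' @param noise_sd_gyro Gaussian noise sd per gyroscope sample, deg/s.
#' @param noise_sd_accel Gaussian noise sd per accelerometer sample, g.
#' @param gyro_bias Constant additive gyroscope bias, deg/s (exercises the
#'   drift handling of the orientation integrator).
#' @param standstill_duration Seconds of standstill at the start (>= 0).
#' @param walk_stride_duration Walk stride duration in seconds.
#' @param walk_rom_scale Multiplier applied to the trot ranges of motion
#'   during walk segments.
#' @param seed Integer seed for the sensor noise; expanded into one
#'   sub-stream per sensor so streams are independently reproducible.
#' @return An object of class `session_protocol`.
#' @export
#' @examples
#' session_protocol(n_trot_strides = 20, noise_sd_gyro = 2, seed = 1)
session_protocol <- function(surface = c("treadmill", "soft", "hard"),
                             n_trot_strides = 25,
                             walk_segments = c(5, 3),
                             ramp_strides = 3,
                             sample_rate = 102.4,
                             noise_sd_gyro = 0,
                             noise_sd_accel = 0,
                             gyro_bias = 0,
                             standstill_duration = 10,
                             walk_stride_duration = 1.1,
                             walk_rom_scale = 0.6,
                             seed = NULL) {
  surface <- match.arg(surface)
  if (n_trot_strides < 1) {
    abort_eg("`n_trot_strides` must be at least 1.", "equigait_error_parameter")
  }
  if (sample_rate <= 0) {
    abort_eg("`sample_rate` must be positive.", "equigait_error_parameter")
  }
  if (standstill_duration < 0) {
    abort_eg("`standstill_duration` must be non-negative.",
             "equigait_error_parameter")
  }
  if (noise_sd_gyro < 0 || noise_sd_accel < 0) {
    abort_eg("Noise standard deviations must be non-negative.",
             "equigait_error_parameter")
  }
  if (ramp_strides < 0) {
    abort_eg("`ramp_strides` must be non-negative.", "equigait_error_parameter")
  }
  structure(
    list(
      surface = surface,
      n_trot_strides = as.integer(n_trot_strides),
      walk_segments = as.numeric(walk_segments),
      ramp_strides = as.integer(ramp_strides),
      sample_rate = sample_rate,
      noise_sd_gyro = noise_sd_gyro,
      noise_sd_accel = noise_sd_accel,
      gyro_bias = gyro_bias,
      standstill_duration = standstill_duration,
      walk_stride_duration = walk_stride_duration,
      walk_rom_scale = walk_rom_scale,
      seed = seed
    ),
    class = "session_protocol"
  )
}

#' @export
print.session_protocol <- function(x, ...) {
  cat("<session_protocol> ", x$surface,
      ": ", x$standstill_duration, " s standstill, ",
      length(x$walk_segments), " walk segment(s), ",
      x$ramp_strides, "+", x$ramp_strides, " ramp strides, ",
      x$n_trot_strides, " trot strides @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}
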