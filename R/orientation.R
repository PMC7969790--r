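#' Gravity calibration from a standstill window
#'
#' Estimates the sensor's initial tilt from the mean accelerometer vector
#' over the standstill window at the start of a recording (the horse stands
#' still so the accelerometers see only gravity), and the gyroscope bias as
#' the mean angular velocity over the same window.
#'
#' The sensor frame is right-handed with x along the lateromedial axis
#' (sagittal rotation), y craniocaudal (coronal rotation) and z
#' proximodistal; gravity is `(0, 0, -1)` g at zero tilt. Sagittal tilt is
#' `atan2(ax, -az)` and coronal tilt `atan2(-ay, -az)` of the mean
#' acceleration, in degrees.
#'
#' @param stream Tibble with columns `gx_dps`, `gy_dps`, `gz_dps`, `ax_g`,
#'   `ay_g`, `az_g` (one sensor), e.g. from [session_stream()].
#' @param standstill Integer vector `c(first, last)` of sample indices of
#'   the standstill window.
#' @param sample_rate Sampling frequency in Hz; the window must span at
#'   least one second.
#' @return List with `sagittal_deg`, `coronal_deg` and `gyro_bias` (named
#'   vector of per-axis bias in deg/s).
#' @export
calibrate_orientation <- function(stream, standstill, sample_rate = 102.4) {
  idx <- seq.int(standstill[1], standstill[2])
  if (length(idx) < sample_rate) {
    abort_eg("Standstill window must span at least one second.",
             "equigait_error_calibration")
  }
  a <- c(mean(stream$ax_g[idx]), mean(stream$ay_g[idx]), mean(stream$az_g[idx]))
  if (sqrt(sum(a^2)) < 0.5) {
    abort_eg("Mean standstill acceleration is far from 1 g; cannot define the gravitational vector.",
             "equigait_error_calibration")
  }
  list(
    sagittal_deg = atan2(a[1], -a[3]) * 180 / pi,
    coronal_deg = atan2(-a[2], -a[3]) * 180 / pi,
    gyro_bias = c(
      gx = mean(stream$gx_dps[idx]),
      gy = mean(stream$gy_dps[idx]),
      gz = mean(stream$gz_dps[idx])
    )
  )
}

#' Integrate angular velocity into segment orientation
#'
#' Cumulative trapezoidal integration of the bias-corrected rotation
#' velocities about the lateromedial (sagittal) and craniocaudal (coronal)
#' axes, started from the calibrated initial tilt. Drift from residual
#' bias is handled downstream by per-stride detrending (see
#' [spatial_variables()]).
#'
#' @param stream Tibble with `time_s`, `gx_dps`, `gy_dps` columns.
#' @param calibration Result of [calibrate_orientation()], or a list with
#'   the same fields.
#' @return Tibble (`orientation_series`) with `time_s`, `sagittal_deg`,
#'   `coronal_deg`.
#' @export
integrate_orientation <- function(stream,
                                  calibration = list(sagittal_deg = 0,
                                                     coronal_deg = 0,
                                                     gyro_bias = c(gx = 0, gy = 0, gz = 0))) {
  b <- calibration$gyro_bias
  tibble::tibble(
    time_s = stream$time_s,
    sagittal_deg = calibration$sagittal_deg +
      pracma::cumtrapz(stream$time_s, stream$gx_dps - b[["gx"]])[, 1],
    coronal_deg = calibration$coronal_deg +
      pracma::cumtrapz(stream$time_s, stream$gy_dps - b[["gy"]])[, 1]
  )
}
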