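make_standstill_stream <- function(accel, n = 256, gyro = c(0, 0, 0)) {
  tibble::tibble(
    time_s = (seq_len(n) - 1) / 102.4,
    gx_dps = gyro[1], gy_dps = gyro[2], gz_dps = gyro[3],
    ax_g = accel[1], ay_g = accel[2], az_g = accel[3]
  )
}

test_that("gravity-aligned and tilted standstills calibrate exactly", {
  flat <- calibrate_orientation(make_standstill_stream(c(0, 0, -1)),
                                c(1, 256))
  expect_equal(flat$sagittal_deg, 0)
  expect_equal(flat$coronal_deg, 0)

  tilted <- calibrate_orientation(
    make_standstill_stream(c(sin(10 * pi / 180), 0, -cos(10 * pi / 180))),
    c(1, 256)
  )
  expect_equal(tilted$sagittal_deg, 10, tolerance = 1e-10)

  biased <- calibrate_orientation(
    make_standstill_stream(c(0, 0, -1), gyro = c(0.4, -0.2, 0.1)), c(1, 256)
  )
  expect_equal(unname(biased$gyro_bias), c(0.4, -0.2, 0.1))
})

test_that("noisy standstill calibrates to within half a degree", {
  withr::with_seed(21, {
    n <- 1024
    truth <- 7
    s <- make_standstill_stream(c(sin(truth * pi / 180), 0,
                                  -cos(truth * pi / 180)), n = n)
    s$ax_g <- s$ax_g + rnorm(n, 0, 0.01)
    s$ay_g <- s$ay_g + rnorm(n, 0, 0.01)
    s$az_g <- s$az_g + rnorm(n, 0, 0.01)
    cal <- calibrate_orientation(s, c(1, n))
    expect_lt(abs(cal$sagittal_deg - truth), 0.5)
    expect_lt(abs(cal$coronal_deg), 0.5)
  })
})

test_that("degenerate standstills are rejected", {
  expect_error(
    calibrate_orientation(make_standstill_stream(c(0, 0, 0)), c(1, 256)),
    class = "equigait_error_calibration"
  )
  expect_error(
    calibrate_orientation(make_standstill_stream(c(0, 0, -1)), c(1, 50)),
    class = "equigait_error_calibration"
  )
})

test_that("integration reproduces closed-form angles", {
  fs <- 102.4
  t <- seq(0, 2, by = 1 / fs)
  const <- tibble::tibble(time_s = t, gx_dps = 10, gy_dps = 0)
  ang <- integrate_orientation(const)
  expect_equal(ang$sagittal_deg[length(t)], 10 * t[length(t)],
               tolerance = 1e-10)

  # A * sin(2 pi f t) integrates to amplitude A / (2 pi f)
  A <- 36 * pi; f <- 1.368
  t <- seq(0, 5, by = 1 / fs)
  sine <- tibble::tibble(time_s = t, gx_dps = A * sin(2 * pi * f * t),
                         gy_dps = 0)
  ang <- integrate_orientation(sine)
  half_range <- diff(range(ang$sagittal_deg)) / 2
  expect_equal(half_range, A / (2 * pi * f), tolerance = 0.01)
})

test_that("constant gyro bias leaves detrended ROM essentially unchanged", {
  p <- horse_profile()
  clean <- make_trot_session(p, n_trot = 10)
  biased <- make_trot_session(p, n_trot = 10, bias = 1)
  # defeat the standstill bias estimate so integration really drifts
  rec_rom <- function(ses, zero_bias) {
    stream <- session_stream(ses, "L_tibia")
    cal <- calibrate_orientation(stream, ses$standstill)
    if (zero_bias) cal$gyro_bias <- c(gx = 0, gy = 0, gz = 0)
    ori <- integrate_orientation(stream, cal)
    lh <- integrate_orientation(
      session_stream(ses, "LH_mt"),
      calibrate_orientation(session_stream(ses, "LH_mt"), ses$standstill)
    )
    strides <- segment_strides(lh, ses$sample_rate)
    win <- select_window(strides)
    spatial_variables(ori$sagittal_deg, strides, win)
  }
  expect_lt(
    abs(rec_rom(biased, zero_bias = TRUE) / rec_rom(clean, zero_bias = FALSE) - 1),
    0.01
  )
})
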