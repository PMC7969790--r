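test_that("noise-free trot segments into strides of the programmed duration", {
  ses <- make_trot_session(horse_profile(), n_trot = 20)
  lh <- session_stream(ses, "LH_mt")
  ori <- integrate_orientation(
    lh, calibrate_orientation(lh, ses$standstill, ses$sample_rate)
  )
  strides <- segment_strides(ori, ses$sample_rate)
  expect_equal(length(strides$durations), 19)
  expect_true(all(abs(strides$durations - 0.731) <= 1 / ses$sample_rate))
  expect_true(all(diff(strides$boundaries) > 0))
})

test_that("flat signals cannot be segmented", {
  expect_error(segment_strides(rep(0, 1000)),
               class = "equigait_error_segmentation")
  expect_error(segment_strides(tibble::tibble(sagittal_deg = rep(3, 500))),
               class = "equigait_error_segmentation")
})

test_that("boundaries are strictly increasing for noisy inputs", {
  for (s in 1:5) {
    ses <- make_trot_session(horse_profile(), n_trot = 12,
                             noise_gyro = 5, seed = s)
    lh <- session_stream(ses, "LH_mt")
    ori <- integrate_orientation(
      lh, calibrate_orientation(lh, ses$standstill, ses$sample_rate)
    )
    strides <- segment_strides(ori, ses$sample_rate)
    expect_true(all(diff(strides$boundaries) > 0))
  }
})

test_that("window selection finds the steady run and enforces the minimum", {
  steady <- fake_stride_series(rep(0.731, 20))
  expect_equal(select_window(steady), 1:20)

  short <- fake_stride_series(rep(0.731, 4))
  expect_error(select_window(short), class = "equigait_error_selection")

  # linear accel/decel ramps at both ends exceed the CV bound and drop out
  ramped <- fake_stride_series(c(
    seq(1.1, 0.76, length.out = 4), rep(0.731, 10),
    seq(0.76, 1.1, length.out = 4)
  ))
  win <- select_window(ramped, cv_threshold = 0.02)
  expect_equal(win, 5:14)
})

test_that("manual windows are validated, not searched", {
  s <- fake_stride_series(rep(0.731, 20))
  expect_equal(select_window(s, window = c(3, 9)), 3:9)
  expect_error(select_window(s, window = c(0, 9)),
               class = "equigait_error_selection")
  expect_error(select_window(s, window = c(3, 30)),
               class = "equigait_error_selection")
  expect_error(select_window(s, window = c(3, 5)),
               class = "equigait_error_selection")
})

test_that("representative stride matches the brute-force SSD oracle", {
  # all identical -> tie broken to the first stride of the window
  flat <- matrix(rep(sin(2 * pi * (0:99) / 100), each = 6), nrow = 6,
                 byrow = FALSE)
  expect_equal(representative_stride(flat, 2:6), 2)

  # one outlier among identical cycles -> any identical stride, first wins
  out <- flat
  out[4, ] <- out[4, ] + 5
  expect_equal(representative_stride(out, 1:5), 1)

  withr::with_seed(33, {
    for (rep_i in 1:10) {
      cyc <- matrix(rnorm(8 * 100), nrow = 8)
      win <- sort(sample(8, sample(3:8, 1)))
      expect_equal(representative_stride(cyc, win),
                   oracle_representative(cyc, win))
    }
  })
  expect_error(representative_stride(flat, 3),
               class = "equigait_error_input")
})

test_that("gait classification separates trot, walk and unknown patterns", {
  expect_equal(classify_gait(c(LF = 63, RF = 14, RH = 50)), "trot")
  expect_equal(classify_gait(c(LF = 63.1, RF = 13.7, RH = 49.5)), "trot")
  expect_equal(classify_gait(c(LF = 75, RF = 25, RH = 50)), "walk")
  expect_equal(classify_gait(c(LF = 40, RF = 40, RH = 40)), "unknown")
  expect_error(classify_gait(c(LF = 63, RF = 14)),
               class = "equigait_error_input")
})
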