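test_that("noise-free sessions recover every programmed variable", {
  # 1% of stride for phases/event timings, 2% relative for magnitudes;
  # the symmetry index is checked absolutely when the true index is small
  # (a near-zero denominator makes relative error meaningless)
  pct_vars <- grep("phasing|protraction|retraction",
                   gait_variable_names(), value = TRUE)
  mag_vars <- setdiff(gait_variable_names(), c(pct_vars, "symmetry_hock"))
  for (s in 1:20) {
    p <- simulate_horse_profile(seed = 100 + s,
                                horse_id = sprintf("H%02d", s))
    rec <- extract_record(make_trot_session(p, n_trot = 12))
    tr <- profile_truth(p)
    for (v in pct_vars) {
      expect_lt(circ_abs(rec[[v]], tr[[v]]), 1)
    }
    for (v in mag_vars) {
      expect_lt(abs(rec[[v]] / tr[[v]] - 1), 0.02)
    }
    sym_err <- abs(rec$symmetry_hock - tr$symmetry_hock)
    expect_true(sym_err / max(tr$symmetry_hock, 5) < 0.02 || sym_err < 0.1)
  }
})

test_that("records carry their design metadata", {
  rec <- extract_record(make_trot_session(n_trot = 8),
                        evaluator_id = "E4", repetition = 2)
  expect_equal(rec$evaluator_id, "E4")
  expect_equal(rec$repetition, 2L)
  expect_gte(rec$n_strides_evaluated, 5)
  expect_true(all(gait_variable_names() %in% names(rec)))
})

test_that("walk-only recordings are refused as trot windows", {
  ses <- simulate_session(horse_profile(), session_protocol(
    n_trot_strides = 1, walk_segments = 14, ramp_strides = 0,
    standstill_duration = 2
  ))
  expect_error(extract_record(ses), class = "equigait_error_selection")
})

test_that("different windows on a periodic session agree", {
  ses <- make_trot_session(horse_profile(), n_trot = 14)
  prep <- prepare_session(ses)
  a <- extract_record(prep, window = c(2, 8))
  b <- extract_record(prep, window = c(5, 11))
  for (v in gait_variable_names()) {
    expect_lt(abs(a[[v]] - b[[v]]), 0.1)
  }
})

test_that("worse sensor noise never improves worst-case phase recovery", {
  noise_levels <- c(0, 5, 25, 100)
  mean_worst <- vapply(noise_levels, function(ns) {
    errs <- vapply(1:20, function(s) {
      p <- simulate_horse_profile(seed = 500 + s)
      rec <- tryCatch(
        extract_record(make_trot_session(p, n_trot = 10,
                                         noise_gyro = ns, seed = s)),
        equigait_error = function(e) NULL
      )
      # a failed extraction is the worst possible phase outcome
      if (is.null(rec)) return(50)
      tr <- profile_truth(p)
      max(
        circ_abs(rec$limb_phasing_LF, tr$limb_phasing_LF),
        circ_abs(rec$limb_phasing_RF, tr$limb_phasing_RF),
        circ_abs(rec$limb_phasing_RH, tr$limb_phasing_RH)
      )
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_worst) >= -1e-9))
})
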