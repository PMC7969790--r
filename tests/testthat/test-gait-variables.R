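test_that("cross-correlation phasing recovers constructed shifts", {
  ref <- sin(2 * pi * (0:99) / 100) + 0.3 * sin(4 * pi * (0:99) / 100)
  same <- limb_phasing(list(LH = ref, LF = ref))
  expect_equal(same$phase_pct[same$limb == "LF"], 0)

  shifted <- c(ref[76:100], ref[1:75]) # delayed by a quarter cycle
  ph <- limb_phasing(list(LH = ref, RH = shifted))
  expect_equal(ph$phase_pct[ph$limb == "RH"], 25)

  expect_error(limb_phasing(list(LH = ref, LF = rep(1, 100))),
               class = "equigait_error_phase")
  expect_error(limb_phasing(list(LF = ref)), class = "equigait_error_input")
})

test_that("phase differences are invariant to a common rotation", {
  withr::with_seed(17, {
    base <- sin(2 * pi * (0:99) / 100) + 0.2 * cos(4 * pi * (0:99) / 100)
    rot <- function(x, k) if (k == 0) x else c(x[(k + 1):100], x[1:k])
    for (i in 1:10) {
      k1 <- sample(0:99, 1); k2 <- sample(0:99, 1); shift <- sample(0:99, 1)
      cyc <- list(LH = rot(base, k1), LF = rot(base, k2))
      p0 <- limb_phasing(cyc)$phase_pct[2]
      cyc_shift <- list(LH = rot(cyc$LH, shift), LF = rot(cyc$LF, shift))
      p1 <- limb_phasing(cyc_shift)$phase_pct[2]
      expect_equal(p0 %% 100, p1 %% 100)
    }
  })
})

test_that("event timing finds extrema at and between grid points", {
  grid <- (0:99) / 100
  cyc <- cos(2 * pi * grid)
  ev <- temporal_variables(cyc, durations = rep(0.731, 5))
  expect_equal(ev$protraction_pct, 0)
  expect_equal(ev$retraction_pct, 50)
  expect_equal(ev$stride_duration, 0.731)

  peaked <- cos(2 * pi * (grid - 0.18))
  expect_equal(temporal_variables(peaked, 1)$protraction_pct, 18)

  off_grid <- cos(2 * pi * (grid - 0.176))
  expect_lt(abs(temporal_variables(off_grid, 1)$protraction_pct - 17.6), 0.05)

  expect_error(temporal_variables(rep(1, 100), 1),
               class = "equigait_error_event")
})

test_that("protraction recoding folds the late half-cycle", {
  expect_identical(recode_protraction(c(98, 96, 94)), c(2, 4, 6))
  expect_identical(recode_protraction(6), 6)
  # recoding is idempotent: already-mapped values pass through unchanged
  for (p in c(98, 96, 94)) {
    expect_identical(recode_protraction(recode_protraction(p)),
                     recode_protraction(p))
  }
  expect_error(recode_protraction(100), class = "equigait_error_input")
  expect_error(recode_protraction(-1), class = "equigait_error_input")
})

test_that("range of motion is exact for sinusoids and offset-invariant", {
  fs <- 102.4
  t <- seq(0, 10 * 0.8, by = 1 / fs)
  angle <- 10 * sin(2 * pi * t / 0.8)
  strides <- fake_stride_series(rep(0.8, 9), fs)
  expect_equal(spatial_variables(angle, strides, 1:9), 20, tolerance = 0.005)
  expect_equal(
    spatial_variables(angle + 57, strides, 1:9),
    spatial_variables(angle, strides, 1:9)
  )
  expect_equal(spatial_variables(rep(4, length(t)), strides, 1:9), 0)
  expect_error(spatial_variables(angle, strides, integer(0)),
               class = "equigait_error_input")
})

test_that("the symmetry index follows its defining formula", {
  expect_equal(symmetry_index(40, 40), 0)
  expect_equal(symmetry_index(30, 20), 40)
  expect_equal(symmetry_index(42.093, 37.160), 12.4487, tolerance = 1e-4)
  expect_equal(symmetry_index(20, 30), symmetry_index(30, 20))
  expect_error(symmetry_index(1, -1), class = "equigait_error_input")
})
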