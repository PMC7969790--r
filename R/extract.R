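#' Precompute the stride-level decomposition of a session
#'
#' Runs the evaluator-independent part of the extraction exactly once per
#' session: gravity calibration and orientation integration for all six
#' sensors, stride segmentation on the left hind metatarsal sensor (whose
#' maximal retraction defines the session zero point), and resampling of
#' every sensor's lateromedial velocity and sagittal/coronal angle onto
#' the per-stride cycle grid. [extract_record()] then only needs the
#' (evaluator-specific) window choice, which makes simulating many
#' evaluators on the same recording cheap.
#'
#' @param session An [simulate_session()] result or a session read with
#'   [read_session()].
#' @param n_grid Cycle grid resolution (default 100 points, 1% of stride).
#' @return An object of class `session_prep`.
#' @export
prepare_session <- function(session, n_grid = 100) {
  stopifnot(inherits(session, "imu_session"))
  if (is.null(session$standstill)) {
    abort_eg("Session has no standstill window; cannot calibrate.",
             "equigait_error_calibration")
  }
  placements <- names(sensor_segments())
  per <- purrr::map(stats::setNames(placements, placements), function(p) {
    stream <- session_stream(session, p)
    cal <- calibrate_orientation(stream, session$standstill,
                                 session$sample_rate)
    ori <- integrate_orientation(stream, cal)
    list(stream = stream, calibration = cal, orientation = ori)
  })
  # segment only the motion part: the standstill sits at the retraction
  # angle level and would otherwise contribute spurious zero-point events
  start <- session$standstill[2] + 1L
  strides <- segment_strides(
    per$LH_mt$orientation$sagittal_deg[-seq_len(start - 1L)],
    session$sample_rate
  )
  strides$boundaries <- strides$boundaries + start - 1L
  vel_cycles <- purrr::map(per, function(x) {
    stride_cycles(x$stream$gx_dps - x$calibration$gyro_bias[["gx"]],
                  strides, n_grid)
  })
  angle_cycles <- purrr::map(per, function(x) {
    stride_cycles(x$orientation$sagittal_deg, strides, n_grid)
  })
  structure(
    list(
      horse_id = session$horse_id,
      surface = session$surface,
      truth = session$truth,
      strides = strides,
      sensors = per,
      vel_cycles = vel_cycles,
      angle_cycles = angle_cycles,
      n_grid = n_grid
    ),
    class = "session_prep"
  )
}

# Sample-domain event timing: locate the sagittal-angle extremum of one
# stride directly on the sampled series, refine to sub-sample precision
# with a quadratic fit, and express it as percent of the (sub-sample
# refined) stride span. Avoids the cycle-grid quantisation of
# `temporal_variables()` where sub-percent precision matters.
event_pct_sample <- function(angle, strides, i, sense = c("pro", "ret")) {
  sense <- match.arg(sense)
  b <- strides$boundaries
  off <- strides$boundary_offsets
  idx <- b[i]:(b[i + 1L] - 1L)
  y <- if (sense == "pro") angle else -angle
  g <- idx[which.max(y[idx])]
  delta <- if (g > 1L && g < length(y)) {
    den <- y[g - 1L] - 2 * y[g] + y[g + 1L]
    if (abs(den) < .Machine$double.eps * 100) 0 else {
      max(min(0.5 * (y[g - 1L] - y[g + 1L]) / den, 0.5), -0.5)
    }
  } else 0
  start <- b[i] + off[i]
  end <- b[i + 1L] + off[i + 1L]
  wrap_pct((g + delta - start) / (end - start) * 100)
}

# Events are positions on the circular [0, 100) cycle; fold positions
# within `margin` percent of the cycle end onto the origin so a variable
# pinned at the stride boundary stays continuous (0.3 and 99.7 are the
# same event timing to within measurement jitter). The 2% default covers
# one sample period plus sub-sample refinement at 102.4 Hz trot.
fold_boundary_pct <- function(p, margin = 2) {
  ifelse(p > 100 - margin, 100 - p, p)
}

#' Extract the analysed gait variables from one session
#'
#' Runs the full extraction chain — calibration, orientation integration,
#' stride segmentation on the left hind zero point, steady-window
#' selection, representative-stride choice by minimal squared difference
#' (pooled over the six lateromedial velocity cycles), limb phasing by
#' circular cross-correlation, protraction/retraction event timing (with
#' the late-cycle protraction recoding), sagittal and coronal ranges of
#' motion and the hock symmetry index — and returns the 19 analysed
#' variables as one table row. Errors if the selected window does not
#' contain steady trot.
#'
#' @param session An [simulate_session()] result, a session read with
#'   [read_session()], or a [prepare_session()] object (cheapest when
#'   extracting repeatedly from the same recording).
#' @param evaluator_id,repetition Metadata recorded in the output row.
#' @param min_strides Minimum strides the analysis window must contain.
#' @param cv_threshold Stride-duration coefficient-of-variation bound for
#'   the automatic steady-window search.
#' @param window Optional explicit stride range `c(first, last)` (manual
#'   evaluator window).
#' @param n_grid Cycle grid resolution (ignored for prepared sessions).
#' @return One-row tibble: `horse_id`, `surface`, `evaluator_id`,
#'   `repetition`, `n_strides_evaluated` and the columns of
#'   [gait_variable_names()].
#' @export
#' @examples
#' ses <- simulate_session(horse_profile(), session_protocol(seed = 1))
#' extract_record(ses)
extract_record <- function(session, evaluator_id = "E1", repetition = 1L,
                           min_strides = 5, cv_threshold = 0.05,
                           window = NULL, n_grid = 100) {
  prep <- if (inherits(session, "session_prep")) {
    session
  } else {
    prepare_session(session, n_grid)
  }
  win <- select_window(prep$strides, min_strides, cv_threshold, window)
  rep_idx <- representative_stride(prep$vel_cycles, win)

  phases <- limb_phasing(list(
    LH = prep$vel_cycles$LH_mt[rep_idx, ],
    LF = prep$vel_cycles$LF_mc[rep_idx, ],
    RF = prep$vel_cycles$RF_mc[rep_idx, ],
    RH = prep$vel_cycles$RH_mt[rep_idx, ]
  ))
  ph <- stats::setNames(phases$phase_pct, phases$limb)
  if (classify_gait(ph[c("LF", "RF", "RH")]) != "trot") {
    abort_eg("Selected window is not steady trot.", "equigait_error_selection")
  }

  ev <- purrr::map(
    list(mt_L = "LH_mt", mt_R = "RH_mt", mc_L = "LF_mc", mc_R = "RF_mc"),
    function(p) {
      ang <- prep$sensors[[p]]$orientation$sagittal_deg
      list(
        protraction_pct = event_pct_sample(ang, prep$strides, rep_idx, "pro"),
        retraction_pct = event_pct_sample(ang, prep$strides, rep_idx, "ret"),
        stride_duration = mean(prep$strides$durations[win])
      )
    }
  )
  rom <- function(placement, channel) {
    spatial_variables(prep$sensors[[placement]]$orientation[[channel]],
                      prep$strides, win)
  }
  rom_hock_L <- rom("L_tibia", "sagittal_deg")
  rom_hock_R <- rom("R_tibia", "sagittal_deg")

  tibble::tibble(
    horse_id = prep$horse_id,
    surface = prep$surface,
    evaluator_id = evaluator_id,
    repetition = as.integer(repetition),
    n_strides_evaluated = length(win),
    stride_duration = ev$mt_L$stride_duration,
    limb_phasing_LF = ph[["LF"]],
    limb_phasing_RF = ph[["RF"]],
    limb_phasing_RH = ph[["RH"]],
    protraction_mt_L = recode_protraction(ev$mt_L$protraction_pct),
    protraction_mt_R = recode_protraction(ev$mt_R$protraction_pct),
    protraction_mc_L = recode_protraction(ev$mc_L$protraction_pct),
    protraction_mc_R = recode_protraction(ev$mc_R$protraction_pct),
    retraction_mt_L = fold_boundary_pct(ev$mt_L$retraction_pct),
    retraction_mt_R = fold_boundary_pct(ev$mt_R$retraction_pct),
    rom_sag_hock_L = rom_hock_L,
    rom_sag_hock_R = rom_hock_R,
    rom_sag_fore_cannon_L = rom("LF_mc", "sagittal_deg"),
    rom_sag_fore_cannon_R = rom("RF_mc", "sagittal_deg"),
    rom_cor_fore_cannon_L = rom("LF_mc", "coronal_deg"),
    rom_cor_fore_cannon_R = rom("RF_mc", "coronal_deg"),
    rom_cor_hind_cannon_L = rom("LH_mt", "coronal_deg"),
    rom_cor_hind_cannon_R = rom("RH_mt", "coronal_deg"),
    symmetry_hock = symmetry_index(rom_hock_L, rom_hock_R)
  )
}
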