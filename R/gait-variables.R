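#' Limb phasing by circular cross-correlation
#'
#' Computes each limb's temporal phase lag relative to the reference limb
#' (left hind by convention) as the circular cross-correlation lag, in
#' percent of stride, that best aligns the limb's lateromedial
#' rotation-velocity cycle with the reference cycle. The reference limb
#' maps to 0 exactly; ties resolve to the smallest lag.
#'
#' @param cycles Named list of numeric vectors — one representative cycle
#'   per limb on a common `N`-point grid (same stride boundaries for all
#'   sensors).
#' @param reference Name of the reference cycle (default `"LH"`).
#' @return Tibble with columns `limb` and `phase_pct` in `[0, 100)`.
#' @export
#' @examples
#' ref <- sin(2 * pi * (0:99) / 100)
#' limb_phasing(list(LH = ref, RH = c(ref[51:100], ref[1:50])))
limb_phasing <- function(cycles, reference = "LH") {
  if (!reference %in% names(cycles)) {
    abort_eg("Reference cycle missing from `cycles`.", "equigait_error_input")
  }
  n <- length(cycles[[reference]])
  ref <- cycles[[reference]] - mean(cycles[[reference]])
  if (stats::sd(ref) < 1e-12) {
    abort_eg("Reference cycle has zero variance; phase undefined.",
             "equigait_error_phase")
  }
  phases <- purrr::imap_dbl(cycles, function(x, limb) {
    if (limb == reference) return(0)
    if (length(x) != n) {
      abort_eg("All cycles must share one grid length.", "equigait_error_input")
    }
    x <- x - mean(x)
    if (stats::sd(x) < 1e-12) {
      abort_eg("Cycle has zero variance; phase undefined.",
               "equigait_error_phase")
    }
    cc <- vapply(0:(n - 1L), function(k) {
      sum(x * ref[((seq_len(n) - 1L - k) %% n) + 1L])
    }, numeric(1))
    (which.max(cc) - 1L) * 100 / n
  })
  tibble::tibble(limb = names(cycles), phase_pct = unname(phases))
}

#' Temporal event variables of a stride cycle
#'
#' Locates the maximal protraction (sagittal-angle maximum) and maximal
#' retraction (minimum) events on a representative angle cycle, in percent
#' of stride from the session zero point, plus the mean stride duration of
#' the analysis window. Extremum positions are refined to sub-grid
#' precision with a three-point quadratic fit, so event timings are not
#' quantised to the cycle grid.
#'
#' @param angle_cycle Numeric vector: one representative sagittal-angle
#'   cycle on the `N`-point grid.
#' @param durations Stride durations in seconds (from
#'   [segment_strides()]).
#' @param window Integer stride indices over which the stride duration is
#'   averaged (default: all strides).
#' @return List with `protraction_pct` (raw, see [recode_protraction()]),
#'   `retraction_pct` and `stride_duration` in seconds.
#' @export
temporal_variables <- function(angle_cycle, durations,
                               window = seq_along(durations)) {
  n <- length(angle_cycle)
  if (diff(range(angle_cycle)) < 1e-9) {
    abort_eg("Flat angle cycle: no protraction/retraction events.",
             "equigait_error_event")
  }
  event_pos <- function(y, idx) {
    wrap_pct((idx - 1L + parabolic_offset(y, idx)) * 100 / n)
  }
  list(
    protraction_pct = event_pos(angle_cycle, which.max(angle_cycle)),
    retraction_pct = event_pos(-angle_cycle, which.min(angle_cycle)),
    stride_duration = mean(durations[window])
  )
}

#' Recode late-cycle protraction timing
#'
#' Maximal protraction is expressed as a percentage of the stride
#' duration; events falling in the second half of the cycle are recoded to
#' their distance from the cycle end, so that 98% becomes 2%, 96% becomes
#' 4% and 94% becomes 6%. Values at or below 50 pass through unchanged.
#'
#' @param p Numeric vector of percentages in `[0, 100)`.
#' @return Recoded percentages.
#' @export
#' @examples
#' recode_protraction(c(98, 96, 94, 6))
recode_protraction <- function(p) {
  if (any(p < 0 | p >= 100)) {
    abort_eg("Percentages must lie in [0, 100).", "equigait_error_input")
  }
  ifelse(p > 50, 100 - p, p)
}

#' Per-stride ranges of motion
#'
#' Computes the range (max minus min) of a segment angle within each
#' stride of the analysis window and averages across the window. By
#' default each stride is first linearly detrended by subtracting the line
#' through its boundary values, which removes integration drift from
#' residual gyroscope bias while leaving a periodic signal untouched. The
#' result is invariant to adding any constant to the angle series.
#'
#' @param angle Numeric vector: a segment angle series in degrees (e.g.
#'   `sagittal_deg` of [integrate_orientation()]).
#' @param strides A [segment_strides()] result.
#' @param window Integer stride indices (from [select_window()]).
#' @param detrend Per-stride endpoint-pinned linear detrend (default on).
#' @return Mean range of motion in degrees over the window's strides.
#' @export
spatial_variables <- function(angle, strides, window, detrend = TRUE) {
  if (length(window) < 1L) {
    abort_eg("Empty analysis window.", "equigait_error_input")
  }
  b <- strides$boundaries
  roms <- vapply(window, function(i) {
    idx <- b[i]:b[i + 1L]
    seg <- angle[idx]
    if (detrend) {
      seg <- seg - seq(seg[1L], seg[length(seg)], length.out = length(seg))
    }
    diff(range(seg))
  }, numeric(1))
  mean(roms)
}

#' Left-right symmetry index
#'
#' Absolute difference between the left and right limb values divided by
#' the mean of both, in percent. Identical limbs give 0.
#'
#' @param left,right Positive measurements (e.g. hock ranges of motion in
#'   degrees).
#' @return Symmetry index in percent.
#' @export
#' @examples
#' symmetry_index(30, 20) # 40
symmetry_index <- function(left, right) {
  m <- (left + right) / 2
  if (any(m <= 0)) {
    abort_eg("Symmetry undefined for non-positive mean values.",
             "equigait_error_input")
  }
  abs(left - right) / m * 100
}
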