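#' Segment a sagittal-angle series into strides
#'
#' Detects the stride zero-point events — the per-cycle extrema of the
#' sagittal angle in the retraction sense (minima under this package's
#' sign convention, where protraction is positive) — and cuts the series
#' into half-open strides `[b_i, b_{i+1})`. Intended for the left hind
#' metatarsal sensor, whose maximal retraction defines the stride zero
#' point for the whole session.
#'
#' Detection is a local-extremum search on a lightly smoothed copy of the
#' signal: candidate minima deeper than the signal midrange are kept and
#' thinned to a minimum separation of half the median candidate spacing
#' (deepest first).
#'
#' @param orientation An orientation series from [integrate_orientation()],
#'   or any data frame with a `sagittal_deg` column, or a bare numeric
#'   vector of angles.
#' @param sample_rate Sampling frequency in Hz.
#' @param smooth_samples Width of the moving-average pre-smoother.
#' @param min_separation Fraction of the median candidate spacing used as
#'   the minimum event separation.
#' @return An object of class `stride_series`: list with integer
#'   `boundaries` (sample indices of successive zero-point events),
#'   `durations` in seconds (one fewer than the boundaries) and
#'   `sample_rate`.
#' @export
segment_strides <- function(orientation, sample_rate = 102.4,
                            smooth_samples = 5, min_separation = 0.5) {
  x <- if (is.numeric(orientation)) {
    orientation
  } else {
    orientation$sagittal_deg
  }
  if (length(x) < 4L || diff(range(x)) < 1e-8) {
    abort_eg("No stride events detectable: signal is too short or flat.",
             "equigait_error_segmentation")
  }
  xs <- roll_mean(x, smooth_samples)
  d <- diff(xs)
  cand <- which(d[-length(d)] < 0 & d[-1] >= 0) + 1L
  # only genuine retraction extrema: below the signal midrange
  cand <- cand[xs[cand] < min(xs) + 0.45 * diff(range(xs))]
  if (length(cand) < 2L) {
    abort_eg("Fewer than two stride zero-point events detected.",
             "equigait_error_segmentation")
  }
  min_sep <- min_separation * stats::median(diff(cand))
  keep <- integer(0)
  for (i in cand[order(xs[cand])]) {
    if (!length(keep) || all(abs(keep - i) >= min_sep)) keep <- c(keep, i)
  }
  boundaries <- sort(keep)
  if (length(boundaries) < 2L) {
    abort_eg("Fewer than two stride zero-point events detected.",
             "equigait_error_segmentation")
  }
  # sub-sample refinement of each zero-point event (quadratic fit around
  # the detected minimum of the unsmoothed signal); boundaries stay
  # integer for cutting, the fractional offsets let event timings be
  # corrected to sub-sample precision downstream
  boundaries <- vapply(boundaries, function(b) {
    lo <- max(1L, b - 3L); hi <- min(length(x), b + 3L)
    (lo:hi)[which.min(x[lo:hi])]
  }, integer(1))
  boundaries <- unique(boundaries)
  offsets <- vapply(boundaries, function(b) parabolic_offset(-x, b),
                    numeric(1))
  structure(
    list(
      boundaries = boundaries,
      boundary_offsets = offsets,
      durations = diff(boundaries) / sample_rate,
      sample_rate = sample_rate
    ),
    class = "stride_series"
  )
}

#' @export
print.stride_series <- function(x, ...) {
  cat("<stride_series> ", length(x$durations), " strides, median duration ",
      format(stats::median(x$durations), digits = 4), " s\n", sep = "")
  invisible(x)
}

#' Resample a signal into per-stride cycles on a fixed grid
#'
#' Cuts `signal` at the stride boundaries and linearly resamples each
#' half-open stride onto `n_grid` equally spaced points of the normalised
#' cycle, yielding the strides x grid matrix used for representative-stride
#' selection, limb phasing and event timing.
#'
#' @param signal Numeric vector sampled at the series' rate (an angle or
#'   rotation-velocity channel).
#' @param strides A [segment_strides()] result (its boundaries are shared
#'   across all sensors of a session).
#' @param n_grid Number of cycle grid points (default 100, i.e. 1% of
#'   stride resolution).
#' @return Numeric matrix with one row per stride.
#' @export
stride_cycles <- function(signal, strides, n_grid = 100) {
  b <- strides$boundaries
  n_strides <- length(b) - 1L
  out <- matrix(NA_real_, n_strides, n_grid)
  grid <- seq(0, 1, length.out = n_grid + 1L)[seq_len(n_grid)]
  for (i in seq_len(n_strides)) {
    idx <- b[i]:b[i + 1L]
    u <- seq(0, 1, length.out = length(idx))
    out[i, ] <- stats::approx(u, signal[idx], xout = grid)$y
  }
  out
}

#' Select a steady-state analysis window of strides
#'
#' Finds the longest contiguous run of strides whose stride-duration
#' coefficient of variation stays at or below `cv_threshold`; acceleration
#' and deceleration ramps (where the duration changes stride to stride)
#' are thereby excluded. A minimum of `min_strides` strides is required —
#' the canonical minimum for a representative kinematic evaluation is
#' five. An explicit `window` (manual evaluator choice) is validated
#' instead of searched for.
#'
#' @param strides A [segment_strides()] result.
#' @param min_strides Minimum acceptable run length (default 5).
#' @param cv_threshold Maximum coefficient of variation of the stride
#'   durations within the run.
#' @param window Optional explicit integer range `c(first, last)` of
#'   stride indices (manual mode).
#' @return Integer vector of stride indices (class `numeric`), suitable
#'   for indexing rows of [stride_cycles()] matrices.
#' @export
select_window <- function(strides, min_strides = 5, cv_threshold = 0.05,
                          window = NULL) {
  d <- strides$durations
  n <- length(d)
  if (!is.null(window)) {
    if (window[1] < 1 || window[2] > n || window[1] > window[2]) {
      abort_eg("Manual window out of range.", "equigait_error_selection")
    }
    w <- seq.int(window[1], window[2])
    if (length(w) < min_strides) {
      abort_eg(sprintf("Manual window has fewer than %d strides.", min_strides),
               "equigait_error_selection")
    }
    return(w)
  }
  best <- integer(0)
  for (i in seq_len(n)) {
    for (j in i:n) {
      len <- j - i + 1L
      if (len <= length(best)) next
      if (cv(d[i:j]) <= cv_threshold) best <- seq.int(i, j)
    }
  }
  # trim residual accel/decel strides at the run edges: drop boundary
  # strides whose duration deviates from the run median by more than the
  # CV threshold (relative), as at the beginning/end of a trot phase
  while (length(best) > 1L &&
         abs(d[best[1L]] / stats::median(d[best]) - 1) > cv_threshold) {
    best <- best[-1L]
  }
  while (length(best) > 1L &&
         abs(d[best[length(best)]] / stats::median(d[best]) - 1) > cv_threshold) {
    best <- best[-length(best)]
  }
  if (length(best) < min_strides) {
    abort_eg(sprintf(
      "No steady run of at least %d strides (coefficient of variation <= %g).",
      min_strides, cv_threshold
    ), "equigait_error_selection")
  }
  best
}

#' Pick the most representative stride of a window
#'
#' Returns the stride whose resampled cycle has the smallest summed
#' squared difference against all other strides of the window — the
#' "minimal square difference" representative-stride rule. Ties resolve
#' to the lowest stride index.
#'
#' @param cycles Strides x grid matrix from [stride_cycles()], or a list
#'   of such matrices (pooled by column-binding, e.g. the lateromedial
#'   velocity cycles of all six sensors).
#' @param window Integer stride indices from [select_window()].
#' @return A single stride index (relative to the full stride series).
#' @export
representative_stride <- function(cycles, window) {
  if (is.list(cycles)) cycles <- do.call(cbind, cycles)
  if (length(window) < 2L) {
    abort_eg("Representative-stride selection needs at least two strides.",
             "equigait_error_input")
  }
  m <- cycles[window, , drop = FALSE]
  d2 <- as.matrix(stats::dist(m))^2
  window[which.min(rowSums(d2))]
}

#' Classify gait from recovered limb phases
#'
#' Matches the phase pattern of the LF, RF and RH limbs (relative to the
#' left hind zero point) against the trot and walk templates. Trot: the
#' diagonal pairs move together — RF close to LH (offset near 0%), LF
#' close to RH, and the two diagonals half a stride apart (RH near 50%).
#' Walk: the four footfall events are close to evenly spaced (every gap
#' near 25%). Anything else is `"unknown"`.
#'
#' @param phases Named numeric vector with elements `LF`, `RF`, `RH`
#'   (percent of stride).
#' @param tol_diagonal Tolerance in percent of stride for the diagonal
#'   synchrony checks (default 20: wide enough to accommodate the diagonal
#'   advanced placement of sound trotting horses, where a forelimb trails
#'   its diagonal hindlimb by some 10-18% of stride, while still rejecting
#'   the 25% offsets of walk).
#' @param tol_walk Tolerance around the 25% spacing of walk.
#' @return `"trot"`, `"walk"` or `"unknown"`.
#' @export
#' @examples
#' classify_gait(c(LF = 63, RF = 14, RH = 50)) # trot
#' classify_gait(c(LF = 75, RF = 25, RH = 50)) # walk
classify_gait <- function(phases, tol_diagonal = 20, tol_walk = 10) {
  if (!all(c("LF", "RF", "RH") %in% names(phases))) {
    abort_eg("`phases` must name LF, RF and RH.", "equigait_error_input")
  }
  lf <- phases[["LF"]]; rf <- phases[["RF"]]; rh <- phases[["RH"]]
  is_trot <- circ_dist_pct(rf, 0) <= tol_diagonal &&
    circ_dist_pct(lf, rh) <= tol_diagonal &&
    circ_dist_pct(rh, 50) <= tol_diagonal
  if (is_trot) return("trot")
  gaps <- diff(c(sort(c(0, lf, rf, rh) %% 100), 100))
  if (all(abs(gaps - 25) <= tol_walk)) return("walk")
  "unknown"
}
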