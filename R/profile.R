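#' Kinematic profile of a single horse at trot
#'
#' A `horse_profile` holds the ground-truth kinematics from which an IMU
#' session is synthesised: stride duration, the phase of each limb's cycle
#' relative to the stride zero point (maximal retraction of the left hind
#' metatarsus, so LH is 0 by definition), the within-stride timing of the
#' maximal protraction/retraction events, and the sagittal/coronal ranges
#' of motion of the instrumented segments.
#'
#' Unless given explicitly, event timings are derived from the limb phases:
#' each limb reaches maximal retraction at its own phase and maximal
#' protraction `swing_offset` percent of stride later. Keeping this common
#' offset across limbs makes all limb waveforms time-shifted copies of one
#' shape, so that phases are identified exactly by cross-correlation.
#'
#' @param horse_id Identifier string.
#' @param stride_duration Trot stride duration in seconds (> 0).
#' @param speed Nominal speed in m/s (metadata only).
#' @param limb_phases Named vector, percent of stride in `[0, 100)` for
#'   `LF`, `RF`, `RH` relative to the left-hind zero point.
#' @param swing_offset Percent of stride from maximal retraction to maximal
#'   protraction of the same limb.
#' @param protraction_events,retraction_events Optional named vectors over
#'   `LF`, `RF`, `LH`, `RH` (percent of stride, raw i.e. not recoded);
#'   default derived from `limb_phases` and `swing_offset`.
#' @param sagittal_rom Named vector of sagittal ranges of motion in degrees:
#'   `hock_L`, `hock_R`, `fore_cannon_L`, `fore_cannon_R`, `hind_cannon_L`,
#'   `hind_cannon_R`.
#' @param coronal_rom Named vector of coronal (mediolateral) ranges of
#'   motion in degrees: `fore_cannon_L`, `fore_cannon_R`, `hind_cannon_L`,
#'   `hind_cannon_R`, `hock_L`, `hock_R`.
#' @param harmonic Relative amplitude (in `[0, 0.25]`) of the second
#'   harmonic added to the fundamental angle waveform; `0` gives a pure
#'   sinusoid. Values up to 0.25 leave the range of motion and the extremum
#'   positions of the waveform unchanged in closed form.
#' @return An object of class `horse_profile`.
#' @seealso [simulate_horse_profile()], [simulate_session()]
#' @export
#' @examples
#' horse_profile(stride_duration = 0.731)
horse_profile <- function(horse_id = "H01",
                          stride_duration = 0.731,
                          speed = 3.3,
                          limb_phases = c(LF = 63.097, RF = 13.654, RH = 49.460),
                          swing_offset = 60,
                          protraction_events = NULL,
                          retraction_events = NULL,
                          sagittal_rom = c(
                            hock_L = 42.093, hock_R = 37.160,
                            fore_cannon_L = 85.107, fore_cannon_R = 86.177,
                            hind_cannon_L = 60, hind_cannon_R = 60
                          ),
                          coronal_rom = c(
                            fore_cannon_L = 12.920, fore_cannon_R = 20.567,
                            hind_cannon_L = 13.816, hind_cannon_R = 14.317,
                            hock_L = 8, hock_R = 8
                          ),
                          harmonic = 0.15) {
  if (!is.numeric(stride_duration) || stride_duration <= 0) {
    abort_eg("`stride_duration` must be a positive number.",
             "equigait_error_parameter")
  }
  need <- c("LF", "RF", "RH")
  if (!all(need %in% names(limb_phases))) {
    abort_eg("`limb_phases` must name LF, RF and RH.",
             "equigait_error_parameter")
  }
  phases <- c(LH = 0, limb_phases[need])
  names(phases) <- c("LH", need)
  if (any(phases < 0 | phases >= 100)) {
    abort_eg("Limb phases must lie in [0, 100).", "equigait_error_parameter")
  }
  if (is.null(retraction_events)) {
    retraction_events <- phases
  }
  if (is.null(protraction_events)) {
    protraction_events <- wrap_pct(phases + swing_offset)
  }
  limbs <- c("LH", "LF", "RF", "RH")
  for (ev in list(protraction_events, retraction_events)) {
    if (!all(limbs %in% names(ev)) || any(ev < 0 | ev >= 100)) {
      abort_eg("Event timings must cover all four limbs and lie in [0, 100).",
               "equigait_error_parameter")
    }
  }
  if (any(sagittal_rom <= 0) || any(coronal_rom <= 0)) {
    abort_eg("Ranges of motion must be positive.", "equigait_error_parameter")
  }
  if (harmonic < 0 || harmonic > 0.25) {
    abort_eg("`harmonic` must lie in [0, 0.25].", "equigait_error_parameter")
  }
  structure(
    list(
      horse_id = horse_id,
      stride_duration = stride_duration,
      speed = speed,
      limb_phases = phases,
      swing_offset = swing_offset,
      protraction_events = protraction_events[limbs],
      retraction_events = retraction_events[limbs],
      sagittal_rom = sagittal_rom,
      coronal_rom = coronal_rom,
      harmonic = harmonic
    ),
    class = "horse_profile"
  )
}

#' @export
print.horse_profile <- function(x, ...) {
  cat("<horse_profile> ", x$horse_id,
      "  stride ", format(x$stride_duration), " s",
      "  phases LF/RF/RH = ",
      paste(format(x$limb_phases[c("LF", "RF", "RH")], digits = 4),
            collapse = "/"), "%\n", sep = "")
  invisible(x)
}

#' Draw one horse's kinematic profile from a population
#'
#' Perturbs each numeric field of a population-mean profile with an
#' independent Gaussian deviation, giving the between-horse variability of
#' a simulated study cohort. Event timings are re-derived from the drawn
#' limb phases so each horse's limb waveforms stay time-shifted copies of
#' one shape (see [horse_profile()]).
#'
#' @param population A [horse_profile()] holding the population means.
#' @param between_horse_sd Named list of standard deviations; recognised
#'   elements are `stride_duration`, `speed` (scalars) and `limb_phases`,
#'   `sagittal_rom`, `coronal_rom` (named vectors matching the profile
#'   fields). Omitted entries are held fixed. All sds must be `>= 0`.
#' @param seed Integer seed; same seed, same profile. `NULL` uses the
#'   current RNG stream.
#' @param horse_id Identifier for the drawn horse.
#' @return A [horse_profile()].
#' @export
#' @examples
#' simulate_horse_profile(seed = 1, horse_id = "H07")
simulate_horse_profile <- function(population = horse_profile(),
                                   between_horse_sd = default_between_horse_sd(),
                                   seed = NULL,
                                   horse_id = population$horse_id) {
  sds <- between_horse_sd
  bad <- vapply(sds, function(v) any(v < 0), logical(1))
  if (any(bad)) {
    abort_eg("Between-horse standard deviations must be non-negative.",
             "equigait_error_parameter")
  }
  with_substream(seed, 0L, {
    perturb <- function(value, sdv) {
      if (is.null(sdv)) return(value)
      if (is.null(names(sdv)) || is.null(names(value))) {
        full <- rep(sdv, length.out = length(value))
      } else {
        full <- rep(0, length(value))
        names(full) <- names(value)
        shared <- intersect(names(sdv), names(value))
        full[shared] <- sdv[shared]
      }
      value + rnorm(length(value), 0, full)
    }
    stride <- max(
      perturb(population$stride_duration, sds$stride_duration),
      0.05 * population$stride_duration
    )
    speed <- perturb(population$speed, sds$speed)
    phases <- wrap_pct(perturb(
      population$limb_phases[c("LF", "RF", "RH")],
      sds$limb_phases
    ))
    # swing offset varies per horse but stays common across limbs, so the
    # limb waveforms remain time-shifted copies of one shape
    swing <- wrap_pct(perturb(population$swing_offset, sds$swing_offset))
    clamp_pos <- function(x, ref) pmax(x, 0.05 * ref)
    sag <- clamp_pos(perturb(population$sagittal_rom, sds$sagittal_rom),
                     population$sagittal_rom)
    cor <- clamp_pos(perturb(population$coronal_rom, sds$coronal_rom),
                     population$coronal_rom)
    horse_profile(
      horse_id = horse_id,
      stride_duration = stride,
      speed = speed,
      limb_phases = phases,
      swing_offset = swing,
      sagittal_rom = sag,
      coronal_rom = cor,
      harmonic = population$harmonic
    )
  })
}

#' Default between-horse variability used by the session simulator
#'
#' Standard deviations of the horse-level kinematic parameters across a
#' sound cohort, matching the units of [horse_profile()].
#'
#' @return Named list consumed by [simulate_horse_profile()].
#' @export
default_between_horse_sd <- function() {
  list(
    stride_duration = 0.022,
    speed = 0.33,
    swing_offset = 2,
    limb_phases = c(LF = 0.733, RF = 1.073, RH = 0.835),
    sagittal_rom = c(
      hock_L = 3.278, hock_R = 3.169,
      fore_cannon_L = 1.582, fore_cannon_R = 4.055,
      hind_cannon_L = 2, hind_cannon_R = 2
    ),
    coronal_rom = c(
      fore_cannon_L = 5.954, fore_cannon_R = 8.100,
      hind_cannon_L = 3.119, hind_cannon_R = 3.682,
      hock_L = 1.5, hock_R = 1.5
    )
  )
}

#' Expected gait-variable values implied by a profile
#'
#' Computes the 19 gait variables a perfect extraction would report for a
#' noise-free session generated from `profile`: phases and event timings as
#' programmed (protraction recoded to distance from the cycle end when it
#' falls in the second half of the stride), ranges of motion as programmed,
#' and the hock symmetry index from the two hock ROMs.
#'
#' @param profile A [horse_profile()].
#' @return One-row tibble over [gait_variable_names()].
#' @export
profile_truth <- function(profile) {
  pro <- profile$protraction_events
  ret <- profile$retraction_events
  sag <- profile$sagittal_rom
  cor <- profile$coronal_rom
  tibble::tibble(
    stride_duration = profile$stride_duration,
    limb_phasing_LF = profile$limb_phases[["LF"]],
    limb_phasing_RF = profile$limb_phases[["RF"]],
    limb_phasing_RH = profile$limb_phases[["RH"]],
    protraction_mt_L = recode_protraction(pro[["LH"]]),
    protraction_mt_R = recode_protraction(pro[["RH"]]),
    protraction_mc_L = recode_protraction(pro[["LF"]]),
    protraction_mc_R = recode_protraction(pro[["RF"]]),
    retraction_mt_L = ret[["LH"]],
    retraction_mt_R = ret[["RH"]],
    rom_sag_hock_L = sag[["hock_L"]],
    rom_sag_hock_R = sag[["hock_R"]],
    rom_sag_fore_cannon_L = sag[["fore_cannon_L"]],
    rom_sag_fore_cannon_R = sag[["fore_cannon_R"]],
    rom_cor_fore_cannon_L = cor[["fore_cannon_L"]],
    rom_cor_fore_cannon_R = cor[["fore_cannon_R"]],
    rom_cor_hind_cannon_L = cor[["hind_cannon_L"]],
    rom_cor_hind_cannon_R = cor[["hind_cannon_R"]],
    symmetry_hock = symmetry_index(sag[["hock_L"]], sag[["hock_R"]])
  )
}
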