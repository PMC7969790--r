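#' Names of the analysed gait variables
#'
#' The reliability analysis covers 19 gait variables: 10 temporal (stride
#' duration, three limb phasings relative to the left hind zero point,
#' four maximal protraction timings and two maximal metatarsal retraction
#' timings, all in percent of stride duration) and 9 spatial (sagittal
#' range of motion of both hocks and both fore cannons, coronal range of
#' motion of fore and hind cannons, and the hock range-of-motion symmetry
#' index).
#'
#' @param type `"all"`, `"temporal"` or `"spatial"`.
#' @return Character vector of column names used throughout the package.
#' @export
#' @examples
#' gait_variable_names("temporal")
gait_variable_names <- function(type = c("all", "temporal", "spatial")) {
  type <- match.arg(type)
  temporal <- c(
    "stride_duration",
    "limb_phasing_LF", "limb_phasing_RF", "limb_phasing_RH",
    "protraction_mt_L", "protraction_mt_R",
    "protraction_mc_L", "protraction_mc_R",
    "retraction_mt_L", "retraction_mt_R"
  )
  spatial <- c(
    "rom_sag_hock_L", "rom_sag_hock_R",
    "rom_sag_fore_cannon_L", "rom_sag_fore_cannon_R",
    "rom_cor_fore_cannon_L", "rom_cor_fore_cannon_R",
    "rom_cor_hind_cannon_L", "rom_cor_hind_cannon_R",
    "symmetry_hock"
  )
  switch(type,
    all = c(temporal, spatial),
    temporal = temporal,
    spatial = spatial
  )
}

#' Default population means of the gait variables
#'
#' Typical sound-horse treadmill trot values: stride duration in seconds,
#' phasing/event timings in percent of stride, ranges of motion in degrees
#' and the hock symmetry index in percent. Used as the grand means of the
#' gait-variable table simulator.
#'
#' @return Named numeric vector over [gait_variable_names()].
#' @export
default_variable_means <- function() {
  c(
    stride_duration = 0.731,
    limb_phasing_LF = 63.097,
    limb_phasing_RF = 13.654,
    limb_phasing_RH = 49.460,
    protraction_mt_L = 5.222,
    protraction_mt_R = 5.178,
    protraction_mc_L = 18.144,
    protraction_mc_R = 17.044,
    retraction_mt_L = 18.411,
    retraction_mt_R = 18.711,
    rom_sag_hock_L = 42.093,
    rom_sag_hock_R = 37.160,
    rom_sag_fore_cannon_L = 85.107,
    rom_sag_fore_cannon_R = 86.177,
    rom_cor_fore_cannon_L = 12.920,
    rom_cor_fore_cannon_R = 20.567,
    rom_cor_hind_cannon_L = 13.816,
    rom_cor_hind_cannon_R = 14.317,
    symmetry_hock = 12.471
  )
}

#' Default between-horse standard deviations of the gait variables
#'
#' Spread of the variable means across sound horses, on the same units as
#' [default_variable_means()].
#'
#' @return Named numeric vector over [gait_variable_names()].
#' @export
default_variable_sds <- function() {
  c(
    stride_duration = 0.022,
    limb_phasing_LF = 0.733,
    limb_phasing_RF = 1.073,
    limb_phasing_RH = 0.835,
    protraction_mt_L = 2.097,
    protraction_mt_R = 2.526,
    protraction_mc_L = 3.662,
    protraction_mc_R = 3.749,
    retraction_mt_L = 1.564,
    retraction_mt_R = 1.646,
    rom_sag_hock_L = 3.278,
    rom_sag_hock_R = 3.169,
    rom_sag_fore_cannon_L = 1.582,
    rom_sag_fore_cannon_R = 4.055,
    rom_cor_fore_cannon_L = 5.954,
    rom_cor_fore_cannon_R = 8.100,
    rom_cor_hind_cannon_L = 3.119,
    rom_cor_hind_cannon_R = 3.682,
    symmetry_hock = 10.759
  )
}

# Sensor placements and the limb each one tracks.
sensor_placements <- function() {
  c(
    LF_mc = "LF", RF_mc = "RF",
    LH_mt = "LH", RH_mt = "RH",
    L_tibia = "LH", R_tibia = "RH"
  )
}
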