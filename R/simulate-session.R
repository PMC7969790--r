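# Six-sensor IMU session synthesis.
#
# Each segment's sagittal angle over the stride cycle is a phase-warped
# two-harmonic cosine: theta(u) = R/2 * (cos(2*pi*w) + h*cos(4*pi*w)) with a
# piecewise-linear warp w(u) placing the maximum at the protraction event and
# the minimum at the retraction event. For h <= 1/4 the extrema stay at
# w = 0 and w = 1/2 and max - min = R exactly, so the programmed range of
# motion and event timings hold in closed form. The gyroscope channel is the
# analytic derivative, so integrating it recovers the angle.

# piecewise-linear circular warp: w(pro) = 0 (max), w(ret) = 1/2 (min)
phase_warp <- function(u, pro, ret) {
  d1 <- (ret - pro) %% 1
  if (d1 < 1e-9) d1 <- 0.5
  d2 <- 1 - d1
  v <- (u - pro) %% 1
  ifelse(v < d1, 0.5 * v / d1, 0.5 + 0.5 * (v - d1) / d2)
}

phase_warp_deriv <- function(u, pro, ret) {
  d1 <- (ret - pro) %% 1
  if (d1 < 1e-9) d1 <- 0.5
  d2 <- 1 - d1
  v <- (u - pro) %% 1
  ifelse(v < d1, 0.5 / d1, 0.5 / d2)
}

sagittal_angle_wave <- function(u, pro, ret, rom, h) {
  w <- phase_warp(u, pro, ret)
  0.5 * rom * (cos(2 * pi * w) + h * cos(4 * pi * w))
}

# d(theta)/du, degrees per stride fraction
sagittal_angle_wave_du <- function(u, pro, ret, rom, h) {
  w <- phase_warp(u, pro, ret)
  wp <- phase_warp_deriv(u, pro, ret)
  0.5 * rom * (-2 * pi * sin(2 * pi * w) - 4 * pi * h * sin(4 * pi * w)) * wp
}

walk_limb_phases <- function() c(LH = 0, LF = 25, RH = 50, RF = 75)

# map each sensor to the segment names holding its programmed ROMs
sensor_segments <- function() {
  list(
    LF_mc   = c(sag = "fore_cannon_L", cor = "fore_cannon_L"),
    RF_mc   = c(sag = "fore_cannon_R", cor = "fore_cannon_R"),
    LH_mt   = c(sag = "hind_cannon_L", cor = "hind_cannon_L"),
    RH_mt   = c(sag = "hind_cannon_R", cor = "hind_cannon_R"),
    L_tibia = c(sag = "hock_L", cor = "hock_L"),
    R_tibia = c(sag = "hock_R", cor = "hock_R")
  )
}

# stride-by-stride schedule of the motion part of a session
stride_schedule <- function(profile, protocol) {
  trot_T <- profile$stride_duration
  walk_T <- protocol$walk_stride_duration
  walk <- protocol$walk_segments
  gait <- character(0)
  dur <- numeric(0)
  add <- function(g, d) {
    gait <<- c(gait, rep(g, length(d)))
    dur <<- c(dur, d)
  }
  if (length(walk) >= 1 && walk[1] > 0) {
    add("walk", rep(walk_T, ceiling(walk[1] / walk_T)))
  }
  if (protocol$ramp_strides > 0) {
    ramp <- seq(walk_T, trot_T, length.out = protocol$ramp_strides + 2L)
    add("trot", ramp[2:(protocol$ramp_strides + 1L)])
  }
  add("trot", rep(trot_T, protocol$n_trot_strides))
  if (protocol$ramp_strides > 0) {
    ramp <- seq(trot_T, walk_T, length.out = protocol$ramp_strides + 2L)
    add("trot", ramp[2:(protocol$ramp_strides + 1L)])
  }
  if (length(walk) >= 2) {
    for (w in walk[-1]) {
      if (w > 0) add("walk", rep(walk_T, ceiling(w / walk_T)))
    }
  }
  tibble::tibble(gait = gait, dur = dur, t_start = cumsum(c(0, dur[-length(dur)])))
}

#' Simulate one six-sensor IMU recording session
#'
#' Synthesises gyroscope and accelerometer streams for the six sensor
#' placements (left/right metacarpus, left/right metatarsus, left/right
#' tibia) of one horse trotting according to `profile`, following the
#' segment structure of `protocol`: standstill, optional walk, ramped
#' transition, steady trot, ramped transition, optional walk.
#'
#' The rotation velocity about the lateromedial axis (`gx_dps`) is the
#' analytic time derivative of the programmed sagittal segment angle, so
#' numerical integration of the stream recovers the angle and its
#' programmed range of motion; `gy_dps` carries the coronal rotation
#' velocity. Accelerometers report the gravity vector in the tilted sensor
#' frame (x lateromedial/forward-tilt sensitive, z proximodistal; gravity
#' is `(0, 0, -1)` g at zero tilt). Sensor imperfections are additive iid
#' Gaussian noise and an optional constant gyroscope bias.
#'
#' @param profile A [horse_profile()] (the ground truth, kept in the
#'   session's `truth` field).
#' @param protocol A [session_protocol()].
#' @return An object of class `imu_session`: a list with `streams` (one
#'   long tibble with columns `placement`, `time_s`, `gx_dps`, `gy_dps`,
#'   `gz_dps`, `ax_g`, `ay_g`, `az_g`), `sample_rate`, `standstill`
#'   (sample-index range), `horse_id`, `surface`, `truth` and `protocol`.
#' @export
#' @examples
#' ses <- simulate_session(horse_profile(), session_protocol(seed = 1))
#' ses
simulate_session <- function(profile, protocol = session_protocol()) {
  stopifnot(inherits(profile, "horse_profile"),
            inherits(protocol, "session_protocol"))
  fs <- protocol$sample_rate
  sched <- stride_schedule(profile, protocol)
  motion_total <- sum(sched$dur)
  t0 <- protocol$standstill_duration
  n_total <- floor((t0 + motion_total) * fs)
  t <- (seq_len(n_total) - 1L) / fs
  in_motion <- t >= t0
  tm <- t[in_motion] - t0
  k <- findInterval(tm, sched$t_start)
  k[k < 1L] <- 1L
  k[k > nrow(sched)] <- nrow(sched)

  # motion starts a quarter cycle before the first zero-point event so the
  # first retraction extremum is approached from a descending flank (and
  # the standstill holds a mid-flank angle rather than the minimum itself)
  u <- rep(-0.25, n_total)
  u[in_motion] <- (k - 1L) + (tm - sched$t_start[k]) / sched$dur[k] - 0.25
  dur_sample <- rep(NA_real_, n_total)
  dur_sample[in_motion] <- sched$dur[k]
  gait <- rep("stand", n_total)
  gait[in_motion] <- sched$gait[k]
  first_gait <- sched$gait[1]

  segs <- sensor_segments()
  placements <- names(segs)
  wp <- walk_limb_phases()
  swing <- profile$swing_offset / 100

  streams <- purrr::imap(segs, function(seg, placement) {
    limb <- sensor_placements()[[placement]]
    pars <- list(
      trot = list(
        pro = profile$protraction_events[[limb]] / 100,
        ret = profile$retraction_events[[limb]] / 100,
        rom_s = profile$sagittal_rom[[seg[["sag"]]]],
        rom_c = profile$coronal_rom[[seg[["cor"]]]],
        phase = profile$limb_phases[[limb]] / 100
      ),
      walk = list(
        pro = (wp[[limb]] / 100 + swing) %% 1,
        ret = wp[[limb]] / 100,
        rom_s = profile$sagittal_rom[[seg[["sag"]]]] * protocol$walk_rom_scale,
        rom_c = profile$coronal_rom[[seg[["cor"]]]] * protocol$walk_rom_scale,
        phase = wp[[limb]] / 100
      )
    )
    h <- profile$harmonic
    theta_s <- numeric(n_total)
    theta_c <- numeric(n_total)
    omega_s <- numeric(n_total)
    omega_c <- numeric(n_total)
    for (g in c("trot", "walk")) {
      m <- gait == g
      if (!any(m)) next
      p <- pars[[g]]
      theta_s[m] <- sagittal_angle_wave(u[m], p$pro, p$ret, p$rom_s, h)
      omega_s[m] <- sagittal_angle_wave_du(u[m], p$pro, p$ret, p$rom_s, h) /
        dur_sample[m]
      theta_c[m] <- 0.5 * p$rom_c * cos(2 * pi * (u[m] - p$phase))
      omega_c[m] <- -pi * p$rom_c * sin(2 * pi * (u[m] - p$phase)) /
        dur_sample[m]
    }
    stand <- gait == "stand"
    if (any(stand)) {
      p <- pars[[first_gait]]
      theta_s[stand] <- sagittal_angle_wave(-0.25, p$pro, p$ret, p$rom_s, h)
      theta_c[stand] <- 0.5 * p$rom_c * cos(2 * pi * (-0.25 - p$phase))
    }
    ts <- theta_s * pi / 180
    tc <- theta_c * pi / 180
    ax <- sin(ts) * cos(tc)
    ay <- -sin(tc)
    az <- -cos(ts) * cos(tc)
    counter <- match(placement, placements)
    with_substream(protocol$seed, counter, {
      ng <- protocol$noise_sd_gyro
      na <- protocol$noise_sd_accel
      b <- protocol$gyro_bias
      tibble::tibble(
        placement = placement,
        time_s = t,
        gx_dps = omega_s + b + rnorm(n_total, 0, ng),
        gy_dps = omega_c + b + rnorm(n_total, 0, ng),
        gz_dps = b + rnorm(n_total, 0, ng),
        ax_g = ax + rnorm(n_total, 0, na),
        ay_g = ay + rnorm(n_total, 0, na),
        az_g = az + rnorm(n_total, 0, na)
      )
    })
  })

  n_stand <- floor(protocol$standstill_duration * fs)
  structure(
    list(
      horse_id = profile$horse_id,
      surface = protocol$surface,
      sample_rate = fs,
      standstill = if (n_stand >= 1L) c(1L, n_stand) else NULL,
      streams = dplyr::bind_rows(streams),
      truth = profile,
      protocol = protocol
    ),
    class = "imu_session"
  )
}

#' @export
print.imu_session <- function(x, ...) {
  n <- nrow(x$streams) / length(unique(x$streams$placement))
  cat("<imu_session> ", x$horse_id, " on ", x$surface,
      ": 6 streams x ", n, " samples @ ", x$sample_rate, " Hz\n", sep = "")
  invisible(x)
}

#' Extract one sensor's stream from a session
#'
#' @param session An [simulate_session()] result (or a session read back
#'   from disk).
#' @param placement One of `"LF_mc"`, `"RF_mc"`, `"LH_mt"`, `"RH_mt"`,
#'   `"L_tibia"`, `"R_tibia"`.
#' @return Tibble with the time and 6-channel sensor columns.
#' @export
session_stream <- function(session, placement) {
  stopifnot(inherits(session, "imu_session"))
  if (!placement %in% session$streams$placement) {
    abort_eg(paste0("No stream with placement '", placement, "'."),
             "equigait_error_input")
  }
  dplyr::filter(session$streams, .data$placement == .env$placement)
}
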