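# Small sessions for fast extraction tests: short standstill, no walk
# segments, no ramps unless asked for.
make_trot_session <- function(profile = horse_profile(),
                              n_trot = 12,
                              noise_gyro = 0,
                              noise_accel = 0,
                              bias = 0,
                              walk = numeric(0),
                              ramp = 0,
                              seed = NULL) {
  simulate_session(profile, session_protocol(
    n_trot_strides = n_trot,
    walk_segments = walk,
    ramp_strides = ramp,
    standstill_duration = 2,
    noise_sd_gyro = noise_gyro,
    noise_sd_accel = noise_accel,
    gyro_bias = bias,
    seed = seed
  ))
}

# circular absolute difference on the percent-of-stride cycle
circ_abs <- function(a, b) {
  d <- abs(a - b) %% 100
  pmin(d, 100 - d)
}
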