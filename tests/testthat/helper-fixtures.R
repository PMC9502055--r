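# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# gait parameters with all sensor noise switched off
zero_noise_params <- function(gait, ...) {
  gait_params(gait, gyro_noise_sd_dps = 0, marker_noise_sd_m = 0,
              st_artifact_sd_m = 0, quat_noise_sd_deg = 0, ...)
}

# one zero-noise limb recording per gait, cached
zero_noise_limb <- function(gait, limb = "LF") {
  key <- paste0("zn_", gait, "_", limb)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_limb(zero_noise_params(gait), limb,
                                      limb_phase_offsets(gait)[limb])
  }
  .fixtures[[key]]
}

# default-noise limb recording under a given seed
noisy_limb <- function(gait, limb = "LF", seed = 1) {
  p <- gait_params(gait)
  simulate_limb(p, limb, limb_phase_offsets(gait)[limb], seed = seed)
}

# filtered IMU trace of a recording
filtered_imu <- function(rec) {
  butter_lowpass(relative_sagittal_angle(rec$imu$quat_cannon,
                                         rec$imu$quat_pastern,
                                         rec$imu$rate_hz))
}

# filtered, resampled OMC trace of a recording
filtered_omc <- function(rec) {
  butter_lowpass(resample_spline(fja_from_markers(rec$omc$markers,
                                                  rec$omc$rate_hz),
                                 rec$imu$rate_hz))
}

# random planar (about-z) unit quaternion sequence
random_z_quats <- function(n, max_deg = 170) {
  ang <- stats::runif(n, -max_deg, max_deg)
  cbind(cos(ang * pi / 360), 0, 0, sin(ang * pi / 360))
}

# quaternion -> rotation matrix (independent oracle path)
quat_to_mat_oracle <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
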