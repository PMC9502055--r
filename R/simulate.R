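#' Gait simulation parameters
#'
#' Bundles the kinematic and sensor parameters for one simulated limb trial.
#' Defaults reflect overground locomotion of sound horses on a firm surface:
#' walk 1.53 m/s, trot 3.56 m/s; trot stride length 2.5 m; walk stride length
#' 1.8 m (about a 1.2 s walk stride); duty factor (stance fraction) 0.60 at
#' walk and 0.40 at trot; IMU sampling at 200 Hz and video at 60 Hz.
#'
#' @param gait `"walk"` or `"trot"`.
#' @param speed_mps forward speed, m/s.
#' @param stride_length_m stride length, m (stride duration =
#'   `stride_length_m / speed_mps`).
#' @param n_strides number of complete strides in the record (>= 3).
#' @param rom_deg planted fetlock range of motion of the sound waveform,
#'   degrees.
#' @param lameness_factor amplitude scale in (0, 1] applied to the limb's
#'   waveform; 1 = sound.
#' @param flexion_peak_ratio relative height of the two flexion peaks, (0, 1].
#' @param imu_rate_hz,omc_rate_hz sampling rates; IMU must be faster.
#' @param gyro_noise_sd_dps additive white noise SD on each gyroscope axis,
#'   deg/s.
#' @param marker_noise_sd_m additive white digitization noise SD per marker
#'   coordinate, m.
#' @param st_artifact_sd_m SD of the low-frequency (below ~1.5 Hz, near the
#'   stride frequency) correlated soft-tissue marker displacement, m.
#' @param quat_noise_sd_deg SD of the random per-sample orientation
#'   perturbation of each sensor, degrees.
#' @param omc_offset_deg constant convention offset of the optical dorsal
#'   angle relative to the IMU standing zero, degrees (removed by the
#'   pipeline's y-axis alignment).
#' @param duty_factor stance fraction of the stride; default by gait.
#' @param cannon_len_m,pastern_len_m marker chain segment lengths, m.
#' @return a `gait_params` object.
#' @export
gait_params <- function(gait = c("walk", "trot"),
                        speed_mps = NULL, stride_length_m = NULL,
                        n_strides = 5, rom_deg = NULL, lameness_factor = 1,
                        flexion_peak_ratio = 0.9,
                        imu_rate_hz = 200, omc_rate_hz = 60,
                        gyro_noise_sd_dps = 1.0, marker_noise_sd_m = 0.001,
                        st_artifact_sd_m = 0.002, quat_noise_sd_deg = 0.3,
                        omc_offset_deg = 10, duty_factor = NULL,
                        cannon_len_m = 0.25, pastern_len_m = 0.12) {
  gait <- match.arg(gait)
  if (is.null(speed_mps)) speed_mps <- if (gait == "walk") 1.53 else 3.56
  if (is.null(stride_length_m))
    stride_length_m <- if (gait == "walk") 1.8 else 2.5
  if (is.null(rom_deg)) rom_deg <- if (gait == "walk") 58 else 83
  if (is.null(duty_factor)) duty_factor <- if (gait == "walk") 0.60 else 0.40
  p <- list(gait = gait, speed_mps = speed_mps,
            stride_length_m = stride_length_m, n_strides = n_strides,
            rom_deg = rom_deg, lameness_factor = lameness_factor,
            flexion_peak_ratio = flexion_peak_ratio,
            imu_rate_hz = imu_rate_hz, omc_rate_hz = omc_rate_hz,
            gyro_noise_sd_dps = gyro_noise_sd_dps,
            marker_noise_sd_m = marker_noise_sd_m,
            st_artifact_sd_m = st_artifact_sd_m,
            quat_noise_sd_deg = quat_noise_sd_deg,
            omc_offset_deg = omc_offset_deg, duty_factor = duty_factor,
            cannon_len_m = cannon_len_m, pastern_len_m = pastern_len_m)
  num <- unlist(p[-1])
  if (!all(is.finite(num))) stop("gait parameters must be finite")
  if (speed_mps <= 0 || stride_length_m <= 0)
    stop("speed and stride length must be positive")
  if (rom_deg <= 0) stop("rom_deg must be positive")
  if (lameness_factor <= 0 || lameness_factor > 1)
    stop("lameness_factor must be in (0, 1]")
  if (imu_rate_hz <= omc_rate_hz)
    stop("imu_rate_hz must exceed omc_rate_hz")
  if (n_strides < 3) stop("n_strides must be at least 3")
  structure(p, class = "gait_params")
}

#' @export
print.gait_params <- function(x, ...) {
  cat(sprintf(paste0("<gait_params> %s, %.2f m/s, stride %.2f m ",
                     "(%.3f s), %d strides, ROM %.1f deg, lameness %.2f\n"),
              x$gait, x$speed_mps, x$stride_length_m,
              x$stride_length_m / x$speed_mps, x$n_strides, x$rom_deg,
              x$lameness_factor))
  invisible(x)
}

#' Simulate one limb's paired IMU and OMC recording
#'
#' Generates ground-truth fetlock kinematics for one limb and the two
#' observation channels the pipeline consumes. The planted FJA is the
#' one-stride template ([make_fja_waveform()]) tiled over `n_strides`,
#' scaled by `lameness_factor`. The pastern's absolute sagittal angle is
#' quiet during stance (hoof planted) and carries two opposite rotation
#' lobes spanning swing; the cannon's absolute angle is whatever closes the
#' kinematic chain (`cannon = pastern - FJA`), so the relative sensor
#' orientation reproduces the planted angle exactly. Sensor quaternions are
#' rotations about the mediolateral axis with optional per-sample orientation
#' noise; the pastern gyroscope is the analytic time derivative of the
#' pastern orientation plus white noise; markers sit on a two-link planar
#' chain sampled at the video rate with white digitization noise plus
#' low-frequency soft-tissue displacement.
#'
#' The record spans phases `[-0.33, n_strides + 0.17]` of the limb's stride
#' cycle: it begins mid-swing (in the quiet dip between flexion peaks, away
#' from any waveform extremum) and ends early in a stance, so it contains
#' exactly `n_strides` complete toe-on-to-toe-on strides.
#'
#' @param params a [gait_params()] object.
#' @param limb_id one of `"LF"`, `"RF"`, `"LH"`, `"RH"`.
#' @param phase_offset stride-fraction offset of this limb's cycle (gait
#'   footfall pattern; see [limb_phase_offsets()]).
#' @param seed optional integer seed (set once; omit when simulating several
#'   limbs under an outer seed).
#' @return a `limb_recording`: `imu` (quaternions + gyroscope @ IMU rate),
#'   `omc` (marker triad @ video rate), and `truth` (noise-free planted FJA
#'   series, stride duration, duty factor, toe-on/toe-off times, planted
#'   ROM).
#' @export
simulate_limb <- function(params, limb_id = "LF", phase_offset = 0,
                          seed = NULL) {
  stopifnot(inherits(params, "gait_params"))
  if (!limb_id %in% c("LF", "RF", "LH", "RH"))
    stop("limb_id must be one of LF, RF, LH, RH")
  if (!is.null(seed)) set.seed(seed)
  p <- params
  T_s <- p$stride_length_m / p$speed_mps
  duty <- p$duty_factor
  n <- p$n_strides
  wf <- make_fja_waveform(p$gait, p$rom_deg, p$flexion_peak_ratio)
  phase0 <- -0.33 + phase_offset
  t_end <- (n + 0.5) * T_s

  t_imu <- seq(0, t_end, by = 1 / p$imu_rate_hz)
  ph <- phase0 + t_imu / T_s
  fja <- p$lameness_factor * wf$fn(ph)
  psi <- swing_profile(ph, duty)              # pastern absolute angle (deg)
  theta_c <- psi - fja                        # cannon absolute angle (deg)

  q_cannon <- quat_from_axis_angle(c(0, 0, 1), theta_c)
  q_pastern <- quat_from_axis_angle(c(0, 0, 1), psi)
  if (p$quat_noise_sd_deg > 0) {
    q_cannon <- quat_multiply(q_cannon,
                              random_small_rotations(length(t_imu),
                                                     p$quat_noise_sd_deg))
    q_pastern <- quat_multiply(q_pastern,
                               random_small_rotations(length(t_imu),
                                                      p$quat_noise_sd_deg))
  }

  wz <- swing_profile_deriv(ph, duty) / T_s   # deg/s, analytic derivative
  gyro <- cbind(0, 0, wz)
  if (p$gyro_noise_sd_dps > 0)
    gyro <- gyro + matrix(stats::rnorm(3 * length(wz),
                                       sd = p$gyro_noise_sd_dps), ncol = 3)

  t_omc <- seq(0, t_end, by = 1 / p$omc_rate_hz)
  ph_m <- phase0 + t_omc / T_s
  fja_m <- p$lameness_factor * wf$fn(ph_m)
  theta_m <- (swing_profile(ph_m, duty) - fja_m) * pi / 180  # cannon, rad
  fetlock <- cbind(p$speed_mps * t_omc,
                   0.12 + 0.008 * sin(2 * pi * ph_m))
  u <- cbind(sin(theta_m), cos(theta_m))      # metacarpus axis, unit, up
  proximal <- fetlock + p$cannon_len_m * u
  ang_omc <- (fja_m + p$omc_offset_deg) * pi / 180
  w1 <- -u                                    # prolongation of the cannon axis
  v <- cbind(cos(ang_omc) * w1[, 1] - sin(ang_omc) * w1[, 2],
             sin(ang_omc) * w1[, 1] + cos(ang_omc) * w1[, 2])
  distal <- fetlock + p$pastern_len_m * v
  markers <- list(proximal = proximal, fetlock = fetlock, distal = distal)
  markers <- add_marker_noise(markers, p$marker_noise_sd_m,
                              p$st_artifact_sd_m, p$omc_rate_hz)

  k <- seq(ceiling(phase0), floor(phase0 + t_end / T_s))
  toe_on_s <- (k - phase0) * T_s
  toe_on_s <- toe_on_s[toe_on_s >= 0 & toe_on_s <= t_end]
  toe_off_s <- toe_on_s + duty * T_s
  toe_off_s <- toe_off_s[toe_off_s <= t_end]

  structure(list(
    limb_id = limb_id, gait = p$gait, params = p,
    phase_offset = phase_offset,
    imu = list(rate_hz = p$imu_rate_hz, t0 = 0, quat_cannon = q_cannon,
               quat_pastern = q_pastern, gyro_pastern = gyro),
    omc = list(rate_hz = p$omc_rate_hz, t0 = 0, markers = markers),
    truth = list(fja = angle_series(fja, p$imu_rate_hz,
                                    convention = "imu_zeroed",
                                    meta = list(limb = limb_id,
                                                gait = p$gait,
                                                source = "truth")),
                 stride_duration_s = T_s, duty_factor = duty,
                 toe_on_s = toe_on_s, toe_off_s = toe_off_s,
                 rom_deg_planted = p$lameness_factor * p$rom_deg,
                 lameness_factor = p$lameness_factor)),
    class = "limb_recording")
}

#' @export
print.limb_recording <- function(x, ...) {
  cat(sprintf(paste0("<limb_recording> %s %s: %d IMU samples @ %g Hz, ",
                     "%d video frames @ %g Hz, planted ROM %.2f deg\n"),
              x$limb_id, x$gait, nrow(x$imu$quat_cannon), x$imu$rate_hz,
              nrow(x$omc$markers$fetlock), x$omc$rate_hz,
              x$truth$rom_deg_planted))
  invisible(x)
}

#' Footfall phase offsets of the four limbs
#'
#' Stride-fraction offsets of each limb's cycle: the four-beat lateral
#' sequence at walk (LH, LF, RH, RF at quarter-stride intervals) and
#' synchronous diagonal pairs at trot (LF+RH, RF+LH half a stride apart).
#'
#' @param gait `"walk"` or `"trot"`.
#' @return named numeric vector over `LF`, `RF`, `LH`, `RH`.
#' @export
limb_phase_offsets <- function(gait) {
  if (gait == "walk") {
    c(LF = 0.25, RF = 0.75, LH = 0.00, RH = 0.50)
  } else if (gait == "trot") {
    c(LF = 0.00, RF = 0.50, LH = 0.50, RH = 0.00)
  } else stop("unknown gait '", gait, "'")
}

#' Simulate a four-limb trial of one horse at one gait
#'
#' @param horse_id character id.
#' @param gait `"walk"` or `"trot"`.
#' @param rom_by_limb named numeric vector of planted (sound) ROMs for
#'   `LF`, `RF`, `LH`, `RH`, degrees.
#' @param lame_limb limb id of the lame limb, or `NULL` for a sound horse.
#' @param lameness_factor amplitude factor applied to the lame limb.
#' @param base a [gait_params()] carrying the shared trial parameters
#'   (speeds, rates, noise); its `rom_deg`/`lameness_factor` are overridden
#'   per limb.
#' @param seed optional integer seed for the whole trial.
#' @return a `horse_trial` with one `limb_recording` per limb.
#' @export
simulate_horse_trial <- function(horse_id, gait, rom_by_limb,
                                 lame_limb = NULL, lameness_factor = 1,
                                 base = gait_params(gait), seed = NULL) {
  limbs <- c("LF", "RF", "LH", "RH")
  if (!all(limbs %in% names(rom_by_limb)))
    stop("rom_by_limb must name all of LF, RF, LH, RH")
  if (!is.null(lame_limb) && !lame_limb %in% limbs)
    stop("lame_limb must be one of LF, RF, LH, RH")
  if (!is.null(seed)) set.seed(seed)
  offs <- limb_phase_offsets(gait)
  recs <- lapply(limbs, function(l) {
    pl <- base
    pl$rom_deg <- unname(rom_by_limb[l])
    pl$lameness_factor <- if (!is.null(lame_limb) && l == lame_limb)
      lameness_factor else 1
    class(pl) <- "gait_params"
    simulate_limb(pl, limb_id = l, phase_offset = offs[l])
  })
  names(recs) <- limbs
  structure(list(horse_id = horse_id, gait = gait,
                 is_lame = !is.null(lame_limb),
                 lame_limb = if (is.null(lame_limb)) NA_character_
                             else lame_limb,
                 lameness_factor = lameness_factor,
                 recordings = recs),
            class = "horse_trial")
}

#' @export
print.horse_trial <- function(x, ...) {
  cat(sprintf("<horse_trial> %s at %s: %s\n", x$horse_id, x$gait,
              if (x$is_lame) paste0("lame limb ", x$lame_limb,
                                    " (factor ", round(x$lameness_factor, 3),
                                    ")") else "sound"))
  invisible(x)
}

# small random orientation perturbations: random axes, N(0, sd_deg) angles
random_small_rotations <- function(n, sd_deg) {
  ax <- matrix(stats::rnorm(3 * n), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  half <- stats::rnorm(n, sd = sd_deg) * pi / 360
  cbind(cos(half), sin(half) * ax)
}

# white digitization noise + low-frequency (<= 3 Hz) soft-tissue displacement
add_marker_noise <- function(markers, white_sd, st_sd, rate_hz) {
  n <- nrow(markers$fetlock)
  for (m in names(markers)) {
    if (white_sd > 0)
      markers[[m]] <- markers[[m]] + matrix(stats::rnorm(2 * n,
                                                         sd = white_sd),
                                            ncol = 2)
    if (st_sd > 0) {
      # skin displacement tracks limb motion near the stride frequency;
      # band-limit the artifact below ~1.5 Hz
      bf <- signal::butter(2, min(1.5 / (rate_hz / 2), 0.99), type = "low")
      burn <- 4L * rate_hz       # discard filter edges of the noise stream
      for (j in 1:2) {
        raw <- stats::rnorm(n + 2L * burn)
        sm <- filtfilt_padded(bf$b, bf$a, raw)[(burn + 1L):(burn + n)]
        s <- stats::sd(sm)
        if (s > 0) markers[[m]][, j] <- markers[[m]][, j] + sm / s * st_sd
      }
    }
  }
  markers
}
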