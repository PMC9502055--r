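#' Sagittal joint angle from paired segment orientations
#'
#' Computes the relative rotation between the cannon (metacarpus/metatarsus)
#' and pastern sensors, `q_rel = conj(q_cannon) * q_pastern`, and extracts the
#' signed rotation angle about the mediolateral axis (the z axis of the shared
#' sensor frame) by swing-twist decomposition. The per-sample angle lies in
#' (-180, 180] degrees and is then unwrapped across samples so the returned
#' trace is continuous.
#'
#' @param quat_cannon,quat_pastern n x 4 unit-quaternion matrices (w, x, y, z)
#'   sampled at `rate_hz`. Norms must be within `norm_tol` of 1; slightly
#'   off-norm rows are renormalized with a warning, zero-norm rows are an
#'   error.
#' @param rate_hz sampling rate (default 200).
#' @param t0 time of first sample, seconds.
#' @param norm_tol unit-norm tolerance before renormalization warning.
#' @param meta passed to the returned [angle_series()].
#' @return an [angle_series()] with convention `"imu_raw"` (un-zeroed).
#' @seealso [apply_calibration()] for standing-pose zeroing.
#' @export
relative_sagittal_angle <- function(quat_cannon, quat_pastern, rate_hz = 200,
                                    t0 = 0, norm_tol = 1e-6, meta = list()) {
  qa <- as_quat_matrix(quat_cannon, "quat_cannon")
  qb <- as_quat_matrix(quat_pastern, "quat_pastern")
  if (nrow(qa) != nrow(qb))
    stop("quat_cannon and quat_pastern must have the same length (",
         nrow(qa), " vs ", nrow(qb), ")")
  for (nm in c("quat_cannon", "quat_pastern")) {
    q <- if (nm == "quat_cannon") qa else qb
    nrm <- quat_norm(q)
    if (any(nrm < 1e-12))
      stop("zero-norm quaternion in ", nm, " (sample ",
           which(nrm < 1e-12)[1], ")")
    if (any(abs(nrm - 1) > norm_tol)) {
      warning(nm, " contains quaternions off unit norm by up to ",
              format(max(abs(nrm - 1)), digits = 3), "; renormalizing")
    }
  }
  qa <- quat_normalize(qa)
  qb <- quat_normalize(qb)
  qrel <- quat_multiply(quat_conjugate(qa), qb)
  # swing-twist about z: the twist component is (w, 0, 0, z) renormalized
  theta <- wrap_deg(2 * atan2(qrel[, 4], qrel[, 1]) * 180 / pi)
  angle_series(unwrap_deg(theta), rate_hz = rate_hz, t0 = t0,
               convention = "imu_raw", meta = meta)
}

#' Zero an IMU angle series at the standing calibration pose
#'
#' The standing calibration convention sets the fetlock angle to 0 deg while
#' the horse stands square; flexion is positive and extension negative
#' thereafter. The zero offset is the mean angle over the calibration window.
#'
#' @param series an [angle_series()].
#' @param calib_window numeric length-2, `c(start_s, end_s)` of the standing
#'   window in the series' time frame; must span at least `min_window_s` and
#'   lie inside the series.
#' @param min_window_s minimum window length in seconds (default 0.5).
#' @return list with `series` (convention `"imu_zeroed"`) and `calibration`
#'   (list with `zero_offset_deg`, `window_s`, `n_samples`).
#' @export
apply_calibration <- function(series, calib_window, min_window_s = 0.5) {
  stopifnot(inherits(series, "angle_series"))
  if (length(calib_window) != 2L || !all(is.finite(calib_window)) ||
      diff(calib_window) <= 0)
    stop("calib_window must be c(start_s, end_s) with end > start")
  if (diff(calib_window) < min_window_s)
    stop("calibration window must cover at least ", min_window_s, " s")
  tt <- series_time(series)
  inside <- tt >= calib_window[1] & tt <= calib_window[2]
  if (calib_window[1] < tt[1] - 1e-12 ||
      calib_window[2] > tt[length(tt)] + 1e-12)
    stop("calibration window [", calib_window[1], ", ", calib_window[2],
         "] lies outside the series span [", tt[1], ", ", tt[length(tt)], "]")
  offset <- mean(series$values[inside])
  list(series = series_with(series, series$values - offset,
                            convention = "imu_zeroed"),
       calibration = list(zero_offset_deg = offset,
                          window_s = calib_window,
                          n_samples = sum(inside)))
}

#' Fetlock joint angle from planar marker triads
#'
#' Computes, per video frame, the dorsal fetlock angle from the three joint
#' markers: the metacarpus axis is the fetlock-to-proximal (carpus/tarsus)
#' direction, the pastern axis the fetlock-to-distal (coffin joint) direction.
#' The returned angle is the signed planar angle between the pastern axis and
#' the prolongation of the metacarpus axis, with the sign chosen so fetlock
#' flexion increases the value and extension decreases it. A straight limb
#' (collinear markers) reads 0 deg. The trace is unwrapped across frames.
#'
#' Frames in which two markers coincide are flagged and linearly interpolated
#' from neighboring good frames; if more than `max_bad_frac` of frames are
#' bad, the input is rejected.
#'
#' @param markers a list with `proximal`, `fetlock`, `distal`: each an n x 2
#'   matrix of planar positions in meters (x forward, y up).
#' @param rate_hz frame rate (default 60).
#' @param t0 time of first frame, seconds.
#' @param max_bad_frac maximum tolerated fraction of degenerate frames.
#' @param meta passed to the returned [angle_series()].
#' @return an [angle_series()] with convention `"omc_dorsal"`.
#' @export
fja_from_markers <- function(markers, rate_hz = 60, t0 = 0,
                             max_bad_frac = 0.1, meta = list()) {
  need <- c("proximal", "fetlock", "distal")
  if (!is.list(markers) || !all(need %in% names(markers)))
    stop("markers must be a list with proximal, fetlock and distal matrices")
  pm <- lapply(markers[need], function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L) stop("each marker matrix must have two columns (x, y)")
    storage.mode(m) <- "double"
    m
  })
  n <- nrow(pm$fetlock)
  if (n < 3L) stop("need at least 3 frames")
  if (nrow(pm$proximal) != n || nrow(pm$distal) != n)
    stop("marker matrices must have the same number of frames")

  u <- pm$proximal - pm$fetlock       # metacarpus axis (fetlock -> proximal)
  v <- pm$distal - pm$fetlock         # pastern axis (fetlock -> distal)
  lu <- sqrt(rowSums(u^2)); lv <- sqrt(rowSums(v^2))
  bad <- !is.finite(lu) | !is.finite(lv) | lu < 1e-9 | lv < 1e-9
  if (all(bad)) stop("all frames have coincident markers")
  if (mean(bad) > max_bad_frac)
    stop(sprintf("%.1f%% of frames have coincident markers (max %.1f%%)",
                 100 * mean(bad), 100 * max_bad_frac))
  # prolongation of the metacarpus axis is -u; signed angle from -u to v
  w <- -u
  theta <- rep(NA_real_, n)
  ok <- !bad
  theta[ok] <- atan2(w[ok, 1] * v[ok, 2] - w[ok, 2] * v[ok, 1],
                     w[ok, 1] * v[ok, 1] + w[ok, 2] * v[ok, 2]) * 180 / pi
  if (any(bad)) {
    idx <- seq_len(n)
    theta[bad] <- stats::approx(idx[ok], theta[ok], xout = idx[bad],
                                rule = 2)$y
  }
  angle_series(unwrap_deg(theta), rate_hz = rate_hz, t0 = t0,
               convention = "omc_dorsal", meta = meta)
}

#' Resultant angular velocity of a triaxial gyroscope signal
#'
#' Per-sample Euclidean norm of the three gyroscope components, the scalar
#' signal used for stride segmentation (see [segment_strides()]).
#'
#' @param gyro n x 3 matrix of angular velocities in degrees/second.
#' @return numeric vector of resultant magnitudes (degrees/second).
#' @export
resultant_angular_velocity <- function(gyro) {
  gyro <- as.matrix(gyro)
  if (ncol(gyro) != 3L) stop("gyro must be an n x 3 matrix")
  if (!all(is.finite(gyro))) stop("gyro samples must be finite")
  sqrt(rowSums(gyro^2))
}
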