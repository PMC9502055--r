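test_that("relative angle of identical orientations is zero", {
  set.seed(1)
  q <- random_z_quats(50)
  a <- relative_sagittal_angle(q, q)
  expect_true(all(abs(a$values) < 1e-9))
  expect_identical(a$convention, "imu_raw")
})

test_that("a fixed mediolateral rotation reads as that angle", {
  n <- 20
  id <- cbind(rep(1, n), 0, 0, 0)
  rot45 <- matrix(rep(c(cos(22.5 * pi / 180), 0, 0, sin(22.5 * pi / 180)),
                      each = n), n)
  a <- relative_sagittal_angle(id, rot45)
  expect_equal(a$values, rep(45, n), tolerance = 1e-9)
})

test_that("planar pairs match the rotation-matrix oracle", {
  set.seed(7)
  qa <- random_z_quats(200)
  qb <- random_z_quats(200)
  a <- relative_sagittal_angle(qa, qb)$values
  oracle <- vapply(seq_len(200), function(i) {
    R <- t(quat_to_mat_oracle(qa[i, ])) %*% quat_to_mat_oracle(qb[i, ])
    atan2(R[2, 1], R[1, 1]) * 180 / pi
  }, numeric(1))
  # compare wrapped values (the series output is unwrapped)
  wrapped <- a - 360 * round((a - oracle) / 360)
  expect_lt(max(abs(wrapped - oracle)), 1e-9)
})

test_that("angle extraction is invariant to a common rigid rotation", {
  set.seed(11)
  qa <- random_z_quats(100)
  qb <- random_z_quats(100)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- fjagait:::quat_from_axis_angle(ax, 38.4)
  Rn <- matrix(rep(R, each = 100), 100)
  a1 <- relative_sagittal_angle(qa, qb)$values
  a2 <- relative_sagittal_angle(fjagait:::quat_multiply(Rn, qa),
                                fjagait:::quat_multiply(Rn, qb))$values
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("quaternion input validation works", {
  q <- random_z_quats(10)
  expect_error(relative_sagittal_angle(q, q[1:5, ]), "same length")
  qz <- q; qz[3, ] <- 0
  expect_error(relative_sagittal_angle(qz, q), "zero-norm")
  qo <- q; qo[2, ] <- qo[2, ] * 1.001
  expect_warning(relative_sagittal_angle(qo, q), "renormalizing")
})

test_that("calibration zeroes at the standing pose", {
  const <- angle_series(rep(12, 400), 200)
  out <- apply_calibration(const, c(0, 1))
  expect_equal(out$calibration$zero_offset_deg, 12)
  expect_true(all(out$series$values == 0))
  expect_identical(out$series$convention, "imu_zeroed")

  tt <- (0:999) / 200
  wave <- 12 + ifelse(tt > 1.5, sin(2 * pi * (tt - 1.5)), 0)
  s <- angle_series(wave, 200)
  out2 <- apply_calibration(s, c(0, 1.2))
  expect_equal(out2$calibration$zero_offset_deg, 12)
  expect_equal(out2$series$values, wave - 12)
})

test_that("calibration offset from a noisy standing window is accurate", {
  # 1 s at 200 Hz with N(5, 0.1) noise: SE = 0.1 / sqrt(200) ~ 0.007 deg
  for (seed in 1:10) {
    set.seed(seed)
    s <- angle_series(rnorm(300, mean = 5, sd = 0.1), 200)
    out <- apply_calibration(s, c(0, 1))
    expect_lt(abs(out$calibration$zero_offset_deg - 5), 0.05)
  }
})

test_that("calibration window outside the series is rejected", {
  s <- angle_series(rep(1, 200), 200)
  expect_error(apply_calibration(s, c(0.8, 1.6)), "outside")
  expect_error(apply_calibration(s, c(0, 0.2)), "at least")
})

test_that("marker geometry reproduces planted dorsal angles", {
  # collinear markers: straight limb reads zero
  n <- 5
  mk <- list(proximal = cbind(rep(0, n), 2), fetlock = cbind(rep(0, n), 1),
             distal = cbind(rep(0, n), 0))
  expect_equal(fja_from_markers(mk)$values, rep(0, n), tolerance = 1e-12)

  # distal marker rotated 30 deg dorsally about the fetlock
  ang <- 30 * pi / 180
  mk30 <- mk
  mk30$distal <- cbind(rep(sin(ang), n), 1 - cos(ang))
  expect_equal(fja_from_markers(mk30)$values, rep(30, n), tolerance = 1e-9)
})

test_that("random marker triads match the planar-angle oracle", {
  set.seed(3)
  n <- 150
  fet <- cbind(runif(n), runif(n))
  th_c <- runif(n, -50, 50) * pi / 180
  fja <- runif(n, -60, 60)
  u <- cbind(sin(th_c), cos(th_c))
  prox <- fet + 0.25 * u
  aa <- fja * pi / 180
  w1 <- -u
  v <- cbind(cos(aa) * w1[, 1] - sin(aa) * w1[, 2],
             sin(aa) * w1[, 1] + cos(aa) * w1[, 2])
  mk <- list(proximal = prox, fetlock = fet, distal = fet + 0.12 * v)
  out <- fja_from_markers(mk)$values
  expect_lt(max(abs(out - fja)), 1e-9)
})

test_that("degenerate marker frames are interpolated or rejected", {
  n <- 40
  mk <- list(proximal = cbind(rep(0, n), 2), fetlock = cbind(rep(0, n), 1),
             distal = cbind(-sin(seq(0, 0.5, length.out = n)),
                            1 - cos(seq(0, 0.5, length.out = n))))
  good <- fja_from_markers(mk)$values
  mk_bad <- mk
  mk_bad$distal[20, ] <- mk_bad$fetlock[20, ]   # coincident in one frame
  out <- fja_from_markers(mk_bad)$values
  expect_lt(abs(out[20] - good[20]), 0.5)       # interpolated from neighbors
  mk_worse <- mk
  mk_worse$distal[1:10, ] <- mk_worse$fetlock[1:10, ]
  expect_error(fja_from_markers(mk_worse), "coincident")
})

test_that("resultant angular velocity is the Euclidean norm", {
  expect_identical(resultant_angular_velocity(matrix(c(3, 4, 0), 1)), 5)
  expect_identical(resultant_angular_velocity(matrix(0, 4, 3)), rep(0, 4))
  set.seed(9)
  g <- matrix(rnorm(300), ncol = 3)
  oracle <- apply(g, 1, function(r) sqrt(sum(r^2)))
  expect_equal(resultant_angular_velocity(g), oracle, tolerance = 1e-12)
})

test_that("IMU and OMC conventions differ by a constant on noise-free data", {
  for (gait in c("walk", "trot")) {
    rec <- zero_noise_limb(gait)
    omc <- fja_from_markers(rec$omc$markers, rec$omc$rate_hz)
    wf <- make_fja_waveform(gait, rec$params$rom_deg,
                            rec$params$flexion_peak_ratio)
    t_m <- series_time(omc)
    truth_m <- rec$params$lameness_factor *
      wf$fn(-0.33 + rec$phase_offset + t_m / rec$truth$stride_duration_s)
    dev <- omc$values - truth_m
    expect_lt(max(dev) - min(dev), 1e-6)
  }
})
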