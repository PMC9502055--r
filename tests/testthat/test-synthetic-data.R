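test_that("noise-free quaternions round-trip the planted angle exactly", {
  rec <- zero_noise_limb("trot")
  a <- relative_sagittal_angle(rec$imu$quat_cannon, rec$imu$quat_pastern)
  expect_lt(max(abs(a$values - rec$truth$fja$values)), 1e-9)
})

test_that("planted lameness scales the truth ROM exactly", {
  p <- zero_noise_params("walk", rom_deg = 58, lameness_factor = 0.7)
  rec <- simulate_limb(p, "LF", 0)
  expect_equal(rec$truth$rom_deg_planted, 40.6, tolerance = 1e-12)
  sound <- simulate_limb(zero_noise_params("walk", rom_deg = 58), "LF", 0)
  ratio <- diff(range(rec$truth$fja$values)) /
    diff(range(sound$truth$fja$values))
  expect_equal(ratio, 0.7, tolerance = 1e-12)
})

test_that("the noise-free gyro shows one low-velocity trough per stride", {
  rec <- zero_noise_limb("trot")
  v <- resultant_angular_velocity(rec$imu$gyro_pastern)
  lo <- 0.08 * quantile(v, 0.98, names = FALSE)
  below <- v < lo
  runs <- rle(below)
  # complete troughs only: the record ends inside a stance, so drop a
  # terminal low-velocity run touching the last sample
  keep <- runs$values & runs$lengths >= 0.08 * 200
  if (runs$values[length(runs$values)]) keep[length(keep)] <- FALSE
  expect_equal(sum(keep), rec$params$n_strides)
})

test_that("IMU and OMC streams cover the same span and unit quaternions", {
  rec <- noisy_limb("walk", seed = 4)
  t_imu <- (nrow(rec$imu$quat_cannon) - 1) / rec$imu$rate_hz
  t_omc <- (nrow(rec$omc$markers$fetlock) - 1) / rec$omc$rate_hz
  expect_lt(abs(t_imu - t_omc), 1 / rec$omc$rate_hz)
  expect_lt(max(abs(fjagait:::quat_norm(rec$imu$quat_cannon) - 1)), 1e-9)
  expect_lt(max(abs(fjagait:::quat_norm(rec$imu$quat_pastern) - 1)), 1e-9)
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_limb(gait_params("trot"), "RF", 0.5, seed = 123)
  b <- simulate_limb(gait_params("trot"), "RF", 0.5, seed = 123)
  expect_identical(a, b)
  ca <- simulate_cohort(2, 1, seed = 99)
  cb <- simulate_cohort(2, 1, seed = 99)
  expect_identical(ca, cb)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(gait_params("walk", speed_mps = NA), "finite")
  expect_error(gait_params("walk", n_strides = 2), "at least 3")
  expect_error(gait_params("walk", lameness_factor = 0), "lameness_factor")
  expect_error(gait_params("walk", omc_rate_hz = 300), "exceed")
  expect_error(simulate_limb(gait_params("walk"), "XX"), "limb_id")
})

test_that("a paper-shaped cohort has the requested composition", {
  cohort <- simulate_cohort(7, 7, seed = 42)
  expect_identical(nrow(cohort$horses), 14L)
  expect_identical(sum(cohort$horses$group == "lame"), 7L)
  # every lame horse has exactly one lame limb, consistent across gaits
  for (h in cohort$horses$horse_id[cohort$horses$group == "lame"]) {
    limbs <- unique(vapply(Filter(function(tr) tr$horse_id == h,
                                  cohort$trials),
                           function(tr) tr$lame_limb, character(1)))
    expect_identical(length(limbs), 1L)
    expect_true(limbs %in% c("LF", "RF", "LH", "RH"))
    facs <- vapply(Filter(function(tr) tr$horse_id == h, cohort$trials),
                   function(tr) tr$lameness_factor, numeric(1))
    expect_true(all(facs < 1))
  }
  # one trial per horse per gait
  expect_identical(length(cohort$trials), 28L)
})

test_that("zero asymmetry plants identical left-right truth ROMs", {
  cfg <- cohort_config(gaits = "walk",
                       cv_lr_target = c(front_walk = 0, front_trot = 0,
                                        hind_walk = 0, hind_trot = 0),
                       rom_sd = c(front_walk = 0, hind_walk = 0,
                                  front_trot = 0, hind_trot = 0))
  cohort <- simulate_cohort(1, 0, cfg, seed = 1)
  tr <- cohort$trials[[1]]
  expect_identical(tr$recordings$LF$truth$rom_deg_planted,
                   tr$recordings$RF$truth$rom_deg_planted)
  expect_identical(tr$recordings$LH$truth$rom_deg_planted,
                   tr$recordings$RH$truth$rom_deg_planted)
})

test_that("lameness factors derive from the configured pair CV targets", {
  cfg <- cohort_config()
  # CV% = 100*sqrt(2)*(1-f)/(1+f) inverts the configured factor means
  for (g in c("walk", "trot")) {
    f <- cfg$lameness_factor_mean[[g]]
    cv <- 100 * sqrt(2) * (1 - f) / (1 + f)
    expect_equal(cv, cfg$cv_lame_target[[g]], tolerance = 1e-9)
  }
})
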