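small_cohort <- function(seed = 7) {
  cfg <- cohort_config(gaits = c("walk", "trot"), n_strides = 4)
  simulate_cohort(2, 1, cfg, seed = seed)
}

test_that("a zero-noise cohort validates almost perfectly", {
  cfg <- cohort_config(gaits = "trot", n_strides = 4,
                       gyro_noise_sd_dps = 0, marker_noise_sd_m = 0,
                       st_artifact_sd_m = 0, quat_noise_sd_deg = 0)
  cohort <- simulate_cohort(1, 1, cfg, seed = 2)
  study <- run_validation_study(cohort)
  expect_identical(length(study$exclusions), 0L)
  expect_true(all(study$per_limb$rmse_deg < 0.5))
  expect_true(all(study$per_limb$pcc > 0.9999))
  expect_true(all(study$per_limb$granger_agree))
})

test_that("the validation study aggregates by gait and group", {
  study <- run_validation_study(small_cohort())
  expect_setequal(study$summary$by_gait$gait, c("walk", "trot"))
  expect_setequal(study$summary$by_group$group, c("sound", "lame"))
  expect_identical(nrow(study$per_limb) + length(study$exclusions), 24L)
  for (g in c("walk", "trot")) {
    expect_s3_class(study$bland_altman[[g]]$fja, "bland_altman")
    expect_s3_class(study$bland_altman[[g]]$fjrom, "bland_altman")
  }
  expect_true(is.finite(study$granger_agree_percent))
})

test_that("the variability study assembles the lame-pair-only CV table", {
  cohort <- small_cohort()
  study <- run_variability_study(cohort)
  rec <- study$records
  # sound horses contribute two pairs per gait, lame horses one
  expect_identical(sum(rec$lameness == "sound"), 2L * 2L * 2L)
  expect_identical(sum(rec$lameness == "lame"), 1L * 2L)
  lame_limb <- cohort$horses$lame_limb[cohort$horses$group == "lame"]
  expected_pair <- if (lame_limb %in% c("LF", "RF")) "front" else "hind"
  expect_true(all(rec$limb_pair[rec$lameness == "lame"] == expected_pair))
  expect_true(all(rec$cv_percent >= 0))
  expect_s3_class(study$anova, "anova_partition")
})

test_that("study runs are deterministic given the cohort seed", {
  s1 <- run_validation_study(small_cohort(seed = 11))
  s2 <- run_validation_study(small_cohort(seed = 11))
  expect_identical(s1$per_limb, s2$per_limb)
})

test_that("angle CSV round-trips at full precision", {
  s <- angle_series(rnorm(100) * 50, 200, t0 = 0.25,
                    convention = "imu_zeroed")
  path <- withr::local_tempfile(fileext = ".csv")
  write_angle_csv(s, path)
  r <- read_angle_csv(path)
  expect_identical(r$values, s$values)
  expect_equal(r$rate_hz, 200, tolerance = 1e-9)
  expect_identical(r$t0, 0.25)
  expect_identical(r$convention, "imu_zeroed")
})

test_that("cohort directories round-trip the recordings exactly", {
  cohort <- simulate_cohort(1, 1, cohort_config(gaits = "walk",
                                                n_strides = 3), seed = 5)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(length(back$trials), length(cohort$trials))
  r0 <- cohort$trials[[1]]$recordings$LF
  r1 <- back$trials[[1]]$recordings$LF
  expect_identical(r1$imu$quat_cannon[, 1], r0$imu$quat_cannon[, 1])
  expect_identical(r1$imu$gyro_pastern[, 3], r0$imu$gyro_pastern[, 3])
  expect_identical(r1$omc$markers$fetlock[, 2], r0$omc$markers$fetlock[, 2])
  expect_identical(r1$truth$fja$values, r0$truth$fja$values)
  expect_equal(r1$truth$rom_deg_planted, r0$truth$rom_deg_planted)
  # a reloaded cohort is analyzable
  out <- analyze_limb_pair(r1)
  expect_lt(abs(out$fjrom_imu$mean_rom - r0$truth$rom_deg_planted), 2)
})

test_that("reading a missing cohort names the path", {
  expect_error(read_cohort("/nonexistent/cohort_dir"),
               "/nonexistent/cohort_dir")
})

test_that("run configuration round-trips through YAML unchanged", {
  cfg <- run_config(filter = list(cutoff_hz = 12),
                    stance = list(theta_low_frac = 0.1),
                    n_strides = 4, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_run_config(cfg, path)
  expect_identical(read_run_config(path), cfg)
  expect_error(run_config(filter = list(bogus = 1)), "unknown config")
})

test_that("reports embed the resolved configuration", {
  study <- run_validation_study(small_cohort())
  jpath <- withr::local_tempfile(fileext = ".json")
  write_validation_report(study, jpath)
  rep <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  expect_equal(rep$config$filter$cutoff_hz, 10)
  expect_equal(rep$config$granger$alpha, 0.01)
  expect_identical(nrow(rep$per_limb), nrow(study$per_limb))

  vstudy <- run_variability_study(small_cohort())
  cpath <- withr::local_tempfile(fileext = ".csv")
  j2 <- withr::local_tempfile(fileext = ".json")
  write_variability_report(vstudy, cpath, j2)
  tab <- utils::read.csv(cpath)
  expect_identical(nrow(tab), nrow(vstudy$records))
  rep2 <- jsonlite::read_json(j2, simplifyVector = TRUE)
  expect_true("anova" %in% names(rep2))
})
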