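#' Cohort simulation configuration
#'
#' Study-level generator settings for [simulate_cohort()]. Per-horse sound
#' ROMs are drawn around the front/hind x walk/trot population means; the
#' left-right asymmetry of a sound pair is parameterized by the expected
#' left-right CV of the pair, from which the per-side multiplicative SD is
#' derived as `sigma = CV/100 * sqrt(pi/2)` (for two sides drawn with
#' independent N(0, sigma) relative deviations, E[CV%] = 100 sigma
#' sqrt(2/pi)). The lame-limb amplitude factor is likewise derived from the
#' expected lame-vs-contralateral CV: for a pair (f R, R),
#' CV% = 100 sqrt(2) (1-f) / (1+f), inverted as `f = (1-c)/(1+c)` with
#' `c = CV/100/sqrt(2)`.
#'
#' @param gaits gaits simulated per horse (default both).
#' @param rom_mean,rom_sd named over `front_walk`, `hind_walk`, `front_trot`,
#'   `hind_trot`: population mean and between-horse SD of the sound FJROM,
#'   degrees.
#' @param cv_lr_target expected sound left-right CV (percent) per pair and
#'   gait, same names.
#' @param cv_lame_target expected lame-vs-contralateral CV (percent) per
#'   gait (names `walk`, `trot`).
#' @param lameness_factor_sd between-horse SD of the lameness factor.
#' @param lameness_factor_range clamp range of the drawn factor.
#' @param n_strides strides per record.
#' @param flexion_peak_ratio waveform double-peak asymmetry.
#' @param gyro_noise_sd_dps,marker_noise_sd_m,st_artifact_sd_m,quat_noise_sd_deg
#'   sensor noise levels (see [gait_params()]).
#' @param omc_offset_deg constant OMC convention offset, degrees.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(gaits = c("walk", "trot"),
                          rom_mean = c(front_walk = 57.79, hind_walk = 60.48,
                                       front_trot = 82.83, hind_trot = 89.40),
                          rom_sd = c(front_walk = 4.50, hind_walk = 6.10,
                                     front_trot = 6.64, hind_trot = 4.89),
                          cv_lr_target = c(front_walk = 3.00,
                                           front_trot = 2.51,
                                           hind_walk = 3.91,
                                           hind_trot = 3.60),
                          cv_lame_target = c(walk = 15.47, trot = 7.06),
                          lameness_factor_sd = 0.03,
                          lameness_factor_range = c(0.5, 0.98),
                          n_strides = 5, flexion_peak_ratio = 0.9,
                          gyro_noise_sd_dps = 1.0,
                          marker_noise_sd_m = 0.001,
                          st_artifact_sd_m = 0.002,
                          quat_noise_sd_deg = 0.3,
                          omc_offset_deg = 10) {
  gaits <- match.arg(gaits, c("walk", "trot"), several.ok = TRUE)
  asym <- cv_lr_target / 100 * sqrt(pi / 2)
  cc <- cv_lame_target / 100 / sqrt(2)
  lf_mean <- (1 - cc) / (1 + cc)
  structure(list(gaits = gaits, rom_mean = rom_mean, rom_sd = rom_sd,
                 cv_lr_target = cv_lr_target, asymmetry_sd = asym,
                 cv_lame_target = cv_lame_target,
                 lameness_factor_mean = lf_mean,
                 lameness_factor_sd = lameness_factor_sd,
                 lameness_factor_range = lameness_factor_range,
                 n_strides = n_strides,
                 flexion_peak_ratio = flexion_peak_ratio,
                 gyro_noise_sd_dps = gyro_noise_sd_dps,
                 marker_noise_sd_m = marker_noise_sd_m,
                 st_artifact_sd_m = st_artifact_sd_m,
                 quat_noise_sd_deg = quat_noise_sd_deg,
                 omc_offset_deg = omc_offset_deg),
            class = "cohort_config")
}

#' Simulate a cohort of sound and single-limb lame horses
#'
#' Generates one four-limb trial per horse and gait. Sound horses receive
#' per-horse pair ROMs drawn around the configured means with a small
#' left-right asymmetry; each lame horse has one randomly assigned lame limb
#' whose waveform amplitude is scaled by a per-horse, per-gait lameness
#' factor below 1. Fully reproducible under `seed`.
#'
#' @param n_sound,n_lame number of sound / lame horses (>= 0, total >= 1).
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return a `horse_cohort`: `trials` (list of `horse_trial`, horses x
#'   gaits), `horses` (data frame with id, group, lame limb), the config and
#'   seed.
#' @export
simulate_cohort <- function(n_sound = 7, n_lame = 7,
                            config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (n_sound < 0 || n_lame < 0 || n_sound + n_lame < 1)
    stop("need at least one horse")
  if (!is.null(seed)) set.seed(seed)
  limbs <- c("LF", "RF", "LH", "RH")
  ids <- c(if (n_sound > 0) sprintf("S%02d", seq_len(n_sound)),
           if (n_lame > 0) sprintf("L%02d", seq_len(n_lame)))
  groups <- c(rep("sound", n_sound), rep("lame", n_lame))
  lame_limbs <- ifelse(groups == "lame",
                       sample(limbs, n_sound + n_lame, replace = TRUE),
                       NA_character_)
  lf_jitter <- stats::rnorm(n_sound + n_lame, sd = config$lameness_factor_sd)

  trials <- list()
  for (h in seq_along(ids)) {
    for (g in config$gaits) {
      rom <- numeric(4); names(rom) <- limbs
      for (pair in c("front", "hind")) {
        key <- paste(pair, g, sep = "_")
        base_rom <- stats::rnorm(1, config$rom_mean[[key]],
                                 config$rom_sd[[key]])
        e <- stats::rnorm(2, sd = config$asymmetry_sd[[key]])
        side <- if (pair == "front") c("LF", "RF") else c("LH", "RH")
        rom[side] <- base_rom * (1 + e)
      }
      lf <- 1
      if (groups[h] == "lame") {
        lf <- config$lameness_factor_mean[[g]] + lf_jitter[h]
        lf <- min(max(lf, config$lameness_factor_range[1]),
                  config$lameness_factor_range[2])
      }
      base <- gait_params(
        g, n_strides = config$n_strides,
        flexion_peak_ratio = config$flexion_peak_ratio,
        gyro_noise_sd_dps = config$gyro_noise_sd_dps,
        marker_noise_sd_m = config$marker_noise_sd_m,
        st_artifact_sd_m = config$st_artifact_sd_m,
        quat_noise_sd_deg = config$quat_noise_sd_deg,
        omc_offset_deg = config$omc_offset_deg)
      trials[[length(trials) + 1L]] <-
        simulate_horse_trial(ids[h], g, rom,
                             lame_limb = if (groups[h] == "lame")
                               lame_limbs[h] else NULL,
                             lameness_factor = lf, base = base)
    }
  }
  structure(list(trials = trials,
                 horses = data.frame(horse_id = ids, group = groups,
                                     lame_limb = lame_limbs,
                                     stringsAsFactors = FALSE),
                 config = config, seed = seed,
                 n_sound = n_sound, n_lame = n_lame),
            class = "horse_cohort")
}

#' @export
print.horse_cohort <- function(x, ...) {
  cat(sprintf("<horse_cohort> %d sound + %d lame horses, gaits: %s (%d trials)\n",
              x$n_sound, x$n_lame, paste(x$config$gaits, collapse = ", "),
              length(x$trials)))
  invisible(x)
}
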