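#' Pipeline run configuration
#'
#' All tunable thresholds of the processing pipeline in one serializable
#' object, embedded verbatim in every study report for provenance. Defaults:
#' 4th-order 10 Hz zero-phase Butterworth low-pass; synchronization maxima
#' require prominence >= 20% of the trace's peak-to-peak range and separation
#' >= 0.2 stride; stance hysteresis at 8% / 15% of the robust maximum
#' resultant angular velocity with an 80 ms minimum stance; FJROM averaged
#' over 3 consecutive strides; Granger test with BIC-selected lag up to 20
#' samples at alpha = 0.01, agreement when either direction rejects;
#' repeated-measures-corrected Bland-Altman; ANOVA at alpha = 0.05.
#'
#' @param filter,sync,stance,granger,ba,anova named lists overriding
#'   individual entries of the corresponding default group.
#' @param n_strides strides averaged into each FJROM value.
#' @param seed optional integer recorded for provenance.
#' @return a `run_config` object.
#' @export
run_config <- function(filter = list(), sync = list(), stance = list(),
                       granger = list(), ba = list(), anova = list(),
                       n_strides = 3, seed = NULL) {
  merge_group <- function(defaults, user) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad)) stop("unknown config entries: ",
                          paste(bad, collapse = ", "))
    utils::modifyList(defaults, user)
  }
  cfg <- list(
    filter = merge_group(list(cutoff_hz = 10, order = 4), filter),
    sync = merge_group(list(prominence_frac = 0.2,
                            min_separation_frac = 0.2), sync),
    stance = merge_group(list(theta_low_frac = 0.08, theta_high_frac = 0.15,
                              min_stance_s = 0.08, robust_quantile = 0.98),
                         stance),
    granger = merge_group(list(max_lag = 20, alpha = 0.01,
                               decision = "either"), granger),
    ba = merge_group(list(method = "rm_corrected"), ba),
    anova = merge_group(list(alpha = 0.05), anova),
    n_strides = n_strides, seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

#' Process one limb's paired recording through the full pipeline
#'
#' Runs both observation channels of a [simulate_limb()]-style recording end
#' to end: the IMU channel (relative quaternion angle, low-pass filter), the
#' OMC channel (marker angle, spline resampling to the IMU rate, low-pass
#' filter), synchronization and y-axis alignment, gyroscope stride
#' segmentation, per-channel FJROM, and the per-trial agreement report.
#'
#' @param recording a `limb_recording`.
#' @param config a [run_config()].
#' @return list with `imu`, `omc` (aligned [angle_series()]), `sync`,
#'   `events` (in the aligned frame), `fjrom_imu`, `fjrom_omc`,
#'   and `agreement` (an [fja_agreement()]).
#' @export
analyze_limb_pair <- function(recording, config = run_config()) {
  stopifnot(inherits(recording, "limb_recording"))
  p <- recording$params
  stride_s <- recording$truth$stride_duration_s
  meta <- list(limb = recording$limb_id, gait = recording$gait)

  imu_raw <- relative_sagittal_angle(recording$imu$quat_cannon,
                                     recording$imu$quat_pastern,
                                     rate_hz = recording$imu$rate_hz,
                                     t0 = recording$imu$t0, meta = meta)
  imu_f <- butter_lowpass(imu_raw, config$filter$cutoff_hz,
                          config$filter$order)
  omc_raw <- fja_from_markers(recording$omc$markers,
                              rate_hz = recording$omc$rate_hz,
                              t0 = recording$omc$t0, meta = meta)
  omc_200 <- resample_spline(omc_raw, recording$imu$rate_hz)
  omc_f <- butter_lowpass(omc_200, config$filter$cutoff_hz,
                          config$filter$order)

  min_sep <- config$sync$min_separation_frac * stride_s
  al <- synchronize_and_align(imu_f, omc_f,
                              prominence_frac = config$sync$prominence_frac,
                              min_separation_s = min_sep)

  vres <- resultant_angular_velocity(recording$imu$gyro_pastern)
  ev <- segment_strides(vres, recording$imu$rate_hz,
                        theta_low_frac = config$stance$theta_low_frac,
                        theta_high_frac = config$stance$theta_high_frac,
                        min_stance_s = config$stance$min_stance_s,
                        robust_quantile = config$stance$robust_quantile)
  ev_al <- shift_events(ev,
                        by = al$sync$aligned_sync_index -
                          al$sync$imu_sync_index,
                        n_samples = length(al$imu$values))

  list(imu = al$imu, omc = al$omc, sync = al$sync, events = ev_al,
       fjrom_imu = compute_fjrom(al$imu, ev_al, config$n_strides),
       fjrom_omc = compute_fjrom(al$omc, ev_al, config$n_strides),
       agreement = fja_agreement(al$imu, al$omc,
                                 granger_max_lag = config$granger$max_lag,
                                 alpha = config$granger$alpha,
                                 granger_decision = config$granger$decision,
                                 meta = meta))
}

#' IMU-channel FJROM of one limb (no optical channel required)
#'
#' Filters the IMU angle trace, segments strides from the limb's own
#' gyroscope, and averages the per-stride range of motion; the quantity
#' entering the left-right variability analysis.
#'
#' @param recording a `limb_recording`.
#' @param config a [run_config()].
#' @return an `fjrom_summary`.
#' @export
limb_fjrom_imu <- function(recording, config = run_config()) {
  stopifnot(inherits(recording, "limb_recording"))
  imu_raw <- relative_sagittal_angle(recording$imu$quat_cannon,
                                     recording$imu$quat_pastern,
                                     rate_hz = recording$imu$rate_hz)
  imu_f <- butter_lowpass(imu_raw, config$filter$cutoff_hz,
                          config$filter$order)
  vres <- resultant_angular_velocity(recording$imu$gyro_pastern)
  ev <- segment_strides(vres, recording$imu$rate_hz,
                        theta_low_frac = config$stance$theta_low_frac,
                        theta_high_frac = config$stance$theta_high_frac,
                        min_stance_s = config$stance$min_stance_s,
                        robust_quantile = config$stance$robust_quantile)
  compute_fjrom(imu_f, ev, config$n_strides)
}

#' Run the IMU-vs-OMC validation study on a cohort
#'
#' Executes the full pipeline for every horse x gait x limb, collects
#' per-limb agreement measures, and aggregates them the way a method
#' validation is reported: mean +/- SD of RMSE and PCC by gait and by
#' lameness group, the fraction of limb-trials in Granger temporal
#' agreement, and Bland-Altman analyses of the pooled per-sample angles
#' (subjects = limb-trials) and of the per-limb FJROM values (subjects =
#' horses), separately per gait. Per-trial failures are logged and skipped,
#' not fatal.
#'
#' @param cohort a [simulate_cohort()] result (or compatible list of
#'   `horse_trial` objects in `$trials`).
#' @param config a [run_config()].
#' @return an `fja_validation_study`: `per_limb` data frame, `summary`
#'   tables, `bland_altman` per gait (samples and FJROM), `exclusions`,
#'   `config`.
#' @export
run_validation_study <- function(cohort, config = run_config()) {
  trials <- cohort$trials
  if (is.null(trials)) stop("cohort has no trials")
  rows <- list(); excl <- list()
  samples <- list()   # pooled aligned samples per gait
  for (tr in trials) {
    for (rec in tr$recordings) {
      res <- tryCatch(analyze_limb_pair(rec, config), error = function(e) e)
      if (inherits(res, "error")) {
        excl[[length(excl) + 1L]] <- list(horse_id = tr$horse_id,
                                          gait = tr$gait,
                                          limb = rec$limb_id,
                                          message = conditionMessage(res))
        next
      }
      ag <- res$agreement
      rows[[length(rows) + 1L]] <- data.frame(
        horse_id = tr$horse_id, gait = tr$gait,
        group = if (tr$is_lame) "lame" else "sound",
        limb = rec$limb_id,
        is_lame_limb = identical(rec$limb_id, tr$lame_limb),
        rmse_deg = ag$rmse_deg, pcc = ag$pcc, pcc_p = ag$pcc_p,
        granger_agree = ag$granger$agree,
        granger_p_fwd = ag$granger$p_fwd, granger_p_rev = ag$granger$p_rev,
        ba_bias = ag$bland_altman$bias,
        fjrom_imu = res$fjrom_imu$mean_rom,
        fjrom_omc = res$fjrom_omc$mean_rom,
        sync_lag_samples = res$sync$lag_samples,
        stringsAsFactors = FALSE)
      samples[[length(samples) + 1L]] <- data.frame(
        gait = tr$gait,
        subject = paste(tr$horse_id, tr$gait, rec$limb_id, sep = "_"),
        horse_id = tr$horse_id,
        imu = res$imu$values, omc = res$omc$values)
    }
  }
  if (!length(rows)) stop("no limb-trial could be processed")
  per_limb <- do.call(rbind, rows)
  pooled <- do.call(rbind, samples)

  agg <- function(df, by) {
    out <- do.call(rbind, lapply(split(df, df[[by]]), function(s) {
      data.frame(level = s[[by]][1], n = nrow(s),
                 rmse_mean = mean(s$rmse_deg), rmse_sd = stats::sd(s$rmse_deg),
                 pcc_mean = mean(s$pcc), pcc_sd = stats::sd(s$pcc),
                 granger_agree_frac = mean(s$granger_agree),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    names(out)[1] <- by
    out
  }
  ba <- list()
  for (g in unique(per_limb$gait)) {
    sg <- pooled[pooled$gait == g, ]
    pg <- per_limb[per_limb$gait == g, ]
    ba[[g]] <- list(
      fja = bland_altman_rm(sg$imu, sg$omc, subject = sg$subject,
                            method = config$ba$method),
      fjrom = bland_altman_rm(pg$fjrom_imu, pg$fjrom_omc,
                              subject = pg$horse_id,
                              method = config$ba$method))
  }
  structure(list(per_limb = per_limb,
                 summary = list(by_gait = agg(per_limb, "gait"),
                                by_group = agg(per_limb, "group")),
                 granger_agree_percent = 100 * mean(per_limb$granger_agree),
                 bland_altman = ba, exclusions = excl, config = config,
                 cohort_seed = cohort$seed),
            class = "fja_validation_study")
}

#' @export
print.fja_validation_study <- function(x, ...) {
  cat(sprintf("<fja_validation_study> %d limb-trials (%d excluded)\n",
              nrow(x$per_limb), length(x$exclusions)))
  for (i in seq_len(nrow(x$summary$by_gait))) {
    s <- x$summary$by_gait[i, ]
    cat(sprintf("  %-5s RMSE %.2f +/- %.2f deg | PCC %.3f +/- %.3f | Granger agree %.1f%%\n",
                s$gait, s$rmse_mean, s$rmse_sd, s$pcc_mean, s$pcc_sd,
                100 * s$granger_agree_frac))
  }
  cat(sprintf("  overall Granger temporal agreement: %.2f%% of limb-trials\n",
              x$granger_agree_percent))
  invisible(x)
}

#' @export
summary.fja_validation_study <- function(object, ...) {
  list(by_gait = object$summary$by_gait, by_group = object$summary$by_group,
       granger_agree_percent = object$granger_agree_percent,
       bland_altman = object$bland_altman)
}

#' Run the left-right FJROM variability study on a cohort
#'
#' For every horse x gait, computes the IMU-channel FJROM of both limbs of
#' each lateral pair and their coefficient of variation. Sound horses
#' contribute both the front and the hind pair; lame horses contribute only
#' the pair containing the lame limb (the lame limb and its contralateral).
#' The assembled CV table is then partitioned by a main-effects three-way
#' ANOVA on lameness, gait and limb pair.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config a [run_config()].
#' @return an `fja_variability_study`: `records` (the CV table), `anova`
#'   (an [anova3_partition()]), `exclusions`, `config`.
#' @export
run_variability_study <- function(cohort, config = run_config()) {
  trials <- cohort$trials
  if (is.null(trials)) stop("cohort has no trials")
  pairs <- list(front = c("LF", "RF"), hind = c("LH", "RH"))
  rows <- list(); excl <- list()
  for (tr in trials) {
    use_pairs <- if (tr$is_lame) {
      names(pairs)[vapply(pairs, function(p) tr$lame_limb %in% p,
                          logical(1))]
    } else names(pairs)
    for (pr in use_pairs) {
      roms <- tryCatch(
        vapply(pairs[[pr]], function(l)
          limb_fjrom_imu(tr$recordings[[l]], config)$mean_rom, numeric(1)),
        error = function(e) e)
      if (inherits(roms, "error")) {
        excl[[length(excl) + 1L]] <- list(horse_id = tr$horse_id,
                                          gait = tr$gait, pair = pr,
                                          message = conditionMessage(roms))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        horse_id = tr$horse_id, gait = tr$gait, limb_pair = pr,
        lameness = if (tr$is_lame) "lame" else "sound",
        rom_left = roms[1], rom_right = roms[2],
        cv_percent = cv_percent(roms), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no limb pair could be processed")
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(records = records,
                 anova = anova3_partition(records,
                                          alpha = config$anova$alpha),
                 exclusions = excl, config = config,
                 cohort_seed = cohort$seed),
            class = "fja_variability_study")
}

#' @export
print.fja_variability_study <- function(x, ...) {
  cat(sprintf("<fja_variability_study> %d left-right CV records (%d excluded)\n",
              nrow(x$records), length(x$exclusions)))
  cv <- tapply(x$records$cv_percent,
               list(x$records$lameness, x$records$gait), mean)
  for (l in rownames(cv)) for (g in colnames(cv)) {
    if (!is.na(cv[l, g]))
      cat(sprintf("  mean CV %-5s %-5s %6.2f%%\n", l, g, cv[l, g]))
  }
  print(x$anova)
  invisible(x)
}

#' Run the paper-shaped demonstration study
#'
#' Simulates a cohort of sound and single-limb lame horses at walk and trot
#' and runs both the IMU-vs-OMC validation study and the left-right FJROM
#' variability study on it.
#'
#' @param n_sound,n_lame cohort composition (default 7 + 7).
#' @param seed integer seed for the simulation.
#' @param cohort_cfg a [cohort_config()].
#' @param config a [run_config()].
#' @return an `fja_demo_study` with `cohort`, `validation`, `variability`.
#' @export
run_demo_study <- function(n_sound = 7, n_lame = 7, seed = 42,
                           cohort_cfg = cohort_config(),
                           config = run_config()) {
  cohort <- simulate_cohort(n_sound, n_lame, cohort_cfg, seed = seed)
  structure(list(cohort = cohort,
                 validation = run_validation_study(cohort, config),
                 variability = run_variability_study(cohort, config),
                 seed = seed),
            class = "fja_demo_study")
}

#' @export
print.fja_demo_study <- function(x, ...) {
  cat(sprintf("<fja_demo_study> seed %s\n", format(x$seed)))
  print(x$validation)
  print(x$variability)
  invisible(x)
}
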