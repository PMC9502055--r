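# File interchange: CSV for all numeric streams (full %.17g precision so
# write -> read round-trips exactly), JSON for reports and manifests, YAML
# for run configuration.

write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an angle series as CSV
#'
#' Columns `time_s`, `fja_deg`, `convention`; numeric values at full
#' precision. The reader reconstructs the uniform grid from the time column.
#'
#' @param series an [angle_series()].
#' @param path file path.
#' @return `write_angle_csv` the path, invisibly; `read_angle_csv` an
#'   [angle_series()].
#' @export
write_angle_csv <- function(series, path) {
  stopifnot(inherits(series, "angle_series"))
  write_csv_precise(as.data.frame(series), path)
}

#' @rdname write_angle_csv
#' @export
read_angle_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "fja_deg", "convention")
  if (!all(need %in% names(df)))
    stop("not an angle CSV (need columns ", paste(need, collapse = ", "), ")")
  rate <- 1 / stats::median(diff(df$time_s))
  angle_series(df$fja_deg, rate_hz = rate, t0 = df$time_s[1],
               convention = df$convention[1])
}

#' Write / read a simulated cohort directory
#'
#' One subdirectory per horse x gait trial holding per-limb CSVs (sensor
#' quaternions, gyroscope, marker trajectories, noise-free truth angle) and a
#' `trial.json` with the trial's parameters; a top-level `manifest.json`
#' records the cohort composition, configuration and seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return `write_cohort` the directory, invisibly; `read_cohort` a
#'   `horse_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "horse_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_sound = cohort$n_sound, n_lame = cohort$n_lame,
                   seed = cohort$seed, horses = cohort$horses,
                   config = unclass(cohort$config),
                   trials = vapply(cohort$trials, function(tr)
                     paste(tr$horse_id, tr$gait, sep = "_"), character(1)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (tr in cohort$trials) {
    tdir <- file.path(dir, paste(tr$horse_id, tr$gait, sep = "_"))
    dir.create(tdir, showWarnings = FALSE)
    meta <- list(horse_id = tr$horse_id, gait = tr$gait,
                 is_lame = tr$is_lame, lame_limb = tr$lame_limb,
                 lameness_factor = tr$lameness_factor,
                 limbs = lapply(tr$recordings, function(r)
                   list(params = unclass(r$params),
                        phase_offset = r$phase_offset,
                        truth = r$truth[c("stride_duration_s", "duty_factor",
                                          "toe_on_s", "toe_off_s",
                                          "rom_deg_planted",
                                          "lameness_factor")])))
    jsonlite::write_json(meta, file.path(tdir, "trial.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (rec in tr$recordings) {
      l <- rec$limb_id
      ti <- rec$imu$t0 + (seq_len(nrow(rec$imu$quat_cannon)) - 1) /
        rec$imu$rate_hz
      qc <- rec$imu$quat_cannon; qp <- rec$imu$quat_pastern
      write_csv_precise(data.frame(
        time_s = ti,
        qw_cannon = qc[, 1], qx_cannon = qc[, 2], qy_cannon = qc[, 3],
        qz_cannon = qc[, 4],
        qw_pastern = qp[, 1], qx_pastern = qp[, 2], qy_pastern = qp[, 3],
        qz_pastern = qp[, 4]),
        file.path(tdir, paste0(l, "_imu_quat.csv")))
      gy <- rec$imu$gyro_pastern
      write_csv_precise(data.frame(time_s = ti, wx = gy[, 1], wy = gy[, 2],
                                   wz = gy[, 3]),
                        file.path(tdir, paste0(l, "_imu_gyro.csv")))
      mk <- rec$omc$markers
      tm <- rec$omc$t0 + (seq_len(nrow(mk$fetlock)) - 1) / rec$omc$rate_hz
      write_csv_precise(data.frame(
        time_s = tm,
        px_proximal = mk$proximal[, 1], py_proximal = mk$proximal[, 2],
        px_fetlock = mk$fetlock[, 1], py_fetlock = mk$fetlock[, 2],
        px_distal = mk$distal[, 1], py_distal = mk$distal[, 2]),
        file.path(tdir, paste0(l, "_omc_markers.csv")))
      write_angle_csv(rec$truth$fja,
                      file.path(tdir, paste0(l, "_truth_fja.csv")))
    }
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath))
    stop("no cohort manifest found at '", mpath, "'")
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  trials <- lapply(man$trials, function(tname) {
    tdir <- file.path(dir, tname)
    meta <- jsonlite::read_json(file.path(tdir, "trial.json"),
                                simplifyVector = TRUE)
    recs <- lapply(c("LF", "RF", "LH", "RH"), function(l) {
      lm <- meta$limbs[[l]]
      p <- lm$params
      class(p) <- "gait_params"
      qdf <- utils::read.csv(file.path(tdir, paste0(l, "_imu_quat.csv")))
      gdf <- utils::read.csv(file.path(tdir, paste0(l, "_imu_gyro.csv")))
      mdf <- utils::read.csv(file.path(tdir, paste0(l, "_omc_markers.csv")))
      truth_fja <- read_angle_csv(file.path(tdir,
                                            paste0(l, "_truth_fja.csv")))
      truth_fja$convention <- "imu_zeroed"
      truth_fja$meta <- list(limb = l, gait = meta$gait, source = "truth")
      structure(list(
        limb_id = l, gait = meta$gait, params = p,
        phase_offset = lm$phase_offset,
        imu = list(rate_hz = p$imu_rate_hz, t0 = qdf$time_s[1],
                   quat_cannon = as.matrix(qdf[, 2:5]),
                   quat_pastern = as.matrix(qdf[, 6:9]),
                   gyro_pastern = as.matrix(gdf[, 2:4])),
        omc = list(rate_hz = p$omc_rate_hz, t0 = mdf$time_s[1],
                   markers = list(proximal = as.matrix(mdf[, 2:3]),
                                  fetlock = as.matrix(mdf[, 4:5]),
                                  distal = as.matrix(mdf[, 6:7]))),
        truth = c(list(fja = truth_fja), lm$truth)),
        class = "limb_recording")
    })
    names(recs) <- c("LF", "RF", "LH", "RH")
    structure(list(horse_id = meta$horse_id, gait = meta$gait,
                   is_lame = meta$is_lame,
                   lame_limb = if (is.null(meta$lame_limb)) NA_character_
                               else meta$lame_limb,
                   lameness_factor = meta$lameness_factor,
                   recordings = recs),
              class = "horse_trial")
  })
  cfg <- man$config
  class(cfg) <- "cohort_config"
  structure(list(trials = trials, horses = man$horses, config = cfg,
                 seed = man$seed, n_sound = man$n_sound,
                 n_lame = man$n_lame),
            class = "horse_cohort")
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path file path.
#' @return `write_run_config` the path, invisibly; `read_run_config` a
#'   [run_config()] identical to the one written.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass(config), precision = 15), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, c(cfg[c("filter", "sync", "stance", "granger", "ba",
                              "anova")],
                        list(n_strides = cfg$n_strides, seed = cfg$seed)))
}

#' Write a validation study report as JSON
#'
#' Emits the per-limb agreement table, the summary aggregates, the
#' Bland-Altman results, exclusions and the fully resolved configuration.
#'
#' @param study an `fja_validation_study`.
#' @param path output path.
#' @export
write_validation_report <- function(study, path) {
  stopifnot(inherits(study, "fja_validation_study"))
  ba <- lapply(study$bland_altman, function(g)
    lapply(g, function(b) unclass(b)))
  out <- list(config = unclass(study$config),
              cohort_seed = study$cohort_seed,
              summary = study$summary,
              granger_agree_percent = study$granger_agree_percent,
              bland_altman = ba,
              per_limb = study$per_limb,
              exclusions = study$exclusions)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a variability study as CSV + JSON
#'
#' The CV record table goes to `csv_path`; the ANOVA partition, exclusions
#' and configuration go to `json_path`.
#'
#' @param study an `fja_variability_study`.
#' @param csv_path,json_path output paths.
#' @export
write_variability_report <- function(study, csv_path, json_path) {
  stopifnot(inherits(study, "fja_variability_study"))
  write_csv_precise(study$records, csv_path)
  an <- study$anova
  out <- list(config = unclass(study$config),
              cohort_seed = study$cohort_seed,
              anova = list(table = an$table, residual = an$residual,
                           total_ss = an$total_ss, shapiro_p = an$shapiro_p,
                           ss_type = an$ss_type),
              exclusions = study$exclusions)
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(json_path)
}
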