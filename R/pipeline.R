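#' Resample an angle series with a not-a-knot cubic spline
#'
#' Interpolates the series onto the target-rate grid spanning the original
#' time range using a cubic interpolating spline with not-a-knot end
#' conditions (third-derivative continuity at the second and second-to-last
#' knots), the construction used by MATLAB-style `spline` interpolation. The
#' first original sample is preserved exactly; no extrapolation beyond the
#' original span is allowed.
#'
#' @param series an [angle_series()] (>= 4 samples).
#' @param target_rate_hz target sampling rate (default 200).
#' @return an [angle_series()] at `target_rate_hz`, same convention.
#' @export
resample_spline <- function(series, target_rate_hz = 200) {
  stopifnot(inherits(series, "angle_series"))
  x <- series_time(series)
  y <- series$values
  if (length(x) < 4L) stop("need at least 4 samples for spline resampling")
  t_end <- x[length(x)]
  xi <- seq(series$t0, t_end, by = 1 / target_rate_hz)
  yi <- notaknot_spline_eval(x, y, xi)
  angle_series(yi, rate_hz = target_rate_hz, t0 = series$t0,
               convention = series$convention, meta = series$meta)
}

# not-a-knot cubic spline: solve for knot second derivatives, evaluate at xi
notaknot_spline_eval <- function(x, y, xi) {
  n <- length(x)
  if (any(xi < x[1] - 1e-9) || any(xi > x[n] + 1e-9))
    stop("evaluation points outside the original span: extrapolation rejected")
  h <- diff(x)
  d <- diff(y) / h
  # triplets for the sparse system in M (second derivatives)
  ii <- c(1, 1, 1, n, n, n,
          rep(2:(n - 1), each = 3))
  jj <- c(1, 2, 3, n - 2, n - 1, n,
          as.vector(vapply(2:(n - 1), function(i) c(i - 1, i, i + 1),
                           numeric(3))))
  vv <- c(-h[2], h[1] + h[2], -h[1],
          -h[n - 1], h[n - 2] + h[n - 1], -h[n - 2],
          as.vector(vapply(2:(n - 1), function(i)
            c(h[i - 1], 2 * (h[i - 1] + h[i]), h[i]), numeric(3))))
  rhs <- c(0, rep(0, n - 2), 0)
  rhs[2:(n - 1)] <- 6 * (d[-1] - d[-(n - 1)])
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  M <- as.numeric(Matrix::solve(A, rhs))

  k <- findInterval(xi, x, rightmost.closed = TRUE)
  k[k < 1] <- 1L; k[k > n - 1] <- n - 1L
  hk <- h[k]
  a <- (x[k + 1] - xi) / hk
  b <- (xi - x[k]) / hk
  a * y[k] + b * y[k + 1] +
    ((a^3 - a) * M[k] + (b^3 - b) * M[k + 1]) * hk^2 / 6
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass filter forward and backward
#' (zero phase lag, squared magnitude response). Edge transients are handled
#' MATLAB/scipy-filtfilt style: the series is extended by odd reflection at
#' both ends and the filter state is initialized to its steady-state response,
#' so a constant series passes through exactly (DC gain exactly 1).
#'
#' @param series an [angle_series()].
#' @param cutoff_hz cutoff frequency in Hz (default 10); the sampling rate
#'   must exceed `2 * cutoff_hz`.
#' @param order filter order (default 4).
#' @return a filtered [angle_series()], same grid and convention.
#' @export
butter_lowpass <- function(series, cutoff_hz = 10, order = 4) {
  stopifnot(inherits(series, "angle_series"))
  if (series$rate_hz <= 2 * cutoff_hz)
    stop("sampling rate (", series$rate_hz,
         " Hz) must exceed twice the cutoff (", cutoff_hz, " Hz)")
  bf <- signal::butter(order, cutoff_hz / (series$rate_hz / 2), type = "low")
  # pad by ~3 cutoff periods so edge transients fully decay (the minimal
  # 3-coefficient pad leaves percent-level edge error at low cutoffs)
  padlen <- max(3L * (order + 1L), ceiling(3 * series$rate_hz / cutoff_hz))
  y <- filtfilt_padded(bf$b, bf$a, series$values, padlen = padlen)
  series_with(series, y)
}

# steady-state filter state for unit DC input (direct form II transposed)
lfilter_zi <- function(b, a) {
  nz <- length(a) - 1L
  A <- rbind(-a[-1], cbind(diag(1, nz - 1), 0))   # companion matrix
  B <- b[-1] - b[1] * a[-1]
  as.numeric(solve(diag(nz) - t(A), B))
}

# direct form II transposed filter with initial state
df2t_filter <- function(b, a, x, zi) {
  n <- length(x); nz <- length(b) - 1L
  z <- zi; y <- numeric(n)
  for (i in seq_len(n)) {
    yi <- b[1] * x[i] + z[1]
    for (k in seq_len(nz - 1L)) {
      z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi
    }
    z[nz] <- b[nz + 1] * x[i] - a[nz + 1] * yi
    y[i] <- yi
  }
  y
}

filtfilt_padded <- function(b, a, x, padlen = 3L * max(length(a), length(b))) {
  n <- length(x)
  if (n <= 3L * padlen)
    stop("series too short for stable zero-phase filtering (need > ",
         3L * padlen, " samples, got ", n, ")")
  zi <- lfilter_zi(b, a)
  xp <- c(2 * x[1] - x[(padlen + 1):2], x,
          2 * x[n] - x[(n - 1):(n - padlen)])
  y <- df2t_filter(b, a, xp, zi * xp[1])
  y <- rev(df2t_filter(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Locate the synchronization point of an angle trace
#'
#' Finds the index of the absolute minimum strictly between the first two
#' qualifying local maxima of the series. A maximum qualifies when its
#' topographic prominence is at least `prominence_frac` of the series'
#' peak-to-peak range; maxima closer together than `min_separation_s` are
#' merged (the higher one is kept).
#'
#' @param series an [angle_series()] (typically low-pass filtered).
#' @param prominence_frac prominence threshold as a fraction of the
#'   peak-to-peak range (default 0.2).
#' @param min_separation_s minimum separation between qualifying maxima in
#'   seconds; defaults to 0.1 s, and pipeline callers pass 0.2 x the expected
#'   stride duration.
#' @return the sample index (integer) of the synchronization minimum.
#' @export
find_sync_point <- function(series, prominence_frac = 0.2,
                            min_separation_s = 0.1) {
  stopifnot(inherits(series, "angle_series"))
  pk <- find_prominent_maxima(series$values,
                              prominence_frac * diff(range(series$values)),
                              min_sep = max(1L, round(min_separation_s *
                                                        series$rate_hz)))
  if (length(pk) < 2L) {
    stop("need at least 2 qualifying local maxima for synchronization; ",
         "detected peaks at indices [",
         paste(pk, collapse = ", "), "]")
  }
  lo <- pk[1] + 1L; hi <- pk[2] - 1L
  if (lo > hi) stop("first two maxima are adjacent; no interior minimum")
  lo + which.min(series$values[lo:hi]) - 1L
}

# strict local maxima filtered by absolute prominence and minimum separation
find_prominent_maxima <- function(v, min_prominence, min_sep = 1L) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1L
  if (!length(core)) return(integer(0))
  prom <- vapply(core, function(i) peak_prominence(v, i), numeric(1))
  keep <- core[prom >= min_prominence]
  if (length(keep) < 2L || min_sep <= 1L) return(keep)
  out <- keep[1]
  for (i in keep[-1]) {
    if (i - out[length(out)] >= min_sep) {
      out <- c(out, i)
    } else if (v[i] > v[out[length(out)]]) {
      out[length(out)] <- i
    }
  }
  out
}

peak_prominence <- function(v, i) {
  # walk left/right until a higher value; prominence relative to the higher
  # of the two interval minima
  left <- if (i > 1) {
    j <- max(c(0, which(v[1:(i - 1)] > v[i])))
    min(v[(j + 1):i])
  } else v[i]
  right <- if (i < length(v)) {
    j <- i + suppressWarnings(min(c(Inf, which(v[(i + 1):length(v)] > v[i]))))
    hi <- if (is.finite(j)) j else length(v)
    min(v[i:hi])
  } else v[i]
  v[i] - max(left, right)
}

#' Synchronize and vertically align two angle traces
#'
#' Both series (already at a common rate) are shifted so their
#' synchronization points (see [find_sync_point()]) coincide, cropped to the
#' overlapping span, and the second series is aligned on the y axis by
#' subtracting the difference of the two traces at the synchronization point.
#' After alignment the traces are equal at the synchronization sample.
#'
#' @param imu,omc [angle_series()] at the same rate.
#' @param prominence_frac,min_separation_s passed to [find_sync_point()].
#' @return list with `imu`, `omc` (aligned, convention `"common"`) and `sync`
#'   (a `sync_result`: original sync indices, lag in samples, y offset in
#'   degrees, and the common sync index in the aligned frame).
#' @export
synchronize_and_align <- function(imu, omc, prominence_frac = 0.2,
                                  min_separation_s = 0.1) {
  stopifnot(inherits(imu, "angle_series"), inherits(omc, "angle_series"))
  if (abs(imu$rate_hz - omc$rate_hz) > 1e-9)
    stop("series must share a sampling rate; resample first (",
         imu$rate_hz, " vs ", omc$rate_hz, " Hz)")
  s1 <- find_sync_point(imu, prominence_frac, min_separation_s)
  s2 <- find_sync_point(omc, prominence_frac, min_separation_s)
  n1 <- length(imu$values); n2 <- length(omc$values)
  m0 <- min(s1, s2) - 1L
  m1 <- min(n1 - s1, n2 - s2)
  y_off <- omc$values[s2] - imu$values[s1]
  t0 <- imu$t0 + (s1 - m0 - 1) / imu$rate_hz
  imu_out <- angle_series(imu$values[(s1 - m0):(s1 + m1)], imu$rate_hz,
                          t0 = t0, convention = "common", meta = imu$meta)
  omc_out <- angle_series(omc$values[(s2 - m0):(s2 + m1)] - y_off,
                          omc$rate_hz, t0 = t0, convention = "common",
                          meta = omc$meta)
  sync <- structure(list(imu_sync_index = s1, omc_sync_index = s2,
                         lag_samples = s2 - s1, y_offset_deg = y_off,
                         aligned_sync_index = m0 + 1L),
                    class = "sync_result")
  list(imu = imu_out, omc = omc_out, sync = sync)
}

#' @export
print.sync_result <- function(x, ...) {
  cat(sprintf(paste0("<sync_result> imu idx %d, omc idx %d ",
                     "(lag %+d samples), y offset %.3f deg\n"),
              x$imu_sync_index, x$omc_sync_index, x$lag_samples,
              x$y_offset_deg))
  invisible(x)
}

#' Segment strides from the resultant pastern angular velocity
#'
#' Stance phases are detected as sustained low-velocity intervals of the
#' resultant gyroscope signal using hysteresis thresholding: stance is entered
#' when the resultant drops below `theta_low_frac` of the trial's robust
#' maximum and left when it rises above `theta_high_frac`; candidate stances
#' shorter than `min_stance_s` are discarded. Toe-on is the stance entry
#' sample, toe-off the stance exit sample; a stride runs from one toe-on to
#' the next. A leading low-velocity interval whose entry was not observed is
#' ignored.
#'
#' @param gyro_resultant numeric vector from [resultant_angular_velocity()].
#' @param rate_hz sampling rate of the gyroscope signal.
#' @param theta_low_frac,theta_high_frac hysteresis thresholds as fractions of
#'   the robust maximum (defaults 0.08 and 0.15).
#' @param min_stance_s minimum stance duration in seconds (default 0.08).
#' @param robust_quantile quantile used as the robust maximum (default 0.98).
#' @param min_resultant_dps absolute floor (deg/s) below which the trial is
#'   considered motionless and rejected.
#' @return a `stride_events` object: integer vectors `toe_on`, `toe_off`
#'   (possibly one shorter when the record ends mid-stance), the rate, and
#'   `n_complete` strides.
#' @export
segment_strides <- function(gyro_resultant, rate_hz,
                            theta_low_frac = 0.08, theta_high_frac = 0.15,
                            min_stance_s = 0.08, robust_quantile = 0.98,
                            min_resultant_dps = 10) {
  v <- as.numeric(gyro_resultant)
  n <- length(v)
  if (!all(is.finite(v))) stop("gyro resultant must be finite")
  if (n < rate_hz) stop("need at least 1 s of gyroscope data")
  if (theta_high_frac <= theta_low_frac)
    stop("theta_high_frac must exceed theta_low_frac")
  vmax <- stats::quantile(v, robust_quantile, names = FALSE)
  if (vmax < min_resultant_dps)
    stop("no swing activity detected: robust maximum resultant velocity (",
         format(vmax, digits = 3), " deg/s) is below ", min_resultant_dps,
         " deg/s")
  lo <- theta_low_frac * vmax
  hi <- theta_high_frac * vmax
  min_n <- max(1L, round(min_stance_s * rate_hz))

  toe_on <- integer(0); toe_off <- integer(0)
  state <- if (v[1] < lo) "leading_low" else "swing"
  entry <- NA_integer_
  for (i in seq_len(n)) {
    if (state == "leading_low") {
      if (v[i] > hi) state <- "swing"
    } else if (state == "swing") {
      if (v[i] < lo) { state <- "stance"; entry <- i }
    } else {                                   # stance candidate
      if (v[i] > hi) {
        if (i - entry >= min_n) {
          toe_on <- c(toe_on, entry); toe_off <- c(toe_off, i)
        }
        state <- "swing"
      }
    }
  }
  if (state == "stance" && n - entry + 1L >= min_n)
    toe_on <- c(toe_on, entry)                 # trailing stance, exit unseen
  if (!length(toe_on))
    stop("no stance interval found (thresholds ",
         format(lo, digits = 3), "/", format(hi, digits = 3), " deg/s)")
  structure(list(toe_on = toe_on, toe_off = toe_off, rate_hz = rate_hz,
                 n_complete = max(0L, length(toe_on) - 1L)),
            class = "stride_events")
}

#' @export
print.stride_events <- function(x, ...) {
  cat(sprintf("<stride_events> %d toe-on, %d toe-off (%d complete strides) @ %g Hz\n",
              length(x$toe_on), length(x$toe_off), x$n_complete, x$rate_hz))
  invisible(x)
}

#' Shift stride events by a sample offset
#'
#' Used to re-index events (detected on the full gyroscope record) into the
#' frame of a cropped/aligned angle series. Events falling outside
#' `1..n_samples` are dropped pairwise.
#'
#' @param events a `stride_events` object.
#' @param by integer sample offset added to all indices.
#' @param n_samples optional length of the target series for bounds filtering.
#' @return a `stride_events` object.
#' @export
shift_events <- function(events, by, n_samples = NULL) {
  stopifnot(inherits(events, "stride_events"))
  on <- events$toe_on + as.integer(by)
  off <- if (length(events$toe_off)) events$toe_off + as.integer(by)
         else integer(0)
  if (!is.null(n_samples)) {
    keep <- on >= 1L & on <= n_samples
    on <- on[keep]
    off <- off[keep[seq_along(off)]]
    off <- off[off >= 1L & off <= n_samples]
  }
  structure(list(toe_on = on, toe_off = off, rate_hz = events$rate_hz,
                 n_complete = max(0L, length(on) - 1L)),
            class = "stride_events")
}

#' Per-stride fetlock joint range of motion
#'
#' For each complete stride (toe-on to next toe-on) the range of motion is
#' `|max(FJA) - min(FJA)|` over the stride's samples; the summary mean is
#' taken over the first `n_strides` complete strides (three consecutive
#' strides by convention).
#'
#' @param fja an [angle_series()].
#' @param events a `stride_events` object indexed in the same sample frame as
#'   `fja` (see [shift_events()]).
#' @param n_strides number of consecutive strides to average (default 3).
#' @return an `fjrom_summary`: `per_stride_rom` (all complete strides),
#'   `mean_rom` (over the first `n_strides`), `n_strides_used`.
#' @export
compute_fjrom <- function(fja, events, n_strides = 3) {
  stopifnot(inherits(fja, "angle_series"), inherits(events, "stride_events"))
  n <- length(fja$values)
  on <- events$toe_on[events$toe_on >= 1L & events$toe_on <= n]
  n_avail <- max(0L, length(on) - 1L)
  if (n_avail < n_strides)
    stop("only ", n_avail, " complete strides available, need ", n_strides)
  rom <- vapply(seq_len(n_avail), function(k) {
    w <- fja$values[on[k]:on[k + 1]]
    abs(max(w) - min(w))
  }, numeric(1))
  structure(list(per_stride_rom = rom,
                 mean_rom = mean(rom[seq_len(n_strides)]),
                 n_strides_used = as.integer(n_strides),
                 stride_starts = on[seq_len(n_avail)]),
            class = "fjrom_summary")
}

#' @export
print.fjrom_summary <- function(x, ...) {
  cat(sprintf("<fjrom_summary> mean ROM %.2f deg over %d strides (per-stride: %s)\n",
              x$mean_rom, x$n_strides_used,
              paste(sprintf("%.2f", x$per_stride_rom), collapse = ", ")))
  invisible(x)
}
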