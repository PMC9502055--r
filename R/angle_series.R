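#' Uniformly sampled joint-angle series
#'
#' Container for a joint-angle trace sampled on the implicit grid
#' `t0 + (0:(n-1)) / rate_hz`. The `convention` tag records the sign/zero
#' convention of the values: `"imu_raw"` (relative inter-sensor angle before
#' standing calibration), `"imu_zeroed"` (flexion positive, zero at the
#' standing calibration pose), `"omc_dorsal"` (dorsal angle from marker
#' geometry) or `"common"` (the pipeline's canonical flexion-positive,
#' standing-zero frame after y-axis alignment).
#'
#' @param values numeric vector of angles in degrees; must be finite.
#' @param rate_hz sampling rate in samples/second.
#' @param t0 time of the first sample in seconds.
#' @param convention one of `"imu_raw"`, `"imu_zeroed"`, `"omc_dorsal"`,
#'   `"common"`.
#' @param meta optional named list (limb id, gait, source, ...).
#' @return an object of class `angle_series`.
#' @export
angle_series <- function(values, rate_hz, t0 = 0,
                         convention = c("common", "imu_raw", "imu_zeroed",
                                        "omc_dorsal"),
                         meta = list()) {
  convention <- match.arg(convention)
  values <- as.numeric(values)
  if (length(values) < 1L) stop("angle_series needs at least one sample")
  if (!all(is.finite(values))) stop("angle values must be finite")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("rate_hz must be a positive scalar")
  structure(list(values = values, rate_hz = rate_hz, t0 = t0,
                 convention = convention, meta = meta),
            class = "angle_series")
}

#' Sample times of an angle series
#' @param series an [angle_series()].
#' @return numeric vector of times in seconds.
#' @export
series_time <- function(series) {
  stopifnot(inherits(series, "angle_series"))
  series$t0 + (seq_along(series$values) - 1) / series$rate_hz
}

#' @export
print.angle_series <- function(x, ...) {
  cat(sprintf("<angle_series> %d samples @ %g Hz, t0 = %.4g s, convention = %s\n",
              length(x$values), x$rate_hz, x$t0, x$convention))
  cat(sprintf("  range [%.2f, %.2f] deg\n", min(x$values), max(x$values)))
  if (length(x$meta)) {
    tag <- paste(names(x$meta), unlist(lapply(x$meta, format)),
                 sep = "=", collapse = ", ")
    cat("  meta:", tag, "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.angle_series <- function(x, ...) {
  data.frame(time_s = series_time(x), fja_deg = x$values,
             convention = x$convention)
}

#' @export
plot.angle_series <- function(x, ..., xlab = "time (s)", ylab = "FJA (deg)") {
  graphics::plot(series_time(x), x$values, type = "l",
                 xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
length.angle_series <- function(x) length(x$values)

# internal: copy with new values (and optionally convention), keeping the grid
series_with <- function(series, values, convention = series$convention,
                        t0 = series$t0, rate_hz = series$rate_hz) {
  angle_series(values, rate_hz = rate_hz, t0 = t0, convention = convention,
               meta = series$meta)
}

# internal: unwrap a degree series across +-180 jumps
unwrap_deg <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  jump <- round(d / 360)
  theta - c(0, cumsum(jump)) * 360
}

# internal: wrap to (-180, 180]
wrap_deg <- function(theta) {
  out <- theta - 360 * floor((theta + 180) / 360)
  out[out == -180] <- 180
  out
}
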