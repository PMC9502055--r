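#' One-stride fetlock joint angle template
#'
#' Builds a smooth, periodic one-stride FJA template on the unit phase circle
#' (phase 0 = toe-on). The template is a sum of wrapped Gaussian bumps:
#' positive bumps are flexion peaks, negative bumps extension peaks. The walk
#' morphology alternates flexion and extension bumps (a double peak of flexion
#' and two extension peaks per stride); the trot morphology has a double peak
#' of flexion in swing separated by a positive dip, and a single extension
#' peak in stance. The template is rescaled so that its exact continuous range
#' (max - min) equals `rom_deg`.
#'
#' Bump widths are chosen so the template is effectively band-limited below
#' about 7 Hz at the package's default stride durations, inside the pass-band
#' of the 10 Hz pipeline filter (see [butter_lowpass()]).
#'
#' @param gait `"walk"` or `"trot"`.
#' @param rom_deg planted range of motion in degrees (> 0).
#' @param flexion_peak_ratio relative height of the first flexion peak with
#'   respect to the second, in (0, 1]; 1 gives a symmetric double peak.
#' @return an object of class `fja_waveform`: a list with `fn(phase)` and
#'   `deriv(phase)` (degrees and degrees per unit phase, vectorized, periodic),
#'   the gait, the duty factor (stance fraction of the stride) and the planted
#'   range.
#' @examples
#' wf <- make_fja_waveform("trot", rom_deg = 80, flexion_peak_ratio = 0.9)
#' waveform_range(wf)
#' count_flexion_peaks(wf)
#' @export
make_fja_waveform <- function(gait, rom_deg, flexion_peak_ratio = 1) {
  if (length(gait) != 1L || !gait %in% c("walk", "trot"))
    stop("unknown gait '", paste(gait, collapse = ","),
         "': must be \"walk\" or \"trot\"")
  if (!is.numeric(rom_deg) || length(rom_deg) != 1L || !is.finite(rom_deg) ||
      rom_deg <= 0)
    stop("rom_deg must be a positive finite scalar")
  r <- flexion_peak_ratio
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0 || r > 1)
    stop("flexion_peak_ratio must be in (0, 1]")

  if (gait == "walk") {
    duty <- 0.60
    bumps <- data.frame(
      center = c(0.12, 0.32, 0.52, 0.78),
      width  = c(0.065, 0.085, 0.080, 0.085),
      amp    = c(-0.60, 0.52 * r, -0.45, 0.52))
  } else {
    duty <- 0.40
    bumps <- data.frame(
      center = c(0.18, 0.53, 0.82),
      width  = c(0.120, 0.110, 0.110),
      amp    = c(-0.45, 0.62 * r, 0.62))
  }

  raw <- function(p) gauss_bumps(p, bumps$center, bumps$width, bumps$amp)
  ext <- template_extrema(raw, bumps$center)
  scale <- rom_deg / (ext$max - ext$min)

  wf <- list(
    fn = function(phase) scale * gauss_bumps(phase, bumps$center,
                                             bumps$width, bumps$amp),
    deriv = function(phase) scale * gauss_bumps_deriv(phase, bumps$center,
                                                      bumps$width, bumps$amp),
    gait = gait, rom_deg = rom_deg, flexion_peak_ratio = r,
    duty_factor = duty, bumps = bumps, scale = scale)
  class(wf) <- "fja_waveform"
  wf
}

#' @export
print.fja_waveform <- function(x, ...) {
  cat(sprintf("<fja_waveform> %s, ROM %.2f deg, peak ratio %.2f, duty %.2f\n",
              x$gait, x$rom_deg, x$flexion_peak_ratio, x$duty_factor))
  invisible(x)
}

#' Exact continuous range of a waveform template
#'
#' Locates the template's true extrema (grid scan refined with
#' [stats::optimize()] around each candidate) and returns `max - min`.
#'
#' @param wf an [make_fja_waveform()] template.
#' @return range of the template in degrees.
#' @export
waveform_range <- function(wf) {
  stopifnot(inherits(wf, "fja_waveform"))
  ext <- template_extrema(wf$fn, wf$bumps$center)
  ext$max - ext$min
}

#' Count flexion / extension peaks of a waveform template
#'
#' Flexion peaks are strict local maxima with positive value; extension peaks
#' are strict local minima with negative value (flexion positive, extension
#' negative relative to the standing zero). Counting is circular over one
#' stride.
#'
#' @param wf an [make_fja_waveform()] template.
#' @param n_grid grid resolution used for the scan.
#' @return integer count.
#' @export
count_flexion_peaks <- function(wf, n_grid = 4096) {
  ext <- circular_extrema(wf, n_grid)
  sum(ext$maxima_values > 0)
}

#' @rdname count_flexion_peaks
#' @export
count_extension_peaks <- function(wf, n_grid = 4096) {
  ext <- circular_extrema(wf, n_grid)
  sum(ext$minima_values < 0)
}

#' Count all strict local extrema of a template over one cycle
#' @rdname count_flexion_peaks
#' @export
count_strict_extrema <- function(wf, n_grid = 4096) {
  ext <- circular_extrema(wf, n_grid)
  c(maxima = length(ext$maxima_values), minima = length(ext$minima_values))
}

# --- internals ---------------------------------------------------------------

# sum of Gaussian bumps wrapped on the unit circle; vectorized over p
gauss_bumps <- function(p, centers, widths, amps) {
  p <- p %% 1
  out <- numeric(length(p))
  for (i in seq_along(centers)) {
    for (k in -3:3) {
      out <- out + amps[i] * exp(-((p - centers[i] + k) / widths[i])^2)
    }
  }
  out
}

gauss_bumps_deriv <- function(p, centers, widths, amps) {
  p <- p %% 1
  out <- numeric(length(p))
  for (i in seq_along(centers)) {
    for (k in -3:3) {
      u <- (p - centers[i] + k) / widths[i]
      out <- out - amps[i] * 2 * u / widths[i] * exp(-u^2)
    }
  }
  out
}

# true extrema of a periodic template: coarse grid scan, then optimize
# in a bracket around each strict grid extremum
template_extrema <- function(fn, centers, n_grid = 2048) {
  p <- seq(0, 1, length.out = n_grid + 1)[-(n_grid + 1)]
  v <- fn(p)
  h <- 1 / n_grid
  left <- c(v[n_grid], v[-n_grid]); right <- c(v[-1], v[1])
  refine <- function(idx, maximum) {
    vapply(idx, function(i) {
      opt <- stats::optimize(fn, lower = p[i] - h, upper = p[i] + h,
                             maximum = maximum, tol = 1e-12)
      if (maximum) opt$objective else opt$objective
    }, numeric(1))
  }
  imax <- which(v > left & v > right)
  imin <- which(v < left & v < right)
  list(max = max(refine(imax, TRUE)), min = min(refine(imin, FALSE)))
}

circular_extrema <- function(wf, n_grid = 4096) {
  p <- seq(0, 1, length.out = n_grid + 1)[-(n_grid + 1)]
  v <- wf$fn(p)
  left <- c(v[n_grid], v[-n_grid]); right <- c(v[-1], v[1])
  list(maxima_values = v[v > left & v > right],
       minima_values = v[v < left & v < right])
}

# pastern swing-rotation profile: absolute pastern angle over the stride,
# quiet in stance, two opposite rotation lobes spanning swing. Lobe placement
# (centers duty + 0.24/0.76 of swing, widths 0.13/0.12 of swing) puts the
# sustained low-angular-velocity interval within ~2% of the planted stance.
swing_profile_bumps <- function(duty) {
  sw <- 1 - duty
  data.frame(center = duty + c(0.24, 0.76) * sw,
             width  = c(0.13, 0.12) * sw,
             amp    = c(-35, 45))
}

swing_profile <- function(p, duty) {
  b <- swing_profile_bumps(duty)
  gauss_bumps(p, b$center, b$width, b$amp)
}

swing_profile_deriv <- function(p, duty) {
  b <- swing_profile_bumps(duty)
  gauss_bumps_deriv(p, b$center, b$width, b$amp)
}
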