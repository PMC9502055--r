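#' Root mean square error between two angle sequences
#'
#' `sqrt(sum((x - y)^2) / n)`, the per-sample accuracy measure between the
#' IMU-derived and optically derived joint angle traces.
#'
#' @param x,y numeric vectors of equal length (degrees).
#' @return RMSE in degrees.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  if (length(x) < 1L) stop("need at least one sample")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  sqrt(mean((x - y)^2))
}

#' Pearson correlation between two angle sequences
#'
#' Product-moment correlation with a two-sided p-value, measuring the strength
#' of the linear relationship between the two measurement systems' traces.
#'
#' @param x,y numeric vectors of equal length, n >= 3, both with nonzero
#'   variance.
#' @return list with `estimate` and `p_value`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(estimate = unname(ct$estimate), p_value = ct$p.value)
}

#' Coefficient of variation in percent
#'
#' `CV[%] = sd / mean x 100` with the sample (n-1) standard deviation; used
#' for left-right range-of-motion variability.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
cv_percent <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("values must be finite")
  m <- mean(values)
  if (abs(m) < 1e-12) stop("mean is zero: CV undefined")
  stats::sd(values) / m * 100
}

#' Granger temporal-agreement test between two traces
#'
#' Tests, in both directions, whether past values of one series improve the
#' prediction of the other beyond its own past (Granger causality), used here
#' as a criterion of temporal agreement between the IMU and OMC angle
#' patterns. Both series are first-differenced by default. The lag order is
#' selected by an information criterion on the unrestricted regression (own
#' plus cross lags, up to `max_lag`); the restricted (own lags only) and
#' unrestricted regressions are then compared with an F test at that order.
#'
#' @param x,y numeric vectors (e.g. IMU and OMC angle traces).
#' @param max_lag maximum lag order considered (default 20 samples, 100 ms at
#'   200 Hz).
#' @param alpha significance level for the agreement verdict (default 0.01).
#' @param difference first-difference the series before testing (default
#'   TRUE).
#' @param ic `"bic"` or `"aic"` for lag selection.
#' @param decision `"either"` (default): agreement when the null of no
#'   predictive content is rejected in at least one direction; `"both"`:
#'   require rejection in both directions.
#' @return a `granger_result`: `lag_order` (per direction), `p_fwd`
#'   (x predicting y), `p_rev` (y predicting x), `agree`, `alpha`.
#' @export
granger_agreement <- function(x, y, max_lag = 20, alpha = 0.01,
                              difference = TRUE, ic = c("bic", "aic"),
                              decision = c("either", "both")) {
  ic <- match.arg(ic)
  decision <- match.arg(decision)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant series: Granger test undefined")
  if (difference) { x <- diff(x); y <- diff(y) }
  n <- length(x)
  if (n <= 10 * max_lag)
    stop("series too short for max_lag = ", max_lag,
         " (need > ", 10 * max_lag, " differenced samples, got ", n, ")")
  fwd <- granger_one_direction(cause = x, target = y, max_lag, ic)
  rev <- granger_one_direction(cause = y, target = x, max_lag, ic)
  agree <- if (decision == "either") {
    fwd$p_value < alpha || rev$p_value < alpha
  } else {
    fwd$p_value < alpha && rev$p_value < alpha
  }
  structure(list(lag_order = c(fwd = fwd$lag, rev = rev$lag),
                 p_fwd = fwd$p_value, p_rev = rev$p_value,
                 F_fwd = fwd$statistic, F_rev = rev$statistic,
                 agree = agree, alpha = alpha, decision = decision),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf(paste0("<granger_result> lags (%d, %d); p_fwd = %.3g, ",
                     "p_rev = %.3g; agree = %s at alpha = %g (%s)\n"),
              x$lag_order[1], x$lag_order[2], x$p_fwd, x$p_rev,
              x$agree, x$alpha, x$decision))
  invisible(x)
}

# lag selection by IC on the unrestricted (own + cross lags) regression,
# then restricted-vs-unrestricted F at the chosen order
granger_one_direction <- function(cause, target, max_lag, ic) {
  # common estimation sample across candidate lags: rows max_lag+1 .. n
  emb_t <- stats::embed(target, max_lag + 1L)
  emb_c <- stats::embed(cause, max_lag + 1L)
  yy <- emb_t[, 1]
  n_eff <- length(yy)
  crit <- vapply(seq_len(max_lag), function(p) {
    X <- cbind(1, emb_t[, 2:(p + 1), drop = FALSE],
               emb_c[, 2:(p + 1), drop = FALSE])
    rss <- sum(stats::lm.fit(X, yy)$residuals^2)
    pen <- if (ic == "bic") log(n_eff) else 2
    n_eff * log(rss / n_eff) + pen * ncol(X)
  }, numeric(1))
  p <- which.min(crit)
  X0 <- cbind(1, emb_t[, 2:(p + 1), drop = FALSE])
  X1 <- cbind(X0, emb_c[, 2:(p + 1), drop = FALSE])
  rss0 <- sum(stats::lm.fit(X0, yy)$residuals^2)
  rss1 <- sum(stats::lm.fit(X1, yy)$residuals^2)
  df2 <- n_eff - ncol(X1)
  Fstat <- ((rss0 - rss1) / p) / (rss1 / df2)
  list(lag = p, statistic = Fstat,
       p_value = stats::pf(Fstat, p, df2, lower.tail = FALSE))
}

#' Bland-Altman limits of agreement, optionally repeated-measures corrected
#'
#' Computes the bias (mean of the pairwise differences `x - y`) and 95%
#' limits of agreement. With `method = "pooled"` the limits are
#' `bias +/- 1.96 * SD(differences)`. With `method = "rm_corrected"`
#' (multiple paired observations per subject) the difference variance is
#' decomposed by a one-way analysis of the differences by subject: the
#' within-subject mean square plus the between-subject variance component
#' (estimated from the subject-means mean square) give the total variance
#' entering the limits, so repeated measures on the same subject do not
#' artificially narrow them.
#'
#' @param x,y paired measurements (equal length).
#' @param subject subject/grouping factor of the pairs; required for
#'   `"rm_corrected"` with at least 2 subjects, each with at least 2 pairs
#'   (otherwise the function falls back to `"pooled"` with a warning).
#' @param method `"rm_corrected"` (default) or `"pooled"`.
#' @return a `bland_altman` object: `bias`, `loa_low`, `loa_high`, `sd_total`,
#'   `method`, `n`, `n_subjects`.
#' @export
bland_altman_rm <- function(x, y, subject = NULL,
                            method = c("rm_corrected", "pooled")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  if (!all(is.finite(d))) stop("pairs must be finite")
  n <- length(d)
  if (method == "rm_corrected") {
    if (is.null(subject)) {
      warning("no subject grouping supplied; falling back to pooled method")
      method <- "pooled"
    } else {
      subject <- as.factor(subject)
      if (length(subject) != n) stop("subject must match the pairs in length")
      m <- table(subject)
      if (length(m) < 2L || any(m < 2L)) {
        warning("rm_corrected needs >= 2 subjects with >= 2 pairs each; ",
                "falling back to pooled method")
        method <- "pooled"
      }
    }
  }
  bias <- mean(d)
  if (method == "pooled") {
    sd_tot <- stats::sd(d)
    n_subj <- if (is.null(subject)) 1L else length(unique(subject))
  } else {
    k <- nlevels(subject)
    m <- as.numeric(table(subject))
    grand <- bias
    means <- tapply(d, subject, mean)
    ss_between <- sum(m * (means - grand)^2)
    ss_within <- sum((d - means[subject])^2)
    ms_between <- ss_between / (k - 1)
    ms_within <- ss_within / (n - k)
    n0 <- (n - sum(m^2) / n) / (k - 1)
    var_between <- max(0, (ms_between - ms_within) / n0)
    sd_tot <- sqrt(ms_within + var_between)
    n_subj <- k
  }
  structure(list(bias = bias, loa_low = bias - 1.96 * sd_tot,
                 loa_high = bias + 1.96 * sd_tot, sd_total = sd_tot,
                 method = method, n = n, n_subjects = n_subj),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.3f, LoA [%.3f, %.3f] (%s, n = %d, %d subjects)\n",
              x$bias, x$loa_low, x$loa_high, x$method, x$n, x$n_subjects))
  invisible(x)
}

#' Agreement report for one aligned limb-trial pair
#'
#' Bundles the per-sample agreement measures between an aligned IMU and OMC
#' angle trace of one limb and gait: RMSE, Pearson correlation, the Granger
#' temporal-agreement verdict, and Bland-Altman bias and limits of agreement
#' over the paired samples.
#'
#' @param imu,omc aligned [angle_series()] (equal length) or numeric vectors.
#' @param granger_max_lag,alpha,granger_decision passed to
#'   [granger_agreement()].
#' @param ba_method Bland-Altman method over the trial's samples; within a
#'   single trial there is one "subject", so the default is `"pooled"`.
#' @param meta optional named list describing the trial.
#' @return an `fja_agreement` object.
#' @export
fja_agreement <- function(imu, omc, granger_max_lag = 20, alpha = 0.01,
                          granger_decision = "either", ba_method = "pooled",
                          meta = list()) {
  xi <- if (inherits(imu, "angle_series")) imu$values else as.numeric(imu)
  yo <- if (inherits(omc, "angle_series")) omc$values else as.numeric(omc)
  cc <- pcc(xi, yo)
  structure(list(
    rmse_deg = rmse(xi, yo),
    pcc = cc$estimate, pcc_p = cc$p_value,
    granger = granger_agreement(xi, yo, max_lag = granger_max_lag,
                                alpha = alpha, decision = granger_decision),
    bland_altman = bland_altman_rm(xi, yo, method = ba_method),
    n = length(xi), meta = meta), class = "fja_agreement")
}

#' @export
print.fja_agreement <- function(x, ...) {
  cat(sprintf("<fja_agreement> n = %d samples\n", x$n))
  cat(sprintf("  RMSE %.2f deg | PCC %.4f (p = %.3g)\n",
              x$rmse_deg, x$pcc, x$pcc_p))
  cat(sprintf("  Granger agree: %s (p_fwd %.3g, p_rev %.3g)\n",
              x$granger$agree, x$granger$p_fwd, x$granger$p_rev))
  cat(sprintf("  Bland-Altman bias %.3f deg, LoA [%.2f, %.2f]\n",
              x$bland_altman$bias, x$bland_altman$loa_low,
              x$bland_altman$loa_high))
  invisible(x)
}
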