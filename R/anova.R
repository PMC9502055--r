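#' Three-way ANOVA variance partition of left-right ROM variability
#'
#' Main-effects ANOVA of the left-right FJROM coefficient of variation on the
#' factors lameness (sound/lame), gait (walk/trot) and limb pair
#' (front/hind), with no horse-level clustering term. Each factor's share of
#' the total variation is reported as `SS_factor / SS_total x 100` (the
#' "percent of total variation" convention); residuals are checked for
#' normality with a Shapiro-Wilk test beforehand (a warning, not an error, on
#' rejection). Sums of squares are Type II (identical to Type I on a balanced
#' design); factors with fewer than two observed levels are dropped with a
#' warning.
#'
#' @param records data frame with columns `cv_percent` (response) and the
#'   factors `lameness`, `gait`, `limb_pair` (optionally `horse_id`, carried
#'   through but unused by the model).
#' @param alpha significance level reported alongside the F tests
#'   (default 0.05).
#' @return an `anova_partition` object: a per-factor table (`ss`, `df`, `F`,
#'   `p`, `percent_of_total`), residual and total SS, the Shapiro-Wilk
#'   p-value, and the fitted model.
#' @export
anova3_partition <- function(records, alpha = 0.05) {
  if (!is.data.frame(records) || !"cv_percent" %in% names(records))
    stop("records must be a data frame with a cv_percent column")
  if (any(records$cv_percent < 0)) stop("cv_percent must be non-negative")
  factors <- c("lameness", "gait", "limb_pair")
  missing_cols <- setdiff(factors, names(records))
  if (length(missing_cols))
    stop("records lacks factor column(s): ", paste(missing_cols, collapse = ", "))
  for (f in factors) records[[f]] <- factor(records[[f]])
  usable <- factors[vapply(factors, function(f)
    nlevels(droplevels(records[[f]])) >= 2L, logical(1))]
  dropped <- setdiff(factors, usable)
  if (length(dropped))
    warning("factor(s) with a single level dropped from the model: ",
            paste(dropped, collapse = ", "))
  if (!length(usable)) stop("no factor has two levels; nothing to test")
  y <- records$cv_percent
  ss_total <- sum((y - mean(y))^2)

  form <- stats::as.formula(paste("cv_percent ~", paste(usable, collapse = " + ")))
  fit <- stats::lm(form, data = records)

  sw_p <- NA_real_
  if (ss_total > 1e-10 && length(y) >= 3 && length(y) <= 5000 &&
      stats::df.residual(fit) >= 3 &&
      stats::sd(stats::residuals(fit)) > 1e-10) {
    sw <- stats::shapiro.test(stats::residuals(fit))
    sw_p <- sw$p.value
    if (sw_p < alpha)
      warning(sprintf(paste0("Shapiro-Wilk rejects normality of residuals ",
                             "(p = %.3g); ANOVA p-values are approximate"),
                      sw_p))
  }

  if (ss_total <= 1e-10) {
    tab <- data.frame(factor = usable, ss = 0, df = NA_integer_,
                      F = NA_real_, p = NA_real_, percent_of_total = 0,
                      stringsAsFactors = FALSE)
    res <- list(ss = 0, df = stats::df.residual(fit), percent_of_total = 0)
  } else {
    # a saturated fit (zero residual df) has no Type II tests; fall back to
    # sequential sums of squares with NA test statistics
    a2 <- if (stats::df.residual(fit) > 0) car::Anova(fit, type = 2)
          else stats::anova(fit)
    idx <- match(usable, rownames(a2))
    tab <- data.frame(factor = usable,
                      ss = a2[idx, "Sum Sq"],
                      df = a2[idx, "Df"],
                      F = a2[idx, "F value"],
                      p = a2[idx, "Pr(>F)"],
                      percent_of_total = a2[idx, "Sum Sq"] / ss_total * 100,
                      stringsAsFactors = FALSE)
    rss <- a2["Residuals", "Sum Sq"]
    res <- list(ss = rss, df = a2["Residuals", "Df"],
                percent_of_total = rss / ss_total * 100)
  }
  structure(list(table = tab, residual = res, total_ss = ss_total,
                 shapiro_p = sw_p, alpha = alpha, dropped_factors = dropped,
                 model = fit, ss_type = "II"),
            class = "anova_partition")
}

#' @export
print.anova_partition <- function(x, ...) {
  cat("<anova_partition> main-effects ANOVA of left-right ROM CV\n")
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-10s SS %8.2f  F %7.2f  p %9.3g  %% of total %6.2f\n",
                tab$factor[i], tab$ss[i], tab$F[i], tab$p[i],
                tab$percent_of_total[i]))
  }
  cat(sprintf("  %-10s SS %8.2f                         %% of total %6.2f\n",
              "residual", x$residual$ss, x$residual$percent_of_total))
  if (is.finite(x$shapiro_p))
    cat(sprintf("  Shapiro-Wilk residual normality p = %.3g\n", x$shapiro_p))
  invisible(x)
}
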