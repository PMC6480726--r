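# Multi-method agreement analysis: two-way variance-components ANOVA,
# Tukey HSD on method means, and pairwise agreement regressions.

check_measurement_table <- function(table) {
  stopifnot(all(c("participant", "method", "concentration") %in%
                  names(table)))
  m <- factor(table$method); p <- factor(table$participant)
  if (nlevels(m) < 2L || nlevels(p) < 2L)
    stop_lfnmr("need >= 2 methods and >= 2 participants",
               class = "lfnmr_validation_error")
  counts <- table(m, p)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    stop_lfnmr("unbalanced method x participant layout; use the pairwise ",
               "agreement_regression path (or a mixed model) instead",
               class = "lfnmr_unbalanced_error")
  list(method = m, participant = p, replicates = counts[1, 1])
}

#' Two-way variance-components ANOVA for method agreement
#'
#' Fits the two-way model \eqn{y_{ijk} = \mu + M_i + P_j + e_{ijk}} with
#' method a fixed effect and participant a random effect, on a balanced
#' method-by-participant table. F tests for both effects use the residual
#' mean square; the between-participant variance component is estimated
#' from expected mean squares as \eqn{(MS_P - MS_E)/(a r)} with `a`
#' methods and `r` replicates per cell, truncated at zero (flagged) when
#' the point estimate is negative.
#'
#' @param table Long-format data frame with columns `participant`,
#'   `method`, `concentration`.
#' @return List of class `vc_anova`: the ANOVA table (sums of squares
#'   partition exactly), per-effect F and p, `sigma2_participant`,
#'   `sigma2_error`, `truncated` flag, and the underlying [stats::aov()]
#'   fit.
#' @export
variance_components_anova <- function(table) {
  chk <- check_measurement_table(table)
  if (stats::sd(table$concentration) == 0) {
    # degenerate flat table: all sums of squares vanish
    return(structure(list(
      anova = NULL, F_method = NA_real_, p_method = NA_real_,
      F_participant = NA_real_, p_participant = NA_real_,
      sigma2_participant = 0, sigma2_error = 0,
      ss = c(method = 0, participant = 0, error = 0),
      truncated = FALSE, aov = NULL), class = "vc_anova"))
  }
  d <- data.frame(y = table$concentration, method = chk$method,
                  participant = chk$participant)
  fit <- stats::aov(y ~ method + participant, data = d)
  an <- stats::anova(fit)
  ms <- an[["Mean Sq"]]; df <- an[["Df"]]; ss <- an[["Sum Sq"]]
  mse <- ms[3]
  a <- nlevels(chk$method); r <- chk$replicates
  sigma2_p <- (ms[2] - mse) / (a * r)
  truncated <- FALSE
  if (is.na(sigma2_p)) sigma2_p <- 0
  if (sigma2_p < 0) { sigma2_p <- 0; truncated <- TRUE }
  f_m <- if (mse > 0) ms[1] / mse else NA_real_
  f_p <- if (mse > 0) ms[2] / mse else NA_real_
  structure(list(
    anova = an,
    F_method = f_m,
    p_method = if (is.na(f_m)) NA_real_ else
      stats::pf(f_m, df[1], df[3], lower.tail = FALSE),
    F_participant = f_p,
    p_participant = if (is.na(f_p)) NA_real_ else
      stats::pf(f_p, df[2], df[3], lower.tail = FALSE),
    sigma2_participant = sigma2_p,
    sigma2_error = mse,
    ss = stats::setNames(ss, c("method", "participant", "error")),
    truncated = truncated, aov = fit),
    class = "vc_anova")
}

#' @export
print.vc_anova <- function(x, ...) {
  cat("<vc_anova> method (fixed) + participant (random)\n")
  cat(sprintf("  method:      F = %s, p = %s\n", format(x$F_method),
              format.pval(x$p_method)))
  cat(sprintf("  participant: F = %s, p = %s\n", format(x$F_participant),
              format.pval(x$p_participant)))
  cat(sprintf("  var components: participant %.4g%s, error %.4g\n",
              x$sigma2_participant,
              if (x$truncated) " (truncated at 0)" else "",
              x$sigma2_error))
  invisible(x)
}

#' Tukey HSD comparison of method means
#'
#' Studentised-range pairwise comparisons of the method means from the
#' blocked two-way layout.
#'
#' @param table Long-format measurement table (balanced).
#' @param alpha Family-wise error rate in (0, 1).
#' @return Data frame with one row per method pair: difference, confidence
#'   bounds, adjusted p and a significance flag.
#' @export
tukey_hsd <- function(table, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    stop_lfnmr("alpha must lie in (0, 1)",
               class = "lfnmr_validation_error")
  chk <- check_measurement_table(table)
  d <- data.frame(y = table$concentration, method = chk$method,
                  participant = chk$participant)
  fit <- stats::aov(y ~ method + participant, data = d)
  tk <- stats::TukeyHSD(fit, "method", conf.level = 1 - alpha)$method
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"],
                    significant = tk[, "p adj"] < alpha,
                    row.names = NULL)
  out
}

#' Pairwise method-agreement regression
#'
#' Ordinary least squares of one method's values on another's, with
#' t-based 95% confidence intervals for the intercept and gradient and
#' flags recording whether they cover 0 and 1 respectively (the values
#' expected under perfect agreement).
#'
#' @param x,y Paired concentration values for the two methods (>= 3
#'   pairs; `x` must not be constant).
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `agreement_fit`: `slope`, `intercept`,
#'   `r_squared`, `slope_ci`, `intercept_ci`, `slope_covers_1`,
#'   `intercept_covers_0`, `n` and the [stats::lm()] fit.
#' @export
agreement_regression <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_lfnmr("need >= 3 paired values",
               class = "lfnmr_validation_error")
  if (stats::sd(x) == 0)
    stop_lfnmr("x method values are constant",
               class = "lfnmr_validation_error")
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, level = conf_level)
  slope_ci <- unname(ci["x", ])
  int_ci <- unname(ci["(Intercept)", ])
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 slope_ci = slope_ci, intercept_ci = int_ci,
                 slope_covers_1 = slope_ci[1] <= 1 && slope_ci[2] >= 1,
                 intercept_covers_0 = int_ci[1] <= 0 && int_ci[2] >= 0,
                 n = length(x), fit = fit),
            class = "agreement_fit")
}

#' @export
print.agreement_fit <- function(x, ...) {
  cat(sprintf(
    "<agreement_fit> n = %d: y = %.4g + %.4g x, R^2 = %.3f\n",
    x$n, x$intercept, x$slope, x$r_squared))
  cat(sprintf("  slope CI [%.4g, %.4g] covers 1: %s\n",
              x$slope_ci[1], x$slope_ci[2], x$slope_covers_1))
  cat(sprintf("  intercept CI [%.4g, %.4g] covers 0: %s\n",
              x$intercept_ci[1], x$intercept_ci[2], x$intercept_covers_0))
  invisible(x)
}
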