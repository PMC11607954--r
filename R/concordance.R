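#' Modified Bland-Altman agreement analysis
#'
#' Computes the limits-of-agreement summary over the valid pairs of a
#' paired HR series: mean difference, SD of the differences (sample SD),
#' limits of agreement `mean +/- 1.96 * SD`, and the fractions of pairs
#' within a fixed clinical band (default +/- 5 bpm) and within the limits
#' of agreement. The companion plot ([autoplot.bland_altman()]) is the
#' *modified* variant: the reference HR on the x-axis (not the pair mean)
#' and the difference radar - reference on the y-axis.
#'
#' @param pairs A `"paired_hr"` tibble, or any tibble with `hr_ref` and
#'   `diff` columns; rows with `exclusion_reason != "none"` are dropped.
#' @param agreement_band Clinical agreement band, bpm.
#' @return Object of class `"bland_altman"` with `n_pairs`, `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `frac_within_band`,
#'   `frac_within_loa`, `agreement_band` and the retained `data`.
#' @export
#' @examples
#' p <- tibble::tibble(hr_ref = c(60, 70), diff = c(-1, 1),
#'                     exclusion_reason = "none")
#' bland_altman(p)
bland_altman <- function(pairs, agreement_band = 5) {
  d <- valid_pairs(pairs)
  if (nrow(d) < 2) stop("need at least 2 valid pairs", call. = FALSE)
  m <- mean(d$diff)
  s <- stats::sd(d$diff)
  structure(
    list(
      n_pairs = nrow(d),
      mean_diff = m,
      sd_diff = s,
      loa_low = m - 1.96 * s,
      loa_high = m + 1.96 * s,
      frac_within_band = mean(abs(d$diff) <= agreement_band),
      frac_within_loa = mean(abs(d$diff - m) <= 1.96 * s),
      agreement_band = agreement_band,
      data = d
    ),
    class = "bland_altman"
  )
}

valid_pairs <- function(pairs) {
  stopifnot(all(c("hr_ref", "diff") %in% names(pairs)))
  if ("exclusion_reason" %in% names(pairs)) {
    pairs <- pairs[pairs$exclusion_reason == "none", , drop = FALSE]
  }
  pairs[is.finite(pairs$diff) & is.finite(pairs$hr_ref), , drop = FALSE]
}

#' @export
print.bland_altman <- function(x, ...) {
  cat("Modified Bland-Altman analysis\n")
  cat(sprintf("  n = %d pairs\n", x$n_pairs))
  cat(sprintf("  mean difference %.3f bpm, SD %.3f bpm\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  limits of agreement [%.2f, %.2f] bpm (mean +/- 1.96 SD)\n",
              x$loa_low, x$loa_high))
  cat(sprintf("  %.2f%% within +/-%g bpm, %.2f%% within the limits of agreement\n",
              100 * x$frac_within_band, x$agreement_band, 100 * x$frac_within_loa))
  invisible(x)
}

#' Least-squares regression of radar on reference heart rate
#'
#' Ordinary least squares of the radar HR on the reference HR over the
#' valid pairs, as plotted alongside the angle bisector in the scatter
#' diagram of a method comparison.
#'
#' @param pairs A `"paired_hr"` tibble (needs `hr_ref` and either
#'   `hr_radar` or `diff`).
#' @return Object of class `"hr_regression"`: `slope`, `intercept`, `n`,
#'   `r_squared`, the underlying `lm` fit and the retained `data`.
#' @export
fit_regression <- function(pairs) {
  d <- valid_pairs(pairs)
  if (!"hr_radar" %in% names(d)) d$hr_radar <- d$hr_ref + d$diff
  if (nrow(d) < 2 || length(unique(d$hr_ref)) < 2) {
    stop("need at least 2 pairs with distinct reference values", call. = FALSE)
  }
  fit <- stats::lm(hr_radar ~ hr_ref, data = d)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         n = nrow(d),
         r_squared = summary(fit)$r.squared,
         fit = fit,
         data = d),
    class = "hr_regression"
  )
}

#' @export
print.hr_regression <- function(x, ...) {
  cat(sprintf("OLS radar ~ reference: y = %.2f + %.2f * x  (n = %d, R^2 = %.3f)\n",
              x$intercept, x$slope, x$n, x$r_squared))
  invisible(x)
}

#' Schuirmann two one-sided equivalence test (paired differences)
#'
#' Tests whether the mean radar - reference difference lies inside the
#' equivalence bounds (default +/- 5 bpm, the band considered clinically
#' irrelevant). The null is non-equivalence (mean <= lower or mean >=
#' upper); each bound gets a one-sided one-sample t test, and equivalence
#' is declared iff both reject at `alpha` -- equivalently, iff the
#' `1 - 2*alpha` (90%) confidence interval lies strictly inside the
#' bounds. The standardized effect Hedges g(z) and the bounds on its scale
#' are reported alongside.
#'
#' @param diffs Numeric vector of paired differences, or a `"paired_hr"`
#'   tibble (valid pairs' `diff` is used).
#' @param bounds Equivalence bounds, bpm.
#' @param alpha One-sided type-I error level.
#' @return Object of class `"tost"`; see [tost_from_summary()] for fields.
#' @export
#' @examples
#' tost_paired(rnorm(50, 0.5, 2))
tost_paired <- function(diffs, bounds = c(-5, 5), alpha = 0.05) {
  if (is.data.frame(diffs)) diffs <- valid_pairs(diffs)$diff
  diffs <- diffs[is.finite(diffs)]
  n <- length(diffs)
  if (n < 3) stop("need at least 3 finite differences", call. = FALSE)
  tost_from_summary(n = n, mean = mean(diffs), sd = stats::sd(diffs),
                    bounds = bounds, alpha = alpha)
}

#' Equivalence test from printed summary statistics
#'
#' Runs the same two one-sided tests as [tost_paired()] from a sample
#' size, mean difference and dispersion -- enabling recomputation of
#' published equivalence tables from their printed summaries. Exactly one
#' of `sd` or `se` must be given (they are not interchangeable, so an
#' untagged dispersion is an error).
#'
#' @param n Number of paired differences.
#' @param mean Mean difference, bpm.
#' @param sd Sample SD of the differences, bpm.
#' @param se Standard error of the mean difference, bpm.
#' @param bounds Equivalence bounds, bpm.
#' @param alpha One-sided level; the reported CI has coverage `1 - 2*alpha`.
#' @return Object of class `"tost"` with `n`, `estimate`, `se`, `sd`,
#'   `df`, `t_raw`, `t_lower`, `t_upper`, `p_raw`, `p_lower`, `p_upper`,
#'   `ci_low`, `ci_high`, `conf_level`, `bounds`, `hedges_gz`,
#'   `gz_bounds`, `gz_ci`, `equivalent`, `degenerate`.
#' @export
#' @examples
#' tost_from_summary(n = 4079, mean = 0.852, se = 0.1067)
tost_from_summary <- function(n, mean, sd = NULL, se = NULL,
                              bounds = c(-5, 5), alpha = 0.05) {
  stopifnot(n >= 3, length(bounds) == 2, bounds[1] < bounds[2])
  if (is.null(sd) == is.null(se)) {
    stop("give exactly one of `sd` or `se`", call. = FALSE)
  }
  if (is.null(se)) se <- sd / sqrt(n)
  if (is.null(sd)) sd <- se * sqrt(n)
  df <- n - 1
  degenerate <- !is.finite(se) || se <= 0
  if (degenerate) {
    eq <- mean > bounds[1] && mean < bounds[2]
    res <- list(n = n, estimate = mean, se = se, sd = sd, df = df,
                t_raw = NA_real_, t_lower = Inf * sign(mean - bounds[1]),
                t_upper = -Inf * sign(bounds[2] - mean),
                p_raw = NA_real_, p_lower = as.numeric(!eq), p_upper = as.numeric(!eq),
                ci_low = mean, ci_high = mean, conf_level = 1 - 2 * alpha,
                bounds = bounds, hedges_gz = NA_real_, gz_bounds = c(NA_real_, NA_real_),
                gz_ci = c(NA_real_, NA_real_), equivalent = eq, degenerate = TRUE)
    return(structure(res, class = "tost"))
  }
  t_raw <- mean / se
  t_lower <- (mean - bounds[1]) / se
  t_upper <- (mean - bounds[2]) / se
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)  # H0: mean <= lower
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)   # H0: mean >= upper
  tcrit <- stats::qt(1 - alpha, df)
  ci <- mean + c(-1, 1) * tcrit * se
  g <- hedges_gz(mean, sd, n)
  corr <- g / (mean / sd)                                # small-sample factor J
  structure(
    list(n = n, estimate = mean, se = se, sd = sd, df = df,
         t_raw = t_raw, t_lower = t_lower, t_upper = t_upper,
         p_raw = 2 * stats::pt(abs(t_raw), df, lower.tail = FALSE),
         p_lower = p_lower, p_upper = p_upper,
         ci_low = ci[1], ci_high = ci[2], conf_level = 1 - 2 * alpha,
         bounds = bounds,
         hedges_gz = g,
         gz_bounds = bounds / sd,
         gz_ci = ci / sd * corr,
         equivalent = max(p_lower, p_upper) < alpha,
         degenerate = FALSE),
    class = "tost"
  )
}

#' @export
print.tost <- function(x, digits = 3, ...) {
  fmt_p <- function(p) ifelse(is.na(p), "NA",
                              ifelse(p < 0.001, "< 0.001", formatC(p, digits = 3, format = "f")))
  cat("Two one-sided equivalence test (paired)\n")
  cat(sprintf("  n = %d, bounds [%g, %g] bpm, alpha = %.2f\n",
              x$n, x$bounds[1], x$bounds[2], (1 - x$conf_level) / 2))
  cat(sprintf("  estimate %.3f bpm, %.0f%% CI [%.3f, %.3f]\n",
              x$estimate, 100 * x$conf_level, x$ci_low, x$ci_high))
  if (!x$degenerate) {
    cat(sprintf("  t (raw) %.2f, df %d, p %s\n", x$t_raw, x$df, fmt_p(x$p_raw)))
    cat(sprintf("  TOST lower t %.2f (p %s), upper t %.2f (p %s)\n",
                x$t_lower, fmt_p(x$p_lower), x$t_upper, fmt_p(x$p_upper)))
    cat(sprintf("  Hedges g(z) %.3f, bounds [%.3f, %.3f]\n",
                x$hedges_gz, x$gz_bounds[1], x$gz_bounds[2]))
  }
  cat(sprintf("  equivalent: %s\n", x$equivalent))
  invisible(x)
}

#' Hedges g(z): standardized one-sample effect size
#'
#' Mean difference over the SD of the differences, with the small-sample
#' correction `J(df) = 1 - 3 / (4 df - 1)`, `df = n - 1`.
#'
#' @param mean Mean difference.
#' @param sd Sample SD of the differences (> 0).
#' @param n Number of differences.
#' @return The corrected standardized effect (scalar).
#' @export
#' @examples
#' hedges_gz(1, 1, 5)  # 0.8
hedges_gz <- function(mean, sd, n) {
  if (!is.finite(sd) || sd <= 0) {
    warning("undefined effect size: sd must be positive")
    return(NA_real_)
  }
  df <- n - 1
  (mean / sd) * (1 - 3 / (4 * df - 1))
}
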