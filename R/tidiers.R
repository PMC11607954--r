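#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Bland-Altman analysis
#'
#' @param x A `"bland_altman"` object.
#' @param ... Unused.
#' @return One-row tibble of the agreement statistics.
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    mean_diff = x$mean_diff,
    sd_diff = x$sd_diff,
    loa_low = x$loa_low,
    loa_high = x$loa_high,
    frac_within_band = x$frac_within_band,
    frac_within_loa = x$frac_within_loa
  )
}

#' @rdname tidy.bland_altman
#' @export
glance.bland_altman <- function(x, ...) tidy.bland_altman(x, ...)

#' Tidy an equivalence test
#'
#' @param x A `"tost"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per test component (raw t test and the two
#'   one-sided tests) with `term`, `statistic`, `df`, `p.value`.
#'   `glance()`: one row with the estimate, CI, effect size and decision.
#' @export
tidy.tost <- function(x, ...) {
  tibble::tibble(
    term = c("t_raw", "tost_lower", "tost_upper"),
    statistic = c(x$t_raw, x$t_lower, x$t_upper),
    df = rep(x$df, 3),
    p.value = c(x$p_raw, x$p_lower, x$p_upper)
  )
}

#' @rdname tidy.tost
#' @export
glance.tost <- function(x, ...) {
  tibble::tibble(
    n = x$n, estimate = x$estimate, se = x$se, sd = x$sd, df = x$df,
    conf.low = x$ci_low, conf.high = x$ci_high, conf.level = x$conf_level,
    bound.lower = x$bounds[1], bound.upper = x$bounds[2],
    hedges_gz = x$hedges_gz, equivalent = x$equivalent
  )
}

#' Tidy a radar-on-reference regression
#'
#' @param x An `"hr_regression"` object.
#' @param ... Passed to the `lm` tidier machinery (unused).
#' @return `tidy()`: term-level coefficients; `glance()`: one-row model
#'   summary.
#' @export
tidy.hr_regression <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = cf[, 1],
    std.error = cf[, 2],
    statistic = cf[, 3],
    p.value = cf[, 4]
  )
}

#' @rdname tidy.hr_regression
#' @export
glance.hr_regression <- function(x, ...) {
  tibble::tibble(n = x$n, slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared)
}

#' @rdname tidy.bland_altman
#' @param x A `"sample_size"` object.
#' @export
tidy.sample_size <- function(x, ...) {
  tibble::tibble(method = x$method, n = x$n,
                 achieved_power = x$achieved_power %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
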