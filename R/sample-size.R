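#' Sample size for Bland-Altman limits-of-agreement precision
#'
#' Smallest number of subjects such that the `conf`-level confidence
#' interval of an estimated limit of agreement has half-width at most
#' `ci_halfwidth`, given an anticipated SD of the inter-method differences.
#' The LoA-estimate variance is approximately `3 * sd^2 / n`, so the
#' criterion `z * sd * sqrt(3/n) <= halfwidth` gives
#' `n = ceil(3 * (z * sd / halfwidth)^2)`.
#'
#' @param sd Anticipated SD of the paired differences, bpm.
#' @param ci_halfwidth Acceptable CI half-width for the limits of
#'   agreement, bpm.
#' @param conf Confidence level of that interval.
#' @return List of class `"sample_size"`: `method = "loa_precision"`, `n`,
#'   and the echoed inputs.
#' @export
#' @examples
#' sample_size_loa(sd = 4, ci_halfwidth = 2.5)$n  # 30
sample_size_loa <- function(sd = 4, ci_halfwidth = 2.5, conf = 0.95) {
  stopifnot(sd > 0, ci_halfwidth > 0, conf > 0, conf < 1)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  n <- max(ceiling(3 * (z * sd / ci_halfwidth)^2), 1)
  structure(
    list(method = "loa_precision", n = as.integer(n),
         inputs = list(sd = sd, ci_halfwidth = ci_halfwidth, conf = conf)),
    class = "sample_size"
  )
}

#' Sample size for a TOST equivalence design
#'
#' Total sample size for a parallel-group additive-scale two one-sided
#' tests design: equivalence bounds, expected true mean difference
#' `theta0`, common SD, one-sided level `alpha` and target power. Starting
#' from a normal-approximation estimate, the total is iterated upward over
#' even numbers (equal allocation) until the exact TOST power -- evaluated
#' through the noncentral t distribution -- reaches the target.
#'
#' @param sd Anticipated SD of the differences, bpm.
#' @param bounds Equivalence bounds, bpm.
#' @param theta0 Expected true mean difference, bpm (must lie strictly
#'   inside the bounds).
#' @param power Target power.
#' @param alpha One-sided type-I error level.
#' @return List of class `"sample_size"`: `method = "tost_parallel"`, `n`
#'   (total), `achieved_power`, and the echoed inputs.
#' @export
#' @examples
#' sample_size_tost(sd = 4, bounds = c(-5, 5), theta0 = 1)$n  # 28
sample_size_tost <- function(sd = 4, bounds = c(-5, 5), theta0 = 1,
                             power = 0.80, alpha = 0.05) {
  stopifnot(sd > 0, length(bounds) == 2, bounds[1] < bounds[2],
            power > 0, power < 1, alpha > 0, alpha < 0.5)
  if (theta0 <= bounds[1] || theta0 >= bounds[2]) {
    stop("`theta0` must lie strictly inside the equivalence bounds; ",
         "power cannot reach the target otherwise", call. = FALSE)
  }
  # normal-approximation start (uses the nearer bound)
  delta <- min(bounds[2] - theta0, theta0 - bounds[1])
  zb <- stats::qnorm(power); za <- stats::qnorm(1 - alpha)
  n0 <- ceiling(2 * ((za + zb) * sd / delta)^2 * 2)  # total, two groups
  n <- max(2 * ceiling(n0 / 2), 4)
  # step down first in case the approximation overshoots, then up to the
  # smallest even total whose exact power reaches the target
  while (n > 4 && tost_power_parallel(n - 2, sd, bounds, theta0, alpha) >= power) {
    n <- n - 2
  }
  while (tost_power_parallel(n, sd, bounds, theta0, alpha) < power) {
    n <- n + 2
  }
  structure(
    list(method = "tost_parallel", n = as.integer(n),
         achieved_power = tost_power_parallel(n, sd, bounds, theta0, alpha),
         inputs = list(sd = sd, bounds = bounds, theta0 = theta0,
                       power = power, alpha = alpha)),
    class = "sample_size"
  )
}

# exact TOST power for a parallel two-group additive design with equal
# allocation: n total, se = sd * sqrt(2 / (n/2)), df = n - 2
tost_power_parallel <- function(n, sd, bounds, theta0, alpha) {
  m <- n / 2
  se <- sd * sqrt(2 / m)
  df <- n - 2
  tcrit <- stats::qt(1 - alpha, df)
  p <- stats::pt(-tcrit, df, ncp = (theta0 - bounds[2]) / se) -
    stats::pt(tcrit, df, ncp = (theta0 - bounds[1]) / se)
  max(p, 0)
}

#' @export
print.sample_size <- function(x, ...) {
  lab <- switch(x$method,
                loa_precision = "limits-of-agreement precision",
                tost_parallel = "TOST equivalence (parallel groups)")
  cat(sprintf("A priori sample size (%s): n = %d patients\n", lab, x$n))
  str_in <- paste(names(x$inputs),
                  vapply(x$inputs, function(v) paste(format(v), collapse = ".."),
                         character(1)),
                  sep = " = ", collapse = ", ")
  cat("  inputs:", str_in, "\n")
  if (!is.null(x$achieved_power)) {
    cat(sprintf("  achieved power %.3f\n", x$achieved_power))
  }
  invisible(x)
}
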