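ba_pairs <- function(diffs, ref = 75) {
  tibble::tibble(hr_ref = rep(ref, length(diffs)), diff = diffs,
                 hr_radar = ref + diffs, exclusion_reason = "none")
}

test_that("Bland-Altman statistics follow the limits-of-agreement arithmetic", {
  ba0 <- bland_altman(ba_pairs(c(0, 0, 0)))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$frac_within_band, 1)
  expect_equal(ba0$frac_within_loa, 1)

  ba1 <- bland_altman(ba_pairs(c(-1, 1)))
  expect_equal(ba1$sd_diff, sqrt(2), tolerance = 1e-12)
  expect_equal(ba1$loa_high, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(ba1$loa_high - ba1$loa_low, 2 * 1.96 * sqrt(2), tolerance = 1e-12)
  expect_error(bland_altman(ba_pairs(1)), "at least 2")
})

test_that("Bland-Altman matches brute-force recomputation on random data", {
  set.seed(20)
  for (i in 1:25) {
    d <- rnorm(sample(10:200, 1), rnorm(1), runif(1, 0.5, 8))
    ba <- bland_altman(ba_pairs(d))
    expect_equal(ba$mean_diff, sum(d) / length(d), tolerance = 1e-12)
    expect_equal(ba$sd_diff, sqrt(sum((d - mean(d))^2) / (length(d) - 1)),
                 tolerance = 1e-12)
    expect_equal(ba$frac_within_band, sum(abs(d) <= 5) / length(d), tolerance = 1e-12)
  }
})

test_that("excluded pairs never enter the agreement statistics", {
  p <- ba_pairs(c(0.5, -0.5, 40, 40))
  p$exclusion_reason[3:4] <- "half_double"
  ba <- bland_altman(p)
  expect_equal(ba$n_pairs, 2)
  expect_equal(ba$mean_diff, 0)
})

test_that("regression of radar on reference is ordinary least squares", {
  ex <- suppressWarnings(      # summary.lm warns on an exact fit
    fit_regression(tibble::tibble(hr_ref = c(0, 1, 2), hr_radar = c(1, 3, 5),
                                  diff = c(1, 2, 3), exclusion_reason = "none")))
  expect_equal(ex$slope, 2, tolerance = 1e-12)
  expect_equal(ex$intercept, 1, tolerance = 1e-12)
  ident <- suppressWarnings(   # summary.lm warns on an exact fit
    fit_regression(tibble::tibble(hr_ref = 60:100, hr_radar = 60:100,
                                  diff = 0, exclusion_reason = "none")))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$intercept, 0, tolerance = 1e-10)
  # regression line passes through the mean point
  set.seed(5)
  d <- tibble::tibble(hr_ref = rnorm(50, 80, 10),
                      hr_radar = rnorm(50, 80, 10), diff = 0,
                      exclusion_reason = "none")
  f <- fit_regression(d)
  expect_equal(f$intercept + f$slope * mean(d$hr_ref), mean(d$hr_radar),
               tolerance = 1e-9)
  expect_error(fit_regression(tibble::tibble(hr_ref = c(70, 70), hr_radar = c(1, 2),
                                             diff = 0, exclusion_reason = "none")),
               "distinct")
})

test_that("paired TOST matches the independent one-sided t oracle", {
  set.seed(30)
  for (i in 1:20) {
    d <- rnorm(50, runif(1, -2, 2), runif(1, 0.5, 6))
    res <- tost_paired(d)
    oracle_lo <- t.test(d, mu = -5, alternative = "greater")
    oracle_hi <- t.test(d, mu = 5, alternative = "less")
    expect_equal(res$p_lower, oracle_lo$p.value, tolerance = 1e-10)
    expect_equal(res$p_upper, oracle_hi$p.value, tolerance = 1e-10)
    ci <- t.test(d, conf.level = 0.90)$conf.int
    expect_equal(c(res$ci_low, res$ci_high), as.numeric(ci), tolerance = 1e-10)
  }
})

test_that("equivalence is declared iff the 90% CI sits inside the bounds", {
  set.seed(31)
  for (i in 1:50) {
    d <- rnorm(sample(5:80, 1), runif(1, -7, 7), runif(1, 0.3, 10))
    res <- tost_paired(d)
    inside <- res$ci_low > res$bounds[1] && res$ci_high < res$bounds[2]
    expect_equal(res$equivalent, inside)
    expect_equal(res$equivalent, max(res$p_lower, res$p_upper) < 0.05)
  }
})

test_that("degenerate zero-spread differences are handled without error", {
  res <- tost_paired(rep(0, 100))
  expect_true(res$degenerate)
  expect_true(res$equivalent)
  res6 <- tost_paired(rep(6, 100))
  expect_false(res6$equivalent)
})

test_that("summary-based TOST reproduces the overnight equivalence table", {
  se <- (1.027 - 0.676) / 2 / qt(0.95, 4078)      # SE recovered from the 90% CI
  res <- tost_from_summary(n = 4079, mean = 0.852, se = se)
  expect_equal(res$t_raw, 7.98, tolerance = 0.005 * 7.98)
  expect_equal(res$t_lower, 54.81, tolerance = 0.005 * 54.81)
  expect_equal(res$t_upper, -38.86, tolerance = 0.005 * 38.86)
  expect_equal(res$hedges_gz, 0.125, tolerance = 0.005 * 0.125)
  expect_equal(res$gz_bounds[2], 0.733, tolerance = 0.005 * 0.733)
  expect_true(res$equivalent)
  expect_true(res$p_lower < 0.001 && res$p_upper < 0.001)
})

test_that("summary input requires exactly one tagged dispersion", {
  expect_error(tost_from_summary(10, 1), "exactly one")
  expect_error(tost_from_summary(10, 1, sd = 2, se = 0.5), "exactly one")
  sym <- tost_from_summary(100, 0, sd = 3)
  expect_equal(sym$t_lower, -sym$t_upper, tolerance = 1e-12)
})

test_that("Hedges g(z) applies the small-sample correction", {
  expect_equal(hedges_gz(0, 2, 50), 0)
  expect_equal(hedges_gz(1, 1, 5), 0.8, tolerance = 1e-12)
  expect_warning(g <- hedges_gz(1, 0, 10), "sd")
  expect_true(is.na(g))
  # beat-wise arm: g(z) recomputed from the printed one-hour summaries lands
  # in 0.162-0.164 (the printed inputs carry only 3 decimals)
  se2 <- (0.707 - 0.650) / 2 / qt(0.95, 57047)
  g_ci <- hedges_gz(0.678, se2 * sqrt(57048), 57048)
  g_loa <- hedges_gz(0.678, 8.2 / 1.96, 57048)
  expect_true(g_ci >= 0.162 && g_ci <= 0.164)
  expect_true(g_loa >= 0.162 && g_loa <= 0.164)
})
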