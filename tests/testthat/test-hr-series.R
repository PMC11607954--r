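beats_at <- function(times) tibble::tibble(s1_time_s = times)

test_that("interval means average IBIs, not instantaneous rates", {
  const <- beats_at(seq(0.5, 299.5, by = 1.0))
  hr <- interval_mean_hr(const, width = 300, t_end = 300)
  expect_equal(hr$hr_bpm, 60.0)
  # alternating 0.8/1.2 s IBIs in equal numbers: HR = 60 / mean = 60.0
  alt <- beats_at(0.5 + cumsum(c(0, rep(c(0.8, 1.2), 149))))
  hr_alt <- interval_mean_hr(alt, width = 300, t_end = 300)
  expect_equal(hr_alt$hr_bpm, 60.0, tolerance = 1e-12)
  # too few IBIs invalidates the interval
  sparse <- interval_mean_hr(beats_at(c(1, 2, 3)), width = 300, t_end = 300)
  expect_false(sparse$valid[1])
})

test_that("interval means track a long simulated recording", {
  cfg <- sim_config(duration = 30000, base_hr = 75, hrv_sd = 2,
                    artifact_rate = 0, seed = 17)
  gt <- simulate_beats(cfg)
  hr <- interval_mean_hr(tibble::tibble(s1_time_s = gt$beats$beat_time_s),
                         t_end = cfg$duration)
  expect_equal(nrow(hr), 100)
  expect_true(all(abs(hr$hr_bpm[hr$valid] - 75) < 2 + 2 * 2.83))
  expect_true(abs(mean(hr$hr_bpm[hr$valid]) - 75) < 2)
})

test_that("rolling mean HR follows the k-IBI definition", {
  one <- rolling_mean_hr(beats_at(cumsum(c(0, rep(0.75, 10)))), k = 10)
  expect_equal(one$hr_bpm, 80.0)
  expect_equal(one$beat_index, 11L)
  eleven <- rolling_mean_hr(beats_at(cumsum(c(0, rep(1, 10), 0.5))), k = 10)
  expect_equal(utils::tail(eleven$hr_bpm, 1), 60 / 0.95, tolerance = 1e-12)
  expect_equal(nrow(rolling_mean_hr(beats_at(1:5), k = 10)), 0)
})

test_that("block means come in beat and time flavours", {
  expect_equal(block_mean_hr(beats_at(cumsum(c(0, rep(0.5, 30)))), k = 30)$hr_bpm, 120)
  b90 <- block_mean_hr(beats_at(cumsum(c(0, rep(0.8, 90)))), k = 30)
  expect_equal(nrow(b90), 3)
  tm <- block_mean_hr(beats_at(seq(0.25, 89.75, by = 0.5)), mode = "time", width = 30)
  expect_equal(nrow(tm), 3)
  expect_equal(tm$hr_bpm, rep(120, 3))
})

test_that("a slow ramp survives block aggregation", {
  # +10 bpm over 30 min then recovery, as in a medication response
  tt <- seq(0, 3600)
  hr_t <- 75 + 10 * pmin(pmax((tt - 600) / 1800, 0), 1) - 10 * pmin(pmax((tt - 2700) / 600, 0), 1)
  t_cur <- 0.3; times <- c()
  while (t_cur < 3600) {
    times <- c(times, t_cur)
    t_cur <- t_cur + 60 / stats::approx(tt, hr_t, t_cur, rule = 2)$y
  }
  blocks <- block_mean_hr(beats_at(times), k = 30)
  truth_at <- stats::approx(tt, hr_t, blocks$time_s, rule = 2)$y
  expect_true(all(abs(blocks$hr_bpm - truth_at) < 2))
})

test_that("all aggregators agree on constant-IBI input", {
  b <- beats_at(cumsum(c(0, rep(0.8, 600))))
  iv <- interval_mean_hr(b, width = 300, t_end = 480)
  ro <- rolling_mean_hr(b, k = 10)
  bl <- block_mean_hr(b, k = 30)
  expect_true(max(abs(iv$hr_bpm[iv$valid] - 75)) < 1e-9)
  expect_true(max(abs(ro$hr_bpm - 75)) < 1e-9)
  expect_true(max(abs(bl$hr_bpm - 75)) < 1e-9)
})

test_that("interval pairing joins on interval start and flags dropout", {
  hr <- tibble::tibble(interval_start_s = seq(0, 299) * 300,
                       hr_bpm = rnorm(300, 75, 5), valid = TRUE)
  p_same <- synchronize_pairs(hr, hr, mode = "interval")
  expect_true(all(p_same$diff == 0))
  expect_true(all(p_same$exclusion_reason == "none"))
  # 12% radar dropout -> 12% missing_radar
  set.seed(4)
  drop <- sample(300, 36)
  hr_r <- hr; hr_r$hr_bpm[drop] <- NA; hr_r$valid[drop] <- FALSE
  p <- synchronize_pairs(hr_r, hr, mode = "interval")
  es <- exclusion_summary(p)
  expect_equal(es$fraction[es$exclusion_reason == "missing_radar"], 0.12)
})

test_that("beat pairing matches nearest within tolerance and warns on disjoint clocks", {
  rad <- tibble::tibble(time_s = seq(1, 100), hr_bpm = 70)
  ref <- tibble::tibble(time_s = seq(1, 100) + 0.1, hr_bpm = 72)
  p <- synchronize_pairs(rad, ref, mode = "beat")
  expect_true(all(p$exclusion_reason == "none"))
  expect_equal(p$diff, rep(-2, 100))
  far <- tibble::tibble(time_s = seq(1, 100) + 500, hr_bpm = 70)
  expect_warning(p2 <- synchronize_pairs(far, ref, mode = "beat"), "overlap")
  expect_equal(nrow(p2), 0)
  shifted <- tibble::tibble(time_s = seq(1, 100) + 0.45, hr_bpm = 70)
  p3 <- synchronize_pairs(shifted, ref, mode = "beat", tolerance = 0.2)
  expect_true(all(p3$exclusion_reason == "missing_radar"))
})

test_that("half/double rule excludes the doubling failure mode and only it", {
  p <- pairs_from_hr(c(41, 78, 160, 75), c(80, 80, 80, 80))
  out <- exclude_half_double(p)
  expect_equal(out$exclusion_reason, c("half_double", "none", "half_double", "none"))
  # idempotent and reason-preserving
  expect_identical(exclude_half_double(out), out)
  # literal-difference variant flags |diff| near half/double of the reference
  pd <- pairs_from_hr(c(120, 82), c(80, 80))
  expect_equal(exclude_half_double(pd, mode = "difference")$exclusion_reason,
               c("half_double", "none"))
})

test_that("annotations propagate through rolling windows", {
  pairs <- tibble::tibble(
    time_s = seq_len(100), hr_radar = 75, hr_ref = 75, diff = 0,
    exclusion_reason = "none", ref_index = seq_len(100)
  )
  expect_identical(apply_annotations(pairs, tibble::tibble(beat_index = integer(),
                                                           label = character())),
                   pairs)
  ann <- tibble::tibble(beat_index = 50L, label = "VES")
  out <- apply_annotations(pairs, ann, k = 10)
  flagged <- which(out$exclusion_reason == "arrhythmia_label")
  expect_equal(flagged, 50:59)
  noisy <- apply_annotations(pairs, tibble::tibble(beat_index = 10L, label = "noisy"),
                             k = 10)
  expect_equal(which(noisy$exclusion_reason == "noisy_reference"), 10:19)
  expect_error(apply_annotations(pairs, tibble::tibble(beat_index = 999L, label = "VES")),
               "outside")
  expect_error(apply_annotations(pairs, tibble::tibble(beat_index = 1L, label = "bogus")),
               "unknown")
})

test_that("each pair carries exactly one exclusion reason and counts add up", {
  set.seed(11)
  p <- pairs_from_hr(c(rnorm(80, 75, 3), 37.5, NA), c(rnorm(80, 75, 3), 75, 75))
  p <- exclude_half_double(p)
  es <- exclusion_summary(p)
  expect_equal(sum(es$n), nrow(p))
  expect_equal(sum(es$fraction), 1)
  expect_true(all(table(p$exclusion_reason) >= 0))
})

test_that("global outlier filter removes impossible values and nothing else", {
  hr <- tibble::tibble(hr_bpm = c(70, 300, 80))
  out <- global_outlier_filter(hr)
  expect_equal(out$valid, c(TRUE, FALSE, TRUE))
  expect_identical(global_outlier_filter(out), out)   # idempotent
  ok <- global_outlier_filter(tibble::tibble(hr_bpm = seq(30, 200, by = 10)))
  expect_true(all(ok$valid))
  expect_error(global_outlier_filter(hr, lo = 100, hi = 50), "below")
})

test_that("local outlier filter removes spikes, keeps trends, and converges", {
  const <- local_outlier_filter(tibble::tibble(hr_bpm = rep(75, 120)))
  expect_true(all(const$valid))
  spiked <- tibble::tibble(hr_bpm = c(rep(75, 30), 115, rep(75, 29)))
  out <- local_outlier_filter(spiked)
  expect_equal(which(!out$valid), 31)
  expect_identical(local_outlier_filter(out), out)    # fixpoint reached
  # genuine medication-response excursion (rise by 10 bpm over 30 min,
  # plateau, decline), 30-s blocks over 3 h: the trend must survive
  blk <- seq_len(360)
  shape <- pmin(pmax((blk - 60) / 60, 0), 1) - pmin(pmax((blk - 180) / 60, 0), 1)
  set.seed(2)
  trend <- tibble::tibble(hr_bpm = 75 + 10 * shape + rnorm(360, 0, 0.5))
  expect_true(all(local_outlier_filter(trend)$valid))
})
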