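test_that("zero-variance heart rate gives metronomic beats", {
  gt <- simulate_beats(sim_config(duration = 300, base_hr = 60, hrv_sd = 0,
                                  artifact_rate = 0, seed = 1))
  n <- nrow(gt$beats)
  expect_true(abs(n - 300) <= 1)
  ibis <- diff(gt$beats$beat_time_s)
  expect_equal(ibis, rep(1.0, n - 1), tolerance = 1e-9)
  expect_equal(gt$beats$s2_time_s - gt$beats$beat_time_s,
               rep(0.33, n), tolerance = 1e-9)
})

test_that("mean heart rate of generated beats tracks the configured rate", {
  gt <- simulate_beats(sim_config(duration = 60, base_hr = 80, hrv_sd = 3,
                                  artifact_rate = 0, seed = 4))
  ibis <- diff(gt$beats$beat_time_s)
  expect_true(abs(mean(60 / ibis) - 80) < 1)
})

test_that("beat count conserves the integrated heart rate", {
  for (seed in 1:3) {
    cfg <- sim_config(duration = 600, base_hr = 70, hrv_sd = 1,
                      artifact_rate = 0, seed = seed)
    gt <- simulate_beats(cfg)
    expected <- sum(gt$true_hr$hr_bpm[seq_len(600)]) / 60
    expect_true(abs(nrow(gt$beats) - expected) <= 1,
                label = sprintf("seed %d: %d beats vs %.1f expected",
                                seed, nrow(gt$beats), expected))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(duration = -1), "duration")
  expect_error(sim_config(base_hr = NaN), "base_hr")
  expect_error(sim_config(base_hr = -10), "base_hr")
  expect_error(sim_config(sampling_rate = 100), "sampling_rate")
  expect_error(sim_config(ves_fraction = 0.6, sves_fraction = 0.5), "fraction")
  expect_error(sim_config(s1_amplitude = -1), "amplitude")
})

test_that("each ectopic beat perturbs two adjacent interbeat intervals", {
  cfg <- sim_config(duration = 3600, base_hr = 75, hrv_sd = 1,
                    ves_fraction = 0.195, artifact_rate = 0, seed = 3)
  gt <- simulate_beats(cfg)
  n <- nrow(gt$beats)
  n_ect <- sum(gt$beats$label != "normal")
  frac_affected <- min(2 * n_ect, n) / n
  # ectopic fraction ~ 0.195, so the affected fraction is ~ 0.39
  expect_true(abs(n_ect / n - 0.195) < 0.03)
  expect_true(abs(frac_affected - 0.39) < 0.06)
  # VES shortens the IBI ending at it by ~40%
  ves_idx <- which(gt$beats$label == "VES")
  ves_idx <- ves_idx[ves_idx > 1 & ves_idx < n]
  prev_ibi <- gt$beats$beat_time_s[ves_idx] - gt$beats$beat_time_s[ves_idx - 1]
  expect_true(median(prev_ibi) < 0.75 * median(diff(gt$beats$beat_time_s)))
  # burden reproduces the whole-patient exclusion decision
  ann <- tibble::tibble(beat_index = which(gt$beats$label != "normal"),
                        label = "VES")
  burden <- arrhythmia_burden(ann, n_beats = n)
  expect_true(burden$exclude_patient)
  expect_equal(burden$fraction_affected, frac_affected)
})

test_that("displacement is zero with no sources and superposes all components", {
  cfg <- quick_config(duration = 10, resp_amplitude = 0, s1_amplitude = 0,
                      s2_amplitude = 0)
  gt <- simulate_beats(cfg)
  gt$artifact_intervals <- list()
  d <- synthesize_displacement(gt, cfg, 1)
  expect_true(all(d$disp_um == 0))
})

test_that("a single beat produces a band-limited S1 wavelet of the right size", {
  cfg <- quick_config(duration = 10, resp_amplitude = 0, s1_amplitude = 30,
                      s2_amplitude = 0)
  gt <- simulate_beats(cfg)
  gt$beats <- gt$beats[3, , drop = FALSE]     # keep one interior beat
  gt$artifact_intervals <- list()
  d <- synthesize_displacement(gt, cfg, 1)
  hs <- extract_heart_sound(d)
  peak_idx <- which.max(abs(hs$hs_um))
  expect_true(abs(hs$time_s[peak_idx] - gt$beats$beat_time_s[1]) < 0.05)
  expect_true(max(abs(hs$hs_um)) >= 0.5 * 30 && max(abs(hs$hs_um)) <= 1.0 * 30)
})

test_that("respiration dominates the raw spectrum below 1 Hz by >= 40 dB", {
  cfg <- quick_config(duration = 120, resp_amplitude = 5, s1_amplitude = 30)
  gt <- simulate_beats(cfg)
  gt$artifact_intervals <- list()
  d <- synthesize_displacement(gt, cfg, 1)
  spec <- Mod(stats::fft(d$disp_um - mean(d$disp_um)))^2
  freq <- (seq_along(spec) - 1) * cfg$sampling_rate / length(spec)
  p_low <- sum(spec[freq > 0.05 & freq < 1])
  p_hs <- sum(spec[freq >= 16 & freq <= 80])
  expect_true(10 * log10(p_low / p_hs) >= 40)
})

test_that("I/Q modulation follows the interferometric phase model", {
  cfg <- quick_config(duration = 4)
  # constant zero displacement, noiseless: constant carrier + offset
  d0 <- tibble::tibble(time_s = seq(0, 4, by = 1 / 500), disp_um = 0)
  iq0 <- modulate_iq(d0, cfg, 1, noiseless = TRUE)
  expect_equal(iq0$i, rep(1 + 0.4, nrow(iq0)))
  expect_equal(iq0$q, rep(-0.25, nrow(iq0)))
  # a 1-mm sweep excurses the phase by 4*pi/12.49 ~ 1.006 rad
  d1 <- tibble::tibble(time_s = d0$time_s,
                       disp_um = 500 * sin(2 * pi * 0.25 * d0$time_s))
  iq1 <- modulate_iq(d1, cfg, 1, noiseless = TRUE)
  ph <- atan2(iq1$q + 0.25, iq1$i - 0.4)
  expect_equal(max(ph) - min(ph), 4 * pi * 1 / 12.49, tolerance = 1e-3)
})

test_that("modulate/demodulate round-trip is the identity at noiseless settings", {
  cfg <- quick_config(duration = 20, resp_amplitude = 1)
  gt <- simulate_beats(cfg)
  gt$artifact_intervals <- list()
  d <- synthesize_displacement(gt, cfg, 1)
  iq <- modulate_iq(d, cfg, 1, noiseless = TRUE)
  rec <- demodulate_displacement(iq)
  err <- rec$disp_um - (d$disp_um - mean(d$disp_um))
  expect_true(sqrt(mean(err^2)) < 0.1)   # um
})

test_that("reference beats carry jitter and honour absence masking", {
  cfg <- sim_config(duration = 1000, base_hr = 70, hrv_sd = 1, seed = 5,
                    absence_intervals = list(c(100, 200)), artifact_rate = 0)
  gt <- simulate_beats(cfg)
  ref0 <- simulate_reference_beats(gt, jitter_sd_ms = 0)
  expect_equal(ref0$beat_time_s, gt$beats$beat_time_s)
  expect_false(any(ref0$beat_time_s >= 100 & ref0$beat_time_s < 200))

  ref5 <- simulate_reference_beats(gt, jitter_sd_ms = 5)
  shifts <- abs(ref5$beat_time_s - gt$beats$beat_time_s[
    seq_along(ref5$beat_time_s)])
  # half-normal mean: 5 ms * sqrt(2/pi) ~ 4 ms (sorting perturbs order a touch)
  expect_true(abs(mean(shifts) * 1000 - 4) < 1)
  expect_equal(attr(ref5, "resolution_hz"), 1000)
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- quick_config(duration = 8, n_channels = 2, seed = 99)
  r1 <- simulate_recording(cfg, jitter_sd_ms = 3)
  r2 <- simulate_recording(cfg, jitter_sd_ms = 3)
  expect_identical(r1$channels, r2$channels)
  expect_identical(r1$truth$beats, r2$truth$beats)
  expect_identical(r1$reference, r2$reference)
})

test_that("recordings survive a write/read round trip", {
  dir <- withr::local_tempdir()
  cfg <- quick_config(duration = 5, n_channels = 2)
  rec <- simulate_recording(cfg)
  write_recording(rec, dir)
  expect_true(file.exists(file.path(dir, "channel_2.csv")))
  back <- read_channel(file.path(dir, "channel_1.csv"))
  expect_equal(back$i, rec$channels[[1]]$i, tolerance = 1e-12)
  expect_equal(attr(back, "sampling_rate"), cfg$sampling_rate)
  expect_equal(attr(back, "carrier_wavelength"), cfg$carrier_wavelength)
  # malformed header is a named error
  bad <- file.path(dir, "bad.csv")
  utils::write.csv(data.frame(a = 1, b = 2), bad, row.names = FALSE)
  expect_error(read_channel(bad), "time_s")
})
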