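# shared fixtures: small seeded recordings and a beat-matching helper

quick_config <- function(duration = 60, n_channels = 1, snr = 25, seed = 42, ...) {
  sim_config(duration = duration, n_channels = n_channels, sampling_rate = 500,
             channel_snr = snr, artifact_rate = 0, seed = seed, ...)
}

# fraction of true beats with a detection within tol seconds, plus the
# spurious-detection fraction relative to the truth count
match_beats <- function(true_times, det_times, tol = 0.05) {
  if (length(det_times) == 0) {
    return(list(sensitivity = 0, spurious_frac = 0, abs_err = numeric()))
  }
  err <- vapply(true_times, function(t) min(abs(det_times - t)), numeric(1))
  hit <- err <= tol
  list(
    sensitivity = mean(hit),
    spurious_frac = max(length(det_times) - sum(hit), 0) / length(true_times),
    abs_err = err[hit]
  )
}

# synthetic envelope features (50 Hz): gaussian bumps at given S1/S2 times,
# used to probe the decoder without the radar front-end
features_from_events <- function(s1, s2, duration, fr = 50,
                                 a1 = 3, a2 = 1.5, sigma = 0.05) {
  t <- seq(0, duration, by = 1 / fr)
  env <- numeric(length(t))
  for (b in s1) env <- env + a1 * exp(-(t - b)^2 / (2 * sigma^2))
  for (b in s2) env <- env + a2 * exp(-(t - b)^2 / (2 * sigma^2))
  out <- tibble::tibble(
    time_s = t,
    homomorphic = as.numeric(scale(env)),
    hilbert = as.numeric(scale(env))
  )
  attr(out, "feature_rate") <- fr
  out
}

# paired interval series built directly from HR vectors
pairs_from_hr <- function(hr_radar, hr_ref) {
  synchronize_pairs(
    tibble::tibble(interval_start_s = seq_along(hr_radar) * 300 - 300,
                   hr_bpm = hr_radar, valid = !is.na(hr_radar)),
    tibble::tibble(interval_start_s = seq_along(hr_ref) * 300 - 300,
                   hr_bpm = hr_ref, valid = TRUE),
    mode = "interval"
  )
}
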