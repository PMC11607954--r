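#' Simulate ground-truth beat times and heart-rate trace
#'
#' Draws a smooth heart-rate trajectory on a 1-second grid -- baseline plus a
#' slow AR(1) drift (coefficient 0.99) plus white Gaussian variability of SD
#' `hrv_sd`, clipped to 30--200 bpm -- and lays down beats whose interbeat
#' intervals (IBIs) are `60 / HR(t)`. Each beat carries a second heart sound
#' (S2) at 0.33 of the local IBI after S1. Ectopic beats (VES/SVES) shorten
#' the IBI that precedes them (by ~40% for VES, ~20% for SVES) and are
#' followed by a compensatory pause, so each ectopic beat perturbs two
#' adjacent IBIs. Beats falling inside absence intervals are dropped.
#'
#' @param config A [sim_config()].
#' @return A list of class `"ground_truth"` with elements
#'   * `beats`: tibble with `beat_time_s` (S1 onset), `s2_time_s`, `label`
#'     (`"normal"`, `"VES"`, `"SVES"`), `ibi_perturbed` (logical);
#'   * `true_hr`: tibble with `time_s`, `hr_bpm` on a 1-s grid;
#'   * `artifact_intervals`, `absence_intervals`: lists of `[start, end)`;
#'   * `config`: the generating configuration.
#' @export
#' @examples
#' gt <- simulate_beats(sim_config(duration = 60, base_hr = 60, hrv_sd = 0, seed = 2))
#' nrow(gt$beats)
simulate_beats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 1L))

  tt <- seq(0, ceiling(config$duration))
  n <- length(tt)
  drift <- numeric(n)
  if (config$hrv_sd > 0) {
    # slow wander subordinate to beat-to-beat variability: stationary SD
    # half of hrv_sd, AR(1) coefficient 0.99 on the 1-s grid
    drift_sd <- config$hrv_sd / 2
    innov_sd <- drift_sd * sqrt(1 - 0.99^2)
    drift[1] <- stats::rnorm(1, 0, drift_sd)
    for (i in seq_len(n - 1)) drift[i + 1] <- 0.99 * drift[i] + stats::rnorm(1, 0, innov_sd)
  }
  hr <- pmin(pmax(config$base_hr + drift + stats::rnorm(n, 0, config$hrv_sd), 30), 200)
  true_hr <- tibble::tibble(time_s = tt, hr_bpm = hr)

  hr_at <- stats::approxfun(tt, hr, rule = 2)
  # the beat after an ectopic is a forced (compensatory) normal, so the draw
  # probability is inflated to p/(1-p) to hit the configured per-beat fraction
  q <- config$ves_fraction + config$sves_fraction
  q_draw <- if (q > 0) q / (1 - q) else 0
  p_ect <- c(normal = 1 - q_draw,
             VES = if (q > 0) q_draw * config$ves_fraction / q else 0,
             SVES = if (q > 0) q_draw * config$sves_fraction / q else 0)

  n_max <- as.integer(ceiling(config$duration * 200 / 60) + 8)
  times <- numeric(n_max); label <- character(n_max); perturbed <- logical(n_max)
  t_cur <- 0.3           # first beat shortly after recording start
  times[1] <- t_cur; label[1] <- "normal"
  k <- 1L
  pending_pause <- 0     # compensatory stretch after an ectopic beat
  while (TRUE) {
    ibi <- 60 / hr_at(t_cur)
    this_perturbed <- FALSE
    if (pending_pause > 0) {            # post-extrasystolic pause
      ibi <- ibi + pending_pause
      pending_pause <- 0
      this_perturbed <- TRUE
      lab <- "normal"
    } else {
      # an ectopic beat arrives early: the IBI *ending* at it is short
      lab <- sample(names(p_ect), 1, prob = p_ect)
      shrink <- switch(lab, VES = 0.6, SVES = 0.8, 1)
      if (lab != "normal") {
        pending_pause <- ibi * (1 - shrink)
        ibi <- ibi * shrink
        this_perturbed <- TRUE
      }
    }
    t_cur <- t_cur + ibi
    if (t_cur >= config$duration || k >= n_max) break
    k <- k + 1L
    times[k] <- t_cur; label[k] <- lab; perturbed[k] <- this_perturbed
  }
  beat_time_s <- times[seq_len(k)]
  label <- label[seq_len(k)]
  ibi_local <- c(diff(beat_time_s), 60 / hr_at(beat_time_s[k]))
  beats <- tibble::tibble(
    beat_time_s = beat_time_s,
    s2_time_s = beat_time_s + 0.33 * ibi_local,
    label = label,
    ibi_perturbed = perturbed[seq_len(k)]
  )
  keep <- !in_intervals(beats$beat_time_s, config$absence_intervals)
  beats <- beats[keep, , drop = FALSE]

  n_art <- stats::rpois(1, config$artifact_rate * config$duration / 3600)
  artifact_intervals <- list()
  if (n_art > 0) {
    starts <- sort(stats::runif(n_art, 0, max(config$duration - 2, 0)))
    artifact_intervals <- lapply(starts, function(s) c(s, s + 2))
  }

  structure(
    list(beats = beats, true_hr = true_hr,
         artifact_intervals = artifact_intervals,
         absence_intervals = config$absence_intervals,
         config = config),
    class = "ground_truth"
  )
}

#' Synthesize chest-surface displacement for one radar channel
#'
#' Builds the physical displacement seen by one radar unit, in micrometres:
#' a respiration sinusoid at millimetre scale, Gabor wavelets (40 Hz centre
#' frequency, ~100 ms envelope) at every S1 and S2 time at micrometre scale,
#' and occasional smoothed bump artifacts at millimetre scale. Channels see
#' the same events through different geometric gains. Displacement is zero
#' during absence intervals.
#'
#' @param truth A `"ground_truth"` object from [simulate_beats()].
#' @param config The generating [sim_config()].
#' @param channel 1-based channel index (sets the gain and artifact stream).
#' @return Tibble with `time_s` and `disp_um`; attributes `sampling_rate`
#'   and `channel`.
#' @export
synthesize_displacement <- function(truth, config = truth$config, channel = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(config, "sim_config"))
  fs <- config$sampling_rate
  t <- seq(0, config$duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  gain <- channel_gain(channel)

  set.seed(child_seed(config$seed, 100L + channel))
  resp_phase <- stats::runif(1, 0, 2 * pi)
  x <- config$resp_amplitude * 1000 *
    sin(2 * pi * config$resp_rate / 60 * t + resp_phase)

  hs_rms <- 0
  if (nrow(truth$beats) > 0) {
    cardiac <- gain * (add_gabor_train(n, fs, truth$beats$beat_time_s, config$s1_amplitude) +
                         add_gabor_train(n, fs, truth$beats$s2_time_s, config$s2_amplitude))
    hs_rms <- sqrt(mean(cardiac^2))
    x <- x + cardiac
  }

  for (iv in truth$artifact_intervals) {
    idx <- which(t >= iv[1] & t < iv[2])
    if (length(idx) < 4) next
    u <- seq(0, 1, length.out = length(idx))
    amp <- stats::runif(1, 2, 8) * 1000      # 2-8 mm body-movement bump
    x[idx] <- x[idx] + amp * exp(-((u - 0.5) / 0.18)^2)
  }

  x[in_intervals(t, config$absence_intervals)] <- 0
  out <- tibble::tibble(time_s = t, disp_um = x)
  attr(out, "sampling_rate") <- fs
  attr(out, "channel") <- as.integer(channel)
  attr(out, "hs_rms_um") <- hs_rms     # cardiac-band RMS, anchors the SNR
  out
}

channel_gain <- function(channel) {
  gains <- c(1, 0.9, 0.8, 0.7)
  gains[((as.integer(channel) - 1L) %% length(gains)) + 1L]
}

# sum of Gabor wavelets (40 Hz carrier, sigma ~ 16.7 ms so ~100 ms support)
# centred at `centers`, peak amplitude `amp` (um); returns a length-n vector
add_gabor_train <- function(n, fs, centers, amp, f0 = 40, sigma = 0.1 / 6) {
  out <- numeric(n)
  if (amp == 0 || length(centers) == 0) return(out)
  half <- ceiling(3 * sigma * fs)
  rel_t <- (-half:half) / fs
  wave <- amp * exp(-rel_t^2 / (2 * sigma^2)) * cos(2 * pi * f0 * rel_t)
  c0 <- round(centers * fs) + 1                  # sample index of each centre
  for (c in c0) {
    lo <- max(1, c - half); hi <- min(n, c + half)
    if (lo > hi) next
    out[lo:hi] <- out[lo:hi] + wave[(lo - c + half + 1):(hi - c + half + 1)]
  }
  out
}

#' Modulate displacement onto a complex radar baseband (I/Q) signal
#'
#' Applies the continuous-wave interferometric model: a target at distance
#' `d(t)` produces baseband `A * exp(i * 4*pi*d(t)/lambda)` plus a complex DC
#' offset (receiver leakage) plus circular Gaussian noise. The noise is
#' scaled so the channel's configured SNR equals the in-band (16--80 Hz)
#' power ratio of the heart-sound displacement to the demodulated noise
#' floor -- the quantity the downstream signal quality index estimates.
#' (A millimetre-wave radar resolves micrometre motion, so the raw
#' carrier-to-noise ratio is far higher than the heart-sound SNR; scaling
#' against the carrier would bury the micrometre cardiac signal at any
#' realistic figure.) When the displacement carries no cardiac component,
#' the SNR falls back to being carrier-relative. On noiseless input the
#' mapping is exactly inverted by [demodulate_displacement()].
#'
#' @param disp Displacement tibble from [synthesize_displacement()] (or any
#'   tibble with `time_s`, `disp_um`).
#' @param config The [sim_config()] (wavelength, SNR, seed).
#' @param channel 1-based channel index.
#' @param dc_offset Complex receiver DC offset added to the baseband.
#' @param noiseless If `TRUE`, omit the noise term regardless of SNR.
#' @return Tibble with `time_s`, `i`, `q`; attributes `sampling_rate`,
#'   `carrier_wavelength` (mm), `channel`.
#' @export
modulate_iq <- function(disp, config, channel = 1L,
                        dc_offset = complex(real = 0.4, imaginary = -0.25),
                        noiseless = FALSE) {
  stopifnot(inherits(config, "sim_config"),
            all(c("time_s", "disp_um") %in% names(disp)))
  lambda_um <- config$carrier_wavelength * 1000
  theta <- 4 * pi * disp$disp_um / lambda_um
  sig <- exp(1i * theta) + dc_offset
  if (!noiseless) {
    snr_db <- config$channel_snr[((as.integer(channel) - 1L) %% length(config$channel_snr)) + 1L]
    hs_rms <- attr(disp, "hs_rms_um")
    if (is.null(hs_rms) && length(disp$disp_um) > 3 * config$sampling_rate &&
        config$sampling_rate > 160) {
      bf <- signal::butter(4, c(16, 80) / (config$sampling_rate / 2), type = "pass")
      hs_rms <- sqrt(mean(as.numeric(signal::filtfilt(bf, disp$disp_um))^2))
    }
    if (!is.null(hs_rms) && is.finite(hs_rms) && hs_rms > 0) {
      # in-band heart-sound SNR: white phase noise spreads over [0, fs/2],
      # only the 16-80 Hz slice competes with the cardiac signal
      theta_rms <- 4 * pi * hs_rms / lambda_um
      inband <- (min(80, config$sampling_rate / 2) - 16) / (config$sampling_rate / 2)
      noise_power <- theta_rms^2 / 10^(snr_db / 10) / inband
      noise_sd <- sqrt(noise_power / 2)        # per quadrature, small-angle
    } else {
      noise_sd <- 10^(-snr_db / 20) / sqrt(2)  # carrier-relative fallback
    }
    if (!is.finite(noise_sd) || noise_sd < 0) {
      stop("channel SNR yields an invalid noise scale", call. = FALSE)
    }
    set.seed(child_seed(config$seed, 200L + channel))
    n <- length(theta)
    sig <- sig + complex(real = stats::rnorm(n, 0, noise_sd),
                         imaginary = stats::rnorm(n, 0, noise_sd))
  }
  out <- tibble::tibble(time_s = disp$time_s, i = Re(sig), q = Im(sig))
  attr(out, "sampling_rate") <- config$sampling_rate
  attr(out, "carrier_wavelength") <- config$carrier_wavelength
  attr(out, "channel") <- as.integer(channel)
  out
}

#' Simulate a beat-synchronous reference channel
#'
#' Emulates the reference device (Holter/beat-wise ECG on a shared clock):
#' true beat times plus Gaussian timing jitter, with beats inside absence
#' intervals removed. Metadata records the nominal 1000 Hz resolution of the
#' emulated ECG timeline.
#'
#' @param truth A `"ground_truth"` object.
#' @param jitter_sd_ms SD of the Gaussian annotation jitter, in ms.
#' @return Tibble with `beat_time_s` and `label`; attribute `resolution_hz`.
#' @export
simulate_reference_beats <- function(truth, jitter_sd_ms = 0) {
  stopifnot(inherits(truth, "ground_truth"), jitter_sd_ms >= 0)
  bt <- truth$beats$beat_time_s
  if (jitter_sd_ms > 0) {
    set.seed(child_seed(truth$config$seed, 300L))
    bt <- bt + stats::rnorm(length(bt), 0, jitter_sd_ms / 1000)
    bt <- sort(bt)
  }
  keep <- !in_intervals(bt, truth$absence_intervals)
  out <- tibble::tibble(beat_time_s = bt[keep], label = truth$beats$label[keep])
  attr(out, "resolution_hz") <- 1000
  out
}

#' Simulate a complete multi-channel radar recording
#'
#' Convenience wrapper running [simulate_beats()],
#' [synthesize_displacement()] and [modulate_iq()] for every channel, plus
#' [simulate_reference_beats()]. Identical seeds give bit-identical
#' recordings.
#'
#' @param config A [sim_config()].
#' @param jitter_sd_ms Reference-channel timing jitter (ms).
#' @return A list of class `"radar_recording"`: `channels` (list of I/Q
#'   tibbles), `truth`, `reference`, `config`.
#' @export
#' @examples
#' rec <- simulate_recording(sim_config(duration = 10, n_channels = 2, seed = 7))
#' length(rec$channels)
simulate_recording <- function(config, jitter_sd_ms = 0) {
  truth <- simulate_beats(config)
  channels <- lapply(seq_len(config$n_channels), function(ch) {
    d <- synthesize_displacement(truth, config, ch)
    modulate_iq(d, config, ch)
  })
  structure(
    list(channels = channels, truth = truth,
         reference = simulate_reference_beats(truth, jitter_sd_ms),
         config = config),
    class = "radar_recording"
  )
}

#' Write / read a simulated recording as plain-text files
#'
#' One CSV per channel (`channel_<k>.csv`: `time_s,i,q`), a ground-truth
#' beat file (`ground_truth.csv`: `beat_time_s,label`) and a JSON sidecar
#' with the generating configuration.
#'
#' @param rec A `"radar_recording"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "radar_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(rec$channels)) {
    utils::write.csv(as.data.frame(rec$channels[[k]]),
                     file.path(dir, sprintf("channel_%d.csv", k)),
                     row.names = FALSE)
  }
  utils::write.csv(
    data.frame(beat_time_s = rec$truth$beats$beat_time_s,
               label = rec$truth$beats$label),
    file.path(dir, "ground_truth.csv"), row.names = FALSE
  )
  cfg <- rec$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_recording
#' @param path Path to one channel CSV written by [write_recording()]; the
#'   `config.json` sidecar in the same directory supplies sampling rate and
#'   wavelength.
#' @export
read_channel <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("time_s", "i", "q") %in% names(x))) {
    stop("malformed channel CSV: need columns time_s,i,q", call. = FALSE)
  }
  out <- tibble::as_tibble(x)
  sidecar <- file.path(dirname(path), "config.json")
  if (file.exists(sidecar)) {
    cfg <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(out, "sampling_rate") <- cfg$sampling_rate
    attr(out, "carrier_wavelength") <- cfg$carrier_wavelength
  } else if (nrow(out) > 1) {
    attr(out, "sampling_rate") <- 1 / stats::median(diff(out$time_s))
  }
  ch <- sub("^channel_(\\d+)\\.csv$", "\\1", basename(path))
  if (grepl("^\\d+$", ch)) attr(out, "channel") <- as.integer(ch)
  out
}
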