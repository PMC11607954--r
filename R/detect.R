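#' Envelope features for heart-sound segmentation
#'
#' Computes the two classic phonocardiogram segmentation features from the
#' band-limited heart-sound signal: the analytic-signal (Hilbert) envelope
#' and the homomorphic envelope (exponential of low-pass-filtered
#' log-envelope, cutoff 8 Hz), both resampled to the decoding frame rate
#' (default 50 Hz) and z-scored.
#'
#' @param hs Heart-sound tibble from [extract_heart_sound()].
#' @param feature_rate Frame rate for decoding, Hz.
#' @return Tibble with `time_s`, `homomorphic`, `hilbert`; attribute
#'   `feature_rate`.
#' @export
envelope_features <- function(hs, feature_rate = 50) {
  fs <- attr(hs, "sampling_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(hs$time_s))
  x <- hs$hs_um
  env <- Mod(analytic_signal(x))
  eps <- max(env) * 1e-6 + 1e-12
  lp <- signal::butter(1, min(8 / (fs / 2), 0.99), type = "low")
  homo <- exp(as.numeric(signal::filtfilt(lp, log(env + eps))))
  hilb <- as.numeric(signal::filtfilt(lp, env))

  t_frame <- seq(hs$time_s[1], hs$time_s[length(hs$time_s)], by = 1 / feature_rate)
  out <- tibble::tibble(
    time_s = t_frame,
    homomorphic = zscore(stats::approx(hs$time_s, homo, t_frame, rule = 2)$y),
    hilbert = zscore(stats::approx(hs$time_s, hilb, t_frame, rule = 2)$y)
  )
  attr(out, "feature_rate") <- feature_rate
  out
}

# FFT analytic signal (one-sided spectrum doubling)
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Coarse heart-rate estimate from envelope periodicity
#'
#' The segmentation model anchors its state-duration priors on an initial
#' average heart rate, estimated here from the autocorrelation of the
#' homomorphic envelope: the highest local peak at lags between 0.33 and
#' 2.0 s (30--180 bpm) gives the heart period. If no peak exceeds 0.2
#' (normalized), the estimate falls back to 75 bpm and is flagged
#' low-confidence.
#'
#' @param features Feature tibble from [envelope_features()].
#' @param min_lag,max_lag Search range for the heart period, seconds.
#' @param min_peak Minimum normalized autocorrelation for a confident peak.
#' @return List with `hr_bpm`, `confidence` (peak autocorrelation) and
#'   `low_confidence` flag.
#' @export
coarse_hr_estimate <- function(features, min_lag = 0.33, max_lag = 2.0,
                               min_peak = 0.2) {
  fr <- attr(features, "feature_rate")
  if (is.null(fr)) fr <- 1 / stats::median(diff(features$time_s))
  x <- features$homomorphic
  if (length(x) < 10 * fr) {
    stop("need at least 10 s of features for a coarse HR estimate", call. = FALSE)
  }
  max_lag_f <- min(as.integer(ceiling(max_lag * fr)), length(x) - 1L)
  ac <- stats::acf(x, lag.max = max_lag_f, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- seq_along(ac) - 1L
  lag_s <- lags / fr
  cand <- which(lag_s >= min_lag & lag_s <= max_lag)
  # local maxima only, so the zero-lag shoulder cannot win
  is_peak <- cand[cand > 1 & cand < length(ac) &
                    ac[cand] >= ac[cand - 1] & ac[cand] >= ac[cand + 1]]
  if (length(is_peak) == 0 || max(ac[is_peak]) < min_peak) {
    return(list(hr_bpm = 75, confidence = if (length(is_peak)) max(ac[is_peak]) else 0,
                low_confidence = TRUE))
  }
  best <- is_peak[which.max(ac[is_peak])]
  list(hr_bpm = 60 / lag_s[best], confidence = ac[best], low_confidence = FALSE)
}

#' Parameterize the four-state heart-sound HSMM
#'
#' Fixed-cycle hidden semi-Markov model S1 -> systole -> S2 -> diastole with
#' Gaussian state durations anchored on the coarse heart period `T =
#' 60/coarse_hr`: S1 120 +/- 25 ms, S2 90 +/- 25 ms, systole (S1 end to S2
#' start) mean `0.33 T - 120 ms`, diastole the remainder of the cycle;
#' duration caps at mean + 3 SD. Emissions are Gaussian over the two
#' z-scored envelope features, with high means for the sound states and low
#' means for the interval states. Parameters are configuration, not fitted.
#'
#' @param coarse_hr Anchor heart rate, bpm (30--180).
#' @param feature_rate Decoding frame rate, Hz.
#' @return List of class `"hsmm_model"`: state names, emission means
#'   (state x feature), duration mean/sd/cap in frames.
#' @export
hsmm_model <- function(coarse_hr, feature_rate = 50) {
  stopifnot(coarse_hr >= 30, coarse_hr <= 180)
  T_s <- 60 / coarse_hr
  mean_s <- c(
    s1 = 0.120,
    systole = max(0.33 * T_s - 0.120, 0.030),
    s2 = 0.090,
    diastole = max(T_s - 0.120 - max(0.33 * T_s - 0.120, 0.030) - 0.090, 0.050)
  )
  sd_s <- c(s1 = 0.025,
            systole = max(0.1 * mean_s[["systole"]], 0.025),
            s2 = 0.025,
            diastole = max(0.12 * mean_s[["diastole"]], 0.035))
  emission_means <- rbind(
    s1 = c(1.5, 1.5),
    systole = c(-0.6, -0.6),
    s2 = c(0.9, 0.9),
    diastole = c(-0.6, -0.6)
  )
  structure(
    list(states = c("s1", "systole", "s2", "diastole"),
         emission_means = emission_means,
         emission_sd = 1,
         dur_mean_f = mean_s * feature_rate,
         dur_sd_f = sd_s * feature_rate,
         dur_cap_f = pmax(ceiling((mean_s + 3 * sd_s) * feature_rate), 2),
         feature_rate = feature_rate),
    class = "hsmm_model"
  )
}

#' Segment heart sounds by duration-dependent Viterbi decoding
#'
#' Decodes the maximum-likelihood S1/systole/S2/diastole state sequence
#' under the model's duration distributions (semi-Markov Viterbi; the state
#' order is the fixed cardiac cycle). S1 and S2 event times are the
#' midpoints of the decoded segments; each S2 is paired with the S1 opening
#' its cycle.
#'
#' @param features Feature tibble from [envelope_features()].
#' @param coarse_hr Anchor heart rate in bpm; when `NULL`, estimated with
#'   [coarse_hr_estimate()].
#' @param model Optional pre-built [hsmm_model()].
#' @return Tibble with `s1_time_s`, `s2_time_s` (NA when the cycle's S2
#'   segment is missing at the window edge). Empty when the window is
#'   shorter than one mean cycle.
#' @export
hsmm_segment <- function(features, coarse_hr = NULL, model = NULL) {
  fr <- attr(features, "feature_rate")
  if (is.null(fr)) fr <- 1 / stats::median(diff(features$time_s))
  n <- nrow(features)
  if (n == 0) return(tibble::tibble(s1_time_s = numeric(), s2_time_s = numeric()))
  if (is.null(model)) {
    if (is.null(coarse_hr)) coarse_hr <- coarse_hr_estimate(features)$hr_bpm
    coarse_hr <- min(max(coarse_hr, 30), 180)
    model <- hsmm_model(coarse_hr, feature_rate = fr)
  }
  if (n < sum(model$dur_mean_f)) {
    return(tibble::tibble(s1_time_s = numeric(), s2_time_s = numeric()))
  }

  feat <- cbind(zscore(features$homomorphic), zscore(features$hilbert))
  S <- length(model$states)
  ll <- matrix(0, n, S)
  for (s in seq_len(S)) {
    ll[, s] <- -0.5 * ((feat[, 1] - model$emission_means[s, 1])^2 +
                         (feat[, 2] - model$emission_means[s, 2])^2) /
      model$emission_sd^2
  }
  Dmax <- max(model$dur_cap_f)
  logdur <- matrix(-Inf, S, Dmax)
  for (s in seq_len(S)) {
    d <- seq_len(model$dur_cap_f[s])
    p <- stats::dnorm(d, model$dur_mean_f[s], model$dur_sd_f[s])
    p <- p / sum(p)
    logdur[s, d] <- log(pmax(p, 1e-300))
  }
  path <- viterbi_hsmm_cpp(ll, logdur)

  seg_mid <- function(state_idx) {
    r <- rle(path == state_idx)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    mid <- (starts[r$values] + ends[r$values]) / 2
    features$time_s[1] + (mid - 1) / fr
  }
  s1 <- seg_mid(1L)
  s2 <- seg_mid(3L)
  if (length(s1) == 0) return(tibble::tibble(s1_time_s = numeric(), s2_time_s = numeric()))
  # pair each S1 with the first S2 before the next S1
  nxt <- c(s1[-1], Inf)
  s2_for <- vapply(seq_along(s1), function(i) {
    hit <- s2[s2 > s1[i] & s2 < nxt[i]]
    if (length(hit)) hit[1] else NA_real_
  }, numeric(1))
  tibble::tibble(s1_time_s = s1, s2_time_s = s2_for)
}

#' Interbeat intervals between consecutive first heart sounds
#'
#' The IBI is defined as the time between two consecutive S1 events; a
#' sequence of `n` beats yields `n - 1` IBIs, stored on the beat opening
#' each interval (the last beat's `ibi_s` is `NA`).
#'
#' @param beats Tibble with an `s1_time_s` column (strictly increasing).
#' @return The input with an `ibi_s` column.
#' @export
#' @examples
#' compute_ibis(tibble::tibble(s1_time_s = c(0, 1, 2.1)))$ibi_s
compute_ibis <- function(beats) {
  stopifnot("s1_time_s" %in% names(beats))
  s1 <- beats$s1_time_s
  if (length(s1) >= 2 && any(diff(s1) <= 0)) {
    stop("`s1_time_s` must be strictly increasing", call. = FALSE)
  }
  beats$ibi_s <- if (length(s1) >= 2) c(diff(s1), NA_real_) else rep(NA_real_, length(s1))
  beats
}

#' Pick the best radar channel per window from SQI
#'
#' For each analysis window the channel with the highest signal quality
#' index is selected; exact ties go to the lowest channel index; windows in
#' which no channel has a valid SQI (subject absent, degenerate signal) are
#' marked missing.
#'
#' @param sqi Long tibble with columns `channel`, `window_start_s`,
#'   `sqi_db` and optionally `valid` (as produced by stacking
#'   [compute_sqi()] results per channel).
#' @return Tibble with `window_start_s`, `channel` (`NA` when missing),
#'   `sqi_db`.
#' @export
select_best_channel <- function(sqi) {
  stopifnot(all(c("channel", "window_start_s", "sqi_db") %in% names(sqi)))
  if (!"valid" %in% names(sqi)) sqi$valid <- is.finite(sqi$sqi_db)
  choose_channel <- function(channel, sqi_db, valid) {
    if (!any(valid)) {
      return(tibble::tibble(channel = NA_integer_, sqi_db = NA_real_))
    }
    channel <- channel[valid]; sqi_db <- sqi_db[valid]
    j <- order(-sqi_db, channel)[1]   # argmax, ties to lowest channel index
    tibble::tibble(channel = as.integer(channel[j]), sqi_db = sqi_db[j])
  }
  sqi |>
    dplyr::reframe(choose_channel(.data$channel, .data$sqi_db, .data$valid),
                   .by = "window_start_s") |>
    dplyr::arrange(.data$window_start_s)
}

#' Process one radar channel into detection inputs
#'
#' Runs demodulation, presence detection, heart-sound extraction, envelope
#' features and per-window SQI for a single channel, returning only the
#' low-rate products needed for channel selection and decoding (the raw
#' waveforms can then be discarded -- important for hours-long recordings).
#'
#' @param iq I/Q tibble for one channel.
#' @param sqi_window SQI / channel-selection window, seconds (60, 30 or 3).
#' @param feature_rate Decoding frame rate, Hz.
#' @param presence_window,presence_threshold_db See [detect_presence()].
#' @return List of class `"radar_channel_features"`: `features`, `sqi`,
#'   `presence`, `channel`, `valid`.
#' @export
process_channel <- function(iq, sqi_window = 60, feature_rate = 50,
                            presence_window = 1, presence_threshold_db = 10) {
  ch <- attr(iq, "channel")
  if (is.null(ch)) ch <- 1L
  disp <- demodulate_displacement(iq)
  pres <- detect_presence(iq, window = presence_window,
                          threshold_db = presence_threshold_db)
  hs <- extract_heart_sound(disp)
  feats <- envelope_features(hs, feature_rate = feature_rate)
  sqi <- compute_sqi(disp, window = sqi_window)
  # SQI is undefined where the subject is absent: invalidate those windows
  if (nrow(sqi) > 0) {
    absent_at <- function(t0) {
      sel <- pres$window_start_s >= t0 & pres$window_start_s < t0 + sqi_window
      any(sel) && mean(pres$present[sel]) < 0.5
    }
    gone <- vapply(sqi$window_start_s, absent_at, logical(1))
    sqi$valid <- sqi$valid & !gone
    sqi$sqi_db[gone] <- -Inf
  }
  structure(
    list(features = feats, sqi = sqi, presence = pres,
         channel = as.integer(ch), valid = isTRUE(attr(disp, "valid"))),
    class = "radar_channel_features"
  )
}

#' Detect heart beats across channels with SQI-driven selection
#'
#' For every channel-selection window the channel with the highest SQI is
#' chosen; decoding itself runs on longer windows (`decode_window`, with 2 s
#' of context on both sides) so the duration-anchored HSMM always sees
#' enough cardiac cycles, even when the selection granularity is as short
#' as 3 s. Within a decode window every channel that wins at least one
#' selection window is decoded, and each selection window keeps the beats
#' of its winning channel. Merged S1 times are de-duplicated and turned
#' into IBIs.
#'
#' @param processed List of `"radar_channel_features"` (one per channel)
#'   from [process_channel()], or a `"radar_recording"` whose channels are
#'   then processed with the given `sqi_window`.
#' @param sqi_window Channel-selection window, seconds.
#' @param decode_window HSMM decoding window, seconds (default at least
#'   60 s and never shorter than `sqi_window`).
#' @param pad Decoding context on each side of a decode window, seconds.
#' @param min_refractory Minimum spacing between merged S1 events, seconds.
#' @return Tibble with `s1_time_s`, `s2_time_s`, `channel`, `ibi_s`.
#' @export
detect_beats <- function(processed, sqi_window = 60, decode_window = NULL,
                         pad = 2, min_refractory = 0.25) {
  if (inherits(processed, "radar_recording")) {
    processed <- lapply(processed$channels, process_channel, sqi_window = sqi_window)
  }
  stopifnot(length(processed) >= 1,
            all(vapply(processed, inherits, logical(1), "radar_channel_features")))
  if (is.null(decode_window)) decode_window <- max(sqi_window, 60)
  stopifnot(decode_window >= sqi_window)
  chan_ids <- vapply(processed, `[[`, integer(1), "channel")
  sqi_all <- purrr::map_dfr(processed, function(p) {
    dplyr::mutate(p$sqi, channel = p$channel)
  })
  choice <- select_best_channel(sqi_all)

  t_max <- max(vapply(processed, function(p) max(p$features$time_s), numeric(1)))
  dw_starts <- seq(0, max(t_max - 1e-9, 0), by = decode_window)
  decode_one <- function(p, t0, t1) {
    f <- p$features
    sel <- f$time_s >= t0 - pad & f$time_s < t1 + pad
    fw <- f[sel, , drop = FALSE]
    attr(fw, "feature_rate") <- attr(f, "feature_rate")
    if (nrow(fw) < 4) return(NULL)
    ch_est <- tryCatch(coarse_hr_estimate(fw)$hr_bpm, error = function(e) 75)
    hsmm_segment(fw, coarse_hr = ch_est)
  }
  beats <- purrr::map_dfr(dw_starts, function(t0) {
    t1 <- t0 + decode_window
    local <- choice[choice$window_start_s >= t0 & choice$window_start_s < t1 &
                      !is.na(choice$channel), , drop = FALSE]
    if (nrow(local) == 0) return(NULL)
    purrr::map_dfr(unique(local$channel), function(ch) {
      seg <- decode_one(processed[[which(chan_ids == ch)[1]]], t0, t1)
      if (is.null(seg) || nrow(seg) == 0) return(NULL)
      # keep beats falling in the selection windows this channel won
      wins <- local$window_start_s[local$channel == ch]
      idx <- findInterval(seg$s1_time_s, c(rbind(wins, wins + sqi_window)))
      keep <- idx %% 2 == 1 &
        seg$s1_time_s >= t0 & seg$s1_time_s < t1
      if (!any(keep)) return(NULL)
      dplyr::mutate(seg[keep, , drop = FALSE], channel = as.integer(ch))
    })
  })
  if (nrow(beats) == 0) {
    return(tibble::tibble(s1_time_s = numeric(), s2_time_s = numeric(),
                          channel = integer(), ibi_s = numeric()))
  }
  beats <- dplyr::arrange(beats, .data$s1_time_s)
  keep <- c(TRUE, diff(beats$s1_time_s) >= min_refractory)
  compute_ibis(beats[keep, , drop = FALSE])
}
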