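#' Demodulate radar I/Q into chest-surface displacement
#'
#' Continuous-wave interferometry maps target displacement `d(t)` to baseband
#' phase `theta(t) = 4*pi*d(t)/lambda`. The receiver adds an unknown complex
#' DC offset, so the I/Q cloud is a circular arc around that offset. The
#' demodulator estimates the offset by an algebraic least-squares circle fit
#' (Kasa normal equations), subtracts it, takes the unwrapped phase angle and
#' rescales by `lambda/(4*pi)`. Output is zero-mean over the recording. The
#' result is invariant to the DC offset and to global phase rotation.
#'
#' @param iq Tibble with columns `time_s`, `i`, `q` and attributes
#'   `sampling_rate` (Hz) and `carrier_wavelength` (mm), as produced by
#'   [modulate_iq()] or [read_channel()].
#' @param carrier_wavelength Override for the wavelength attribute, mm.
#' @return Tibble with `time_s`, `disp_um`; attributes `sampling_rate` and
#'   `valid` (`FALSE` when the I/Q cloud is degenerate, in which case the
#'   displacement is all zero rather than an error).
#' @export
#' @examples
#' cfg <- sim_config(duration = 5, seed = 3)
#' gt <- simulate_beats(cfg)
#' iq <- modulate_iq(synthesize_displacement(gt, cfg, 1), cfg, 1, noiseless = TRUE)
#' d <- demodulate_displacement(iq)
demodulate_displacement <- function(iq, carrier_wavelength = attr(iq, "carrier_wavelength")) {
  stopifnot(all(c("time_s", "i", "q") %in% names(iq)))
  if (is.null(carrier_wavelength)) {
    stop("carrier wavelength not given and not an attribute of `iq`", call. = FALSE)
  }
  fs <- attr(iq, "sampling_rate")
  x <- iq$i; y <- iq$q
  ctr <- fit_circle_center(x, y)
  xc <- x - ctr[1]; yc <- y - ctr[2]
  radius <- sqrt(mean(xc^2 + yc^2))
  spread <- sqrt(stats::var(x) + stats::var(y))
  valid <- is.finite(radius) && radius > 10 * .Machine$double.eps * (1 + spread)
  if (!valid) {
    disp <- numeric(length(x))
  } else {
    theta <- unwrap_phase(atan2(yc, xc))
    disp <- theta * carrier_wavelength * 1000 / (4 * pi)   # lambda mm -> um
    disp <- disp - mean(disp)
  }
  out <- tibble::tibble(time_s = iq$time_s, disp_um = disp)
  attr(out, "sampling_rate") <- fs
  attr(out, "valid") <- valid
  out
}

# Kasa algebraic circle fit: least squares on x^2+y^2 = 2ax + 2by + c
fit_circle_center <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  Suu <- sum(u * u); Svv <- sum(v * v); Suv <- sum(u * v)
  Suuu <- sum(u^3); Svvv <- sum(v^3)
  Suvv <- sum(u * v * v); Svuu <- sum(v * u * u)
  det <- Suu * Svv - Suv * Suv
  if (!is.finite(det) || abs(det) < 1e-12 * (Suu + Svv + 1e-300)) {
    return(c(mx, my))   # degenerate cloud: fall back to the centroid
  }
  a <- (Svv * (Suuu + Suvv) - Suv * (Svvv + Svuu)) / (2 * det)
  b <- (Suu * (Svvv + Svuu) - Suv * (Suuu + Suvv)) / (2 * det)
  c(mx + a, my + b)
}

# phase unwrapping: remove 2*pi jumps between successive samples
unwrap_phase <- function(theta) {
  d <- diff(theta)
  correction <- cumsum(-2 * pi * round(d / (2 * pi)))
  c(theta[1], theta[1] + cumsum(d) + correction)
}

#' Detect subject presence from reflected-signal power
#'
#' A subject in bed modulates the reflected wave (respiration alone sweeps
#' the baseband phase by a large fraction of a radian), so the windowed
#' variance of the received I/Q is orders of magnitude larger than for an
#' empty bed, where only receiver noise remains. Per window the received
#' power variance is compared against an empty-bed baseline and flagged
#' present when it exceeds the baseline by `threshold_db`. The baseline is
#' the window's own receiver-noise floor, estimated from first differences
#' of the I/Q samples (body motion is slow relative to the sampling rate,
#' so successive differences are almost pure noise); a variance within a
#' few dB of that floor means nothing but noise moved. A fixed data-derived
#' quantile would fail on the common overnight recording in which the
#' subject never leaves the bed.
#'
#' @param iq I/Q tibble (see [demodulate_displacement()]).
#' @param window Window length in seconds (>= 1).
#' @param threshold_db Presence margin over the empty-bed baseline, dB.
#' @return Tibble with `window_start_s`, `present` (integer 0/1),
#'   `power_db`; attribute `window`.
#' @export
detect_presence <- function(iq, window = 1, threshold_db = 10) {
  stopifnot(window >= 1)
  fs <- attr(iq, "sampling_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(iq$time_s))
  z <- complex(real = iq$i, imaginary = iq$q)
  wlen <- max(2L, as.integer(round(window * fs)))
  starts <- seq(1L, max(length(z) - wlen + 1L, 1L), by = wlen)
  stats_w <- vapply(starts, function(s) {
    w <- z[s:min(s + wlen - 1L, length(z))]
    dv <- diff(w)
    c(stats::var(Re(w)) + stats::var(Im(w)),
      (stats::var(Re(dv)) + stats::var(Im(dv))) / 2)   # noise-floor estimate
  }, numeric(2))
  pow <- stats_w[1, ]
  floor_w <- pmax(stats_w[2, ], 1e-300)
  pdb <- 10 * log10(pmax(pow, 1e-300) / floor_w)
  out <- tibble::tibble(
    window_start_s = iq$time_s[starts],
    present = as.integer(pdb > threshold_db),
    power_db = pdb
  )
  attr(out, "window") <- window
  out
}

#' Extract the heart-sound band from displacement
#'
#' Band-passes the displacement to 16--80 Hz, where valve-closure vibrations
#' (S1/S2) live and respiration and pulse-wave motion do not. The filter is
#' a 4th-order Butterworth applied forward and backward (zero phase), so
#' S1/S2 timing is not skewed by group delay.
#'
#' @param disp Displacement tibble with `time_s`, `disp_um` and a
#'   `sampling_rate` attribute.
#' @param band Passband corners in Hz.
#' @param order Butterworth order per direction.
#' @return Tibble with `time_s`, `hs_um`; attribute `sampling_rate`.
#' @export
extract_heart_sound <- function(disp, band = c(16, 80), order = 4) {
  fs <- attr(disp, "sampling_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(disp$time_s))
  if (fs <= 2 * band[2]) {
    stop(sprintf("sampling rate %.0f Hz violates the Nyquist limit for the %g Hz band edge",
                 fs, band[2]), call. = FALSE)
  }
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  hs <- signal::filtfilt(bf, disp$disp_um)
  out <- tibble::tibble(time_s = disp$time_s, hs_um = as.numeric(hs))
  attr(out, "sampling_rate") <- fs
  attr(out, "valid") <- isTRUE(attr(disp, "valid")) || is.null(attr(disp, "valid"))
  out
}

#' Per-window signal quality index (SQI)
#'
#' The SQI is the signal-to-noise ratio of the heart-sound band: per
#' half-open window `[t, t+W)`, `10*log10(P_band / P_noise)` where `P_band`
#' is the raw spectral power in 16--80 Hz and `P_noise` the power in the
#' 100 Hz--Nyquist noise floor rescaled to the 64 Hz passband width. White
#' noise therefore scores ~0 dB and a clean in-band tone scores highly. The
#' input must not be pre-band-limited (feed displacement, not the filtered
#' heart-sound signal), otherwise the noise floor is underestimated.
#'
#' @param disp Displacement tibble with `time_s`, `disp_um`, attribute
#'   `sampling_rate` (> 200 Hz so the noise band exists).
#' @param window Window length in seconds (60, 30 and 3 are the usual
#'   choices, matching interval, block and beat-wise processing).
#' @param band Heart-sound band, Hz.
#' @param noise_floor_hz Lower edge of the noise-estimation band, Hz.
#' @return Tibble with `window_start_s`, `sqi_db` (`-Inf` for an all-zero
#'   window), `valid`; attribute `window`.
#' @export
compute_sqi <- function(disp, window = 60, band = c(16, 80), noise_floor_hz = 100) {
  fs <- attr(disp, "sampling_rate")
  if (is.null(fs)) fs <- 1 / stats::median(diff(disp$time_s))
  if (fs / 2 <= noise_floor_hz) {
    stop("sampling rate too low: no spectrum above the noise-floor edge", call. = FALSE)
  }
  x <- disp$disp_um
  wlen <- as.integer(round(window * fs))
  if (wlen > length(x)) stop("`window` exceeds the recording length", call. = FALSE)
  starts <- seq(1L, length(x) - wlen + 1L, by = wlen)
  bw <- band[2] - band[1]
  sqi <- vapply(starts, function(s) {
    w <- x[s:(s + wlen - 1L)]
    if (all(w == 0)) return(-Inf)
    w <- w - mean(w)
    spec <- Mod(stats::fft(w))^2
    freq <- (seq_along(spec) - 1) * fs / length(spec)
    half <- freq <= fs / 2
    p_band <- sum(spec[half & freq >= band[1] & freq <= band[2]])
    noise_sel <- half & freq >= noise_floor_hz
    p_noise_hz <- sum(spec[noise_sel]) / (fs / 2 - noise_floor_hz)
    10 * log10(p_band / (p_noise_hz * bw))
  }, numeric(1))
  out <- tibble::tibble(
    window_start_s = disp$time_s[starts],
    sqi_db = sqi,
    valid = is.finite(sqi)
  )
  attr(out, "window") <- window
  out
}
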