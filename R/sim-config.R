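#' Configuration for the synthetic radar-bed simulator
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults describe the bed-mounted monitoring setup the pipeline targets:
#' four 24-GHz continuous-wave radar units (carrier wavelength 12.49 mm)
#' observing micrometre-scale S1/S2 chest-surface vibrations riding on
#' millimetre-scale respiration.
#'
#' @param duration Recording length in seconds.
#' @param n_channels Number of radar channels (default 4).
#' @param sampling_rate Baseband sampling rate in Hz (default 2000; must be
#'   at least 200 Hz so the 16--80 Hz heart-sound band is representable).
#' @param carrier_wavelength Carrier wavelength in mm (default 12.49, the
#'   24-GHz ISM band).
#' @param base_hr Baseline heart rate in bpm.
#' @param hrv_sd Beat-to-beat heart-rate variability (bpm). Both the white
#'   HRV component and the stationary SD of the slow AR(1) drift use this
#'   scale, so the total HR SD is about `sqrt(2) * hrv_sd`.
#' @param resp_rate Respiration rate in breaths per minute.
#' @param resp_amplitude Respiration displacement amplitude in mm.
#' @param s1_amplitude,s2_amplitude Peak amplitudes of the S1/S2 heart-sound
#'   wavelets in micrometres.
#' @param channel_snr Per-channel signal-to-noise ratio in dB (recycled or
#'   truncated to `n_channels`). SNR is defined against the unit carrier
#'   amplitude.
#' @param artifact_rate Expected number of motion-artifact events per hour.
#' @param absence_intervals List (or 2-column matrix) of `[start, end)`
#'   intervals in seconds during which the subject is out of bed.
#' @param ves_fraction,sves_fraction Proportion of beats that are ventricular
#'   (VES) / supraventricular (SVES) extrasystoles. Each ectopic beat
#'   perturbs the two interbeat intervals adjacent to it.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(duration = 60, base_hr = 75, seed = 1)
#' cfg$carrier_wavelength
sim_config <- function(duration = 300,
                       n_channels = 4,
                       sampling_rate = 2000,
                       carrier_wavelength = 12.49,
                       base_hr = 75,
                       hrv_sd = 2,
                       resp_rate = 14,
                       resp_amplitude = 2,
                       s1_amplitude = 30,
                       s2_amplitude = 15,
                       channel_snr = c(30, 20, 15, 10),
                       artifact_rate = 4,
                       absence_intervals = NULL,
                       ves_fraction = 0,
                       sves_fraction = 0,
                       seed = 1L) {
  stopifnot(is.numeric(duration), length(duration) == 1, is.finite(duration))
  if (duration <= 0) stop("`duration` must be positive", call. = FALSE)
  if (!is.finite(base_hr) || base_hr <= 0) {
    stop("`base_hr` must be finite and positive", call. = FALSE)
  }
  if (sampling_rate < 200) {
    stop("`sampling_rate` must be >= 200 Hz (Nyquist margin for the 80 Hz band edge)",
         call. = FALSE)
  }
  if (carrier_wavelength <= 0) stop("`carrier_wavelength` must be positive", call. = FALSE)
  amps <- c(resp_amplitude, s1_amplitude, s2_amplitude)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("amplitudes must be finite and non-negative", call. = FALSE)
  }
  if (ves_fraction < 0 || sves_fraction < 0 || ves_fraction + sves_fraction >= 1) {
    stop("need 0 <= ves_fraction + sves_fraction < 1", call. = FALSE)
  }
  if (hrv_sd < 0) stop("`hrv_sd` must be non-negative", call. = FALSE)
  absence_intervals <- normalize_intervals(absence_intervals, duration)
  channel_snr <- rep_len(as.numeric(channel_snr), n_channels)

  structure(
    list(
      duration = as.numeric(duration),
      n_channels = as.integer(n_channels),
      sampling_rate = as.numeric(sampling_rate),
      carrier_wavelength = as.numeric(carrier_wavelength),
      base_hr = as.numeric(base_hr),
      hrv_sd = as.numeric(hrv_sd),
      resp_rate = as.numeric(resp_rate),
      resp_amplitude = as.numeric(resp_amplitude),
      s1_amplitude = as.numeric(s1_amplitude),
      s2_amplitude = as.numeric(s2_amplitude),
      channel_snr = channel_snr,
      artifact_rate = as.numeric(artifact_rate),
      absence_intervals = absence_intervals,
      ves_fraction = as.numeric(ves_fraction),
      sves_fraction = as.numeric(sves_fraction),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %.0f s, %d channel(s) @ %.0f Hz, lambda %.2f mm\n",
              x$duration, x$n_channels, x$sampling_rate, x$carrier_wavelength))
  cat(sprintf("  HR %.0f bpm (hrv_sd %.1f), resp %.0f /min x %.1f mm\n",
              x$base_hr, x$hrv_sd, x$resp_rate, x$resp_amplitude))
  cat(sprintf("  S1 %.0f um, S2 %.0f um, SNR [%s] dB, seed %d\n",
              x$s1_amplitude, x$s2_amplitude,
              paste(format(x$channel_snr), collapse = ", "), x$seed))
  invisible(x)
}

# list-of-c(start,end) or 2-col matrix -> list of sorted [start, end) pairs
normalize_intervals <- function(x, duration = Inf) {
  if (is.null(x) || length(x) == 0) return(list())
  if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
  if (is.numeric(x) && length(x) == 2) x <- list(x)
  x <- lapply(x, function(iv) {
    iv <- as.numeric(iv)
    if (length(iv) != 2 || !all(is.finite(iv)) || iv[1] >= iv[2]) {
      stop("each interval must be a finite [start, end) pair with start < end",
           call. = FALSE)
    }
    c(max(iv[1], 0), min(iv[2], duration))
  })
  x[order(vapply(x, `[`, numeric(1), 1))]
}

# TRUE for times falling inside any [start, end) interval
in_intervals <- function(t, intervals) {
  out <- rep(FALSE, length(t))
  for (iv in intervals) out <- out | (t >= iv[1] & t < iv[2])
  out
}

# deterministic child seed for a named sub-stream of the simulator
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(stream) * 7919) %% 2147483647)
}
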