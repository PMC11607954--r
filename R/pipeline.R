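#' Study-arm processing parameters
#'
#' The three validation settings differ only in the channel-selection
#' window and the HR aggregation: overnight Holter comparison (arm `"I"`,
#' 60-s SQI windows, 5-min interval means), beat-wise one-hour comparison
#' (arm `"II"`, 3-s SQI windows, rolling 10-IBI means) and long-term
#' monitoring (arm `"III"`, 30-s SQI windows, 30-beat block means with the
#' two-stage outlier filter).
#'
#' @param arm `"I"`, `"II"` or `"III"`.
#' @return List with `sqi_window` (s), `aggregation`, `interval_width`,
#'   `rolling_k`, `block_k`, `outlier_filter` flag.
#' @export
arm_parameters <- function(arm = c("I", "II", "III")) {
  arm <- match.arg(arm)
  switch(arm,
    I = list(arm = "I", sqi_window = 60, aggregation = "interval_5min",
             interval_width = 300, rolling_k = 10, block_k = 30,
             outlier_filter = FALSE),
    II = list(arm = "II", sqi_window = 3, aggregation = "rolling_10beat",
              interval_width = 300, rolling_k = 10, block_k = 30,
              outlier_filter = FALSE),
    III = list(arm = "III", sqi_window = 30, aggregation = "block_30beat",
               interval_width = 300, rolling_k = 10, block_k = 30,
               outlier_filter = TRUE)
  )
}

#' Run the full radar heart-rate pipeline on a simulated subject
#'
#' End-to-end chain: simulate (channel by channel, so hours-long
#' multi-channel recordings never hold all raw waveforms in memory at
#' once) -> demodulate -> heart-sound band -> SQI -> channel selection ->
#' HSMM beat detection -> HR aggregation per study arm -> pairing with the
#' reference -> exclusion rules -> concordance statistics. Identical
#' configuration and seed give identical outputs.
#'
#' @param config A [sim_config()] describing the subject and recording.
#' @param arm Study arm, see [arm_parameters()].
#' @param jitter_sd_ms Reference-channel timing jitter, ms.
#' @param out_dir Optional directory; when given, the HR series, paired
#'   CSV and a JSON report (full precision, with the parameter echo) are
#'   written there.
#' @param verbose Print stage progress.
#' @return List of class `"radar_hr_run"`: `beats`, `hr_radar`, `hr_ref`,
#'   `pairs` (after exclusions), `exclusions`, `bland_altman`,
#'   `regression`, `tost`, `truth`, `params`.
#' @export
run_pipeline <- function(config, arm = "I", jitter_sd_ms = 0,
                         out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  params <- arm_parameters(arm)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating ground truth (%.0f s, seed %d)", config$duration, config$seed)
  truth <- simulate_beats(config)
  reference <- simulate_reference_beats(truth, jitter_sd_ms)

  say("processing %d channel(s)", config$n_channels)
  processed <- vector("list", config$n_channels)
  presence <- NULL
  for (ch in seq_len(config$n_channels)) {
    d <- synthesize_displacement(truth, config, ch)
    iq <- modulate_iq(d, config, ch)
    rm(d)
    processed[[ch]] <- process_channel(iq, sqi_window = params$sqi_window)
    rm(iq)
    if (is.null(presence)) presence <- processed[[ch]]$presence
  }

  say("detecting beats (HSMM, %g-s channel-selection windows)", params$sqi_window)
  beats <- detect_beats(processed, sqi_window = params$sqi_window)

  say("aggregating HR (%s)", params$aggregation)
  ref_beats <- tibble::tibble(s1_time_s = reference$beat_time_s)
  if (params$aggregation == "interval_5min") {
    t_end <- config$duration
    hr_radar <- interval_mean_hr(beats, width = params$interval_width,
                                 presence = presence, t_end = t_end)
    hr_ref <- interval_mean_hr(ref_beats, width = params$interval_width, t_end = t_end)
    pairs <- synchronize_pairs(hr_radar, hr_ref, mode = "interval")
  } else if (params$aggregation == "rolling_10beat") {
    hr_radar <- rolling_mean_hr(beats, k = params$rolling_k)
    hr_ref <- rolling_mean_hr(ref_beats, k = params$rolling_k)
    pairs <- synchronize_pairs(hr_radar, hr_ref, mode = "beat")
  } else {
    hr_radar <- block_mean_hr(beats, k = params$block_k, mode = "beats")
    hr_ref <- block_mean_hr(ref_beats, k = params$block_k, mode = "beats")
    if (params$outlier_filter) {
      hr_radar <- local_outlier_filter(global_outlier_filter(hr_radar))
    }
    pairs <- synchronize_pairs(
      dplyr::filter(hr_radar, .data$valid), hr_ref, mode = "beat",
      tolerance = params$block_k * 1.5)
  }

  pairs <- exclude_half_double(pairs)
  excl <- exclusion_summary(pairs)

  say("concordance statistics on %d candidate pairs", nrow(pairs))
  nv <- nrow(valid_pairs(pairs))
  ba <- if (nv >= 2) bland_altman(pairs) else NULL
  reg <- if (nv >= 2) tryCatch(fit_regression(pairs), error = function(e) NULL) else NULL
  tost <- if (nv >= 3) tost_paired(pairs) else NULL

  res <- structure(
    list(beats = beats, hr_radar = hr_radar, hr_ref = hr_ref, pairs = pairs,
         exclusions = excl, bland_altman = ba, regression = reg, tost = tost,
         truth = truth, reference = reference, params = params, config = config),
    class = "radar_hr_run"
  )
  if (!is.null(out_dir)) write_run(res, out_dir)
  res
}

#' @export
print.radar_hr_run <- function(x, ...) {
  cat(sprintf("<radar_hr_run> arm %s, %.1f h, %d channels, seed %d\n",
              x$params$arm, x$config$duration / 3600, x$config$n_channels,
              x$config$seed))
  cat(sprintf("  %d detected beats, %d paired values (%d analysed)\n",
              nrow(x$beats), nrow(x$pairs), nrow(valid_pairs(x$pairs))))
  if (!is.null(x$bland_altman)) print(x$bland_altman)
  if (!is.null(x$tost)) print(x$tost)
  invisible(x)
}

#' Write pipeline artifacts
#'
#' Writes `beats.csv` (`beat_index,s1_time_s,s2_time_s,ibi_s,channel`),
#' `pairs.csv` (the paired HR hand-off: interval start, both HRs, their
#' difference, validity and exclusion reason), and `report.json` with the
#' full-precision statistics and a complete parameter echo, so a run is
#' reproducible from its artifacts alone.
#'
#' @param run A `"radar_hr_run"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  beats <- dplyr::mutate(run$beats, beat_index = dplyr::row_number())
  utils::write.csv(
    beats[, c("beat_index", "s1_time_s", "s2_time_s", "ibi_s", "channel")],
    file.path(dir, "beats.csv"), row.names = FALSE)

  pr <- run$pairs
  pr$valid <- pr$exclusion_reason == "none"
  utils::write.csv(
    data.frame(interval_start_s = pr$time_s,
               hr_radar_bpm = pr$hr_radar, hr_ref_bpm = pr$hr_ref,
               diff_bpm = pr$diff, valid = pr$valid,
               exclusion_reason = pr$exclusion_reason),
    file.path(dir, "pairs.csv"), row.names = FALSE)

  cfg <- run$config; class(cfg) <- NULL
  report <- list(
    params = run$params,
    config = cfg,
    exclusions = run$exclusions,
    bland_altman = if (!is.null(run$bland_altman)) tidy(run$bland_altman),
    regression = if (!is.null(run$regression)) glance(run$regression),
    tost = if (!is.null(run$tost)) glance(run$tost)
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
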