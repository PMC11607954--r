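#' Interval-mean heart rate (five-minute intervals)
#'
#' Aggregates IBIs into mean HR over fixed half-open intervals, the scheme
#' used for overnight monitoring against a Holter reference: per interval,
#' `HR = 60 / mean(IBIs fully inside)` (a mean of intervals, not a mean of
#' instantaneous rates). An interval is invalid when it holds fewer than
#' `min_ibis` IBIs or the subject was absent for most of it.
#'
#' @param beats Beat tibble with `s1_time_s` (and `ibi_s`; recomputed if
#'   missing) from [detect_beats()] or built from reference beat times.
#' @param width Interval width in seconds (default 300 = 5 min).
#' @param min_ibis Minimum IBI count for a valid interval.
#' @param presence Optional presence tibble ([detect_presence()]); an
#'   interval with mean presence below 0.5 is invalidated.
#' @param t_end End of the observation span (defaults to the last beat).
#' @return Tibble with `interval_start_s`, `hr_bpm`, `n_ibis`, `valid` and
#'   attribute `aggregation = "interval"`.
#' @export
interval_mean_hr <- function(beats, width = 300, min_ibis = 10,
                             presence = NULL, t_end = NULL) {
  stopifnot(width > 0)
  s1 <- beats$s1_time_s
  if (is.null(t_end)) t_end <- if (length(s1)) max(s1) else width
  n_iv <- max(1L, as.integer(ceiling((t_end - 1e-9) / width)))
  starts <- (seq_len(n_iv) - 1) * width
  ib_start <- s1[-length(s1)]
  ib_end <- s1[-1]
  ibi <- diff(s1)
  out <- purrr::map_dfr(starts, function(t0) {
    sel <- ib_start >= t0 & ib_end < t0 + width   # IBI fully inside
    n <- sum(sel)
    tibble::tibble(
      interval_start_s = t0,
      hr_bpm = if (n > 0) 60 / mean(ibi[sel]) else NA_real_,
      n_ibis = n
    )
  })
  out$valid <- !is.na(out$hr_bpm) & out$n_ibis >= min_ibis
  if (!is.null(presence)) {
    frac <- vapply(out$interval_start_s, function(t0) {
      sel <- presence$window_start_s >= t0 & presence$window_start_s < t0 + width
      if (!any(sel)) return(1)
      mean(presence$present[sel])
    }, numeric(1))
    out$valid <- out$valid & frac >= 0.5
  }
  attr(out, "aggregation") <- "interval"
  attr(out, "width") <- width
  out
}

#' Rolling-mean heart rate over k IBIs
#'
#' Beat-wise HR as used for beat-to-beat validation: at each beat `i >= k`,
#' `HR = 60 / mean(last k IBIs)`, timestamped at that beat.
#'
#' @param beats Beat tibble with `s1_time_s`.
#' @param k Number of IBIs in the rolling window (default 10).
#' @return Tibble with `time_s`, `beat_index`, `hr_bpm`; attribute
#'   `aggregation = "rolling"`. Empty when fewer than `k` IBIs exist.
#' @export
#' @examples
#' rolling_mean_hr(tibble::tibble(s1_time_s = cumsum(rep(0.75, 11))), k = 10)
rolling_mean_hr <- function(beats, k = 10) {
  stopifnot(k >= 1)
  s1 <- beats$s1_time_s
  ibi <- diff(s1)
  if (length(ibi) < k) {
    out <- tibble::tibble(time_s = numeric(), beat_index = integer(), hr_bpm = numeric())
  } else {
    csum <- c(0, cumsum(ibi))
    idx <- seq(k, length(ibi))                   # window of IBIs (idx-k+1)..idx
    mean_ibi <- (csum[idx + 1] - csum[idx - k + 1]) / k
    out <- tibble::tibble(
      time_s = s1[idx + 1],                      # beat closing the window
      beat_index = as.integer(idx + 1),
      hr_bpm = 60 / mean_ibi
    )
  }
  attr(out, "aggregation") <- "rolling"
  attr(out, "k") <- k
  out
}

#' Block-mean heart rate (30 beats or 30 seconds)
#'
#' Non-overlapping block means for long-term trend display: either blocks
#' of `k` consecutive IBIs (`mode = "beats"`) or fixed time blocks of
#' `width` seconds (`mode = "time"`, any number of IBIs fully inside).
#'
#' @param beats Beat tibble with `s1_time_s`.
#' @param k Beats per block (beat mode).
#' @param mode `"beats"` or `"time"`.
#' @param width Block width in seconds (time mode).
#' @param min_ibis Minimum IBIs for a valid time block.
#' @return Tibble with `time_s` (block start), `hr_bpm`, `n_ibis`,
#'   `valid`; attribute `aggregation = "block"`.
#' @export
block_mean_hr <- function(beats, k = 30, mode = c("beats", "time"),
                          width = 30, min_ibis = 1) {
  mode <- match.arg(mode)
  s1 <- beats$s1_time_s
  ibi <- diff(s1)
  if (mode == "beats") {
    nb <- length(ibi) %/% k
    if (nb == 0) {
      out <- tibble::tibble(time_s = numeric(), hr_bpm = numeric(),
                            n_ibis = integer(), valid = logical())
    } else {
      grp <- rep(seq_len(nb), each = k)
      mean_ibi <- tapply(ibi[seq_len(nb * k)], grp, mean)
      out <- tibble::tibble(
        time_s = s1[seq(1, by = k, length.out = nb)],
        hr_bpm = as.numeric(60 / mean_ibi),
        n_ibis = k,
        valid = TRUE
      )
    }
  } else {
    out <- interval_mean_hr(beats, width = width, min_ibis = min_ibis)
    out <- dplyr::rename(out, time_s = "interval_start_s")
  }
  attr(out, "aggregation") <- "block"
  out
}

#' Pair radar and reference HR series on a common clock
#'
#' Interval mode joins series by identical interval start; beat mode pairs
#' every reference beat value with the nearest radar beat value within a
#' tolerance (default half the local reference IBI). Reference points with
#' no radar partner get exclusion reason `missing_radar`; radar values are
#' never fabricated.
#'
#' @param radar,reference HR tibbles from the aggregators above. Interval
#'   mode expects `interval_start_s`; beat mode expects `time_s`.
#' @param mode `"interval"` or `"beat"`.
#' @param tolerance Beat-mode matching tolerance in seconds; `NULL` means
#'   half the local reference inter-value spacing.
#' @return Tibble of class `"paired_hr"`: `time_s`, `hr_radar`, `hr_ref`,
#'   `diff` (radar - reference), `exclusion_reason` (`"none"` for pairs
#'   that enter the statistics).
#' @export
synchronize_pairs <- function(radar, reference, mode = c("interval", "beat"),
                              tolerance = NULL) {
  mode <- match.arg(mode)
  if (mode == "interval") {
    key <- "interval_start_s"
    stopifnot(key %in% names(radar), key %in% names(reference))
    rad <- dplyr::select(radar, time_s = dplyr::all_of(key),
                         hr_radar = "hr_bpm",
                         radar_valid = dplyr::any_of("valid"))
    ref <- dplyr::select(reference, time_s = dplyr::all_of(key),
                         hr_ref = "hr_bpm",
                         ref_valid = dplyr::any_of("valid"))
    out <- dplyr::full_join(ref, rad, by = "time_s")
    if (!"radar_valid" %in% names(out)) out$radar_valid <- TRUE
    if (!"ref_valid" %in% names(out)) out$ref_valid <- TRUE
    out <- out |>
      dplyr::filter(!is.na(.data$hr_ref) & .data$ref_valid) |>
      dplyr::mutate(
        exclusion_reason = dplyr::if_else(
          is.na(.data$hr_radar) | !.data$radar_valid, "missing_radar", "none"),
        diff = .data$hr_radar - .data$hr_ref
      ) |>
      dplyr::select("time_s", "hr_radar", "hr_ref", "diff", "exclusion_reason") |>
      dplyr::arrange(.data$time_s)
  } else {
    stopifnot(nrow(reference) > 0)
    tr <- radar$time_s; tf <- reference$time_s
    if (length(tr) == 0 || max(tr) < min(tf) || min(tr) > max(tf)) {
      warning("radar and reference series do not overlap in time")
      return(structure(tibble::tibble(
        time_s = numeric(), hr_radar = numeric(), hr_ref = numeric(),
        diff = numeric(), exclusion_reason = character(),
        ref_index = integer()), class = c("paired_hr", "tbl_df", "tbl", "data.frame")))
    }
    local_ibi <- c(diff(tf), utils::tail(diff(tf), 1))
    tol <- if (is.null(tolerance)) 0.5 * local_ibi else rep_len(tolerance, length(tf))
    idx <- findInterval(tf, tr)
    near <- vapply(seq_along(tf), function(j) {
      cand <- unique(pmin(pmax(c(idx[j], idx[j] + 1L), 1L), length(tr)))
      d <- abs(tr[cand] - tf[j])
      if (min(d) <= tol[j]) cand[which.min(d)] else NA_integer_
    }, integer(1))
    out <- tibble::tibble(
      time_s = tf,
      hr_radar = ifelse(is.na(near), NA_real_, radar$hr_bpm[near]),
      hr_ref = reference$hr_bpm,
      ref_index = seq_along(tf)
    ) |>
      dplyr::mutate(
        exclusion_reason = dplyr::if_else(is.na(.data$hr_radar), "missing_radar", "none"),
        diff = .data$hr_radar - .data$hr_ref
      ) |>
      dplyr::select("time_s", "hr_radar", "hr_ref", "diff",
                    "exclusion_reason", "ref_index")
  }
  class(out) <- c("paired_hr", class(tibble::tibble()))
  out
}

#' Exclude half/double heart-rate detection failures
#'
#' Low-SNR segmentation can miss every second S1 or insert one between each
#' pair, halving or doubling the estimated HR. A pair is excluded when the
#' radar HR lies within `tol` (relative) of half or double the reference
#' HR. A literal variant -- the *difference* of the rolling means lying
#' within `tol` of half/double the reference -- is available via
#' `mode = "difference"`.
#'
#' @param pairs A `"paired_hr"` tibble.
#' @param tol Relative tolerance (default 0.10).
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return `pairs` with reason `half_double` set on affected rows. Already
#'   excluded rows are untouched (idempotent, one reason per pair).
#' @export
#' @examples
#' p <- synchronize_pairs(
#'   tibble::tibble(interval_start_s = 0, hr_bpm = 41, valid = TRUE),
#'   tibble::tibble(interval_start_s = 0, hr_bpm = 80, valid = TRUE))
#' exclude_half_double(p)$exclusion_reason
exclude_half_double <- function(pairs, tol = 0.10, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  ok <- pairs$exclusion_reason == "none" & !is.na(pairs$hr_radar)
  x <- if (mode == "ratio") pairs$hr_radar else abs(pairs$diff)
  half <- pairs$hr_ref / 2
  dbl <- pairs$hr_ref * 2
  hit <- (abs(x - half) <= tol * half) | (abs(x - dbl) <= tol * dbl)
  pairs$exclusion_reason[ok & hit] <- "half_double"
  pairs
}

#' Apply reference-beat annotations to paired data
#'
#' Beats annotated in the reference record (wrong detection, noisy signal,
#' VES/SVES, other arrhythmia) lose their ground truth, so every rolling
#' HR value whose window contains such a beat is excluded: with a window of
#' `k` IBIs, an annotated beat at index `b` touches the values closed by
#' beats `b .. b+k-1`.
#'
#' @param pairs Beat-mode `"paired_hr"` tibble carrying `ref_index`.
#' @param annotations Tibble with `beat_index` and `label` in
#'   `wrong_detection`, `noisy`, `VES`, `SVES`, `other_arrhythmia`.
#' @param k Rolling-window length used to build the series.
#' @return `pairs` with reasons `arrhythmia_label` (VES/SVES/other) or
#'   `noisy_reference` (wrong detection / noisy) set.
#' @export
apply_annotations <- function(pairs, annotations, k = 10) {
  if (nrow(annotations) == 0) return(pairs)
  stopifnot(all(c("beat_index", "label") %in% names(annotations)),
            "ref_index" %in% names(pairs))
  bad_labels <- c("wrong_detection", "noisy", "VES", "SVES", "other_arrhythmia")
  unknown <- setdiff(annotations$label, bad_labels)
  if (length(unknown)) {
    stop("unknown annotation labels: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  max_idx <- max(pairs$ref_index)
  oob <- annotations$beat_index < 1 | annotations$beat_index > max_idx
  if (any(oob)) {
    stop("annotation rows reference beats outside the record: rows ",
         paste(which(oob), collapse = ", "), call. = FALSE)
  }
  arr <- annotations$label %in% c("VES", "SVES", "other_arrhythmia")
  touched <- function(b) unique(unlist(lapply(b, function(j) j:(j + k - 1L))))
  ok <- pairs$exclusion_reason == "none"
  if (any(arr)) {
    hit <- pairs$ref_index %in% touched(annotations$beat_index[arr])
    pairs$exclusion_reason[ok & hit] <- "arrhythmia_label"
    ok <- pairs$exclusion_reason == "none"
  }
  if (any(!arr)) {
    hit <- pairs$ref_index %in% touched(annotations$beat_index[!arr])
    pairs$exclusion_reason[ok & hit] <- "noisy_reference"
  }
  pairs
}

#' Arrhythmia burden and whole-patient exclusion
#'
#' Each ectopic beat perturbs the two IBIs adjacent to it, so the affected
#' fraction is roughly twice the ectopic fraction. Patients whose affected
#' fraction exceeds the threshold are excluded wholesale, since the
#' segmentation model is not designed for arrhythmic rhythms.
#'
#' @param annotations Annotation tibble (see [apply_annotations()]).
#' @param n_beats Total recorded beats for the patient.
#' @param threshold Affected-beat fraction above which the patient is
#'   excluded (default 0.20).
#' @return List: `n_annotated`, `n_affected` (annotated beats x 2, capped),
#'   `fraction_affected`, `exclude_patient`.
#' @export
arrhythmia_burden <- function(annotations, n_beats, threshold = 0.20) {
  arr <- annotations$label %in% c("VES", "SVES", "other_arrhythmia")
  n_ann <- sum(arr)
  n_aff <- min(2L * n_ann, n_beats)
  frac <- n_aff / n_beats
  list(n_annotated = n_ann, n_affected = n_aff,
       fraction_affected = frac, exclude_patient = frac > threshold)
}

#' Global outlier filter: physiologically impossible heart rates
#'
#' Invalidates HR values outside a fixed physiological envelope.
#'
#' @param hr HR tibble with `hr_bpm` (and optionally `valid`).
#' @param lo,hi Bounds in bpm (defaults 25 and 220).
#' @return The tibble with `valid` updated (idempotent).
#' @export
global_outlier_filter <- function(hr, lo = 25, hi = 220) {
  if (lo >= hi) stop("`lo` must be below `hi`", call. = FALSE)
  if (!"valid" %in% names(hr)) hr$valid <- !is.na(hr$hr_bpm)
  hr$valid <- hr$valid & !is.na(hr$hr_bpm) & hr$hr_bpm >= lo & hr$hr_bpm <= hi
  hr
}

#' Local outlier filter: iterative segment-wise robust screening
#'
#' Scans the valid HR values in consecutive segments of `segment` values
#' and removes points farther than `k` robust SDs (`1.4826 * MAD`) from the
#' segment median, repeating until a pass removes nothing or `max_iter`
#' passes have run. Deterministic. The removal threshold never drops below
#' `mad_floor` bpm: in a near-constant segment (MAD close to or exactly
#' zero) only points more than `mad_floor` from the median are outliers --
#' small physiological fluctuation is never "inconsistent". Slow genuine
#' trends (a 10 bpm change over tens of minutes) move the segment median
#' with them and are preserved.
#'
#' @param hr HR tibble with `hr_bpm` (and optionally `valid`).
#' @param segment Segment length in values (>= 5).
#' @param k Robust-SD multiplier.
#' @param max_iter Maximum passes.
#' @param mad_floor Absolute floor (bpm) used when MAD is zero.
#' @return The tibble with `valid` updated (idempotent once converged).
#' @export
local_outlier_filter <- function(hr, segment = 60, k = 3.0, max_iter = 10,
                                 mad_floor = 5) {
  stopifnot(segment >= 5)
  if (!"valid" %in% names(hr)) hr$valid <- !is.na(hr$hr_bpm)
  for (iter in seq_len(max_iter)) {
    idx <- which(hr$valid)
    if (length(idx) == 0) break
    grp <- ceiling(seq_along(idx) / segment)
    removed <- FALSE
    for (g in unique(grp)) {
      ii <- idx[grp == g]
      x <- hr$hr_bpm[ii]
      med <- stats::median(x)
      s <- stats::mad(x)            # 1.4826 * median absolute deviation
      bad <- abs(x - med) > max(k * s, mad_floor)
      if (any(bad)) {
        hr$valid[ii[bad]] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }
  hr
}

#' Tally exclusion reasons in a paired series
#'
#' @param pairs A `"paired_hr"` tibble.
#' @return Tibble with `exclusion_reason`, `n`, `fraction` (of all pairs);
#'   reasons are mutually exclusive so the counts are additive.
#' @export
exclusion_summary <- function(pairs) {
  pairs |>
    dplyr::count(.data$exclusion_reason, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::arrange(dplyr::desc(.data$n))
}
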