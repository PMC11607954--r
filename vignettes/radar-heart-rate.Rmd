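---
title: "Radar-based heart-rate estimation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radar-based heart-rate estimation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(radarhr)
```

## The measurement problem

A continuous-wave radar mounted under a bed illuminates the chest with a
24-GHz carrier (wavelength $\lambda \approx 12.49$ mm). The reflected wave
interferes with the transmitted one, and the complex baseband (I/Q) signal
encodes the chest-surface distance $d(t)$ through its phase:

$$ s(t) = A\,e^{i\,4\pi d(t)/\lambda} + c + n(t), $$

with $c$ an unknown receiver DC offset and $n(t)$ circular Gaussian noise.
Valve closures (the first and second heart sounds, S1 and S2) vibrate the
chest surface by tens of micrometres in the 16--80 Hz band; respiration
moves it by millimetres below 1 Hz. Estimating heart rate therefore means:
demodulate phase to displacement, isolate the heart-sound band, find S1
events, and average the interbeat intervals (IBIs, consecutive S1-to-S1
times) into heart-rate (HR) series that can be compared against an ECG
reference.

`radarhr` implements this chain end to end, plus the agreement statistics
used to validate it, and a synthetic radar-bed generator with known ground
truth so that every stage is testable without clinical recordings.

## The synthetic generator: what it emulates

`sim_config()` + `simulate_recording()` produce multi-channel I/Q with
ground truth. The generative model, stage by stage:

* **Heart rate trajectory.** On a 1-s grid, $HR(t) = \text{base\_hr} +
  \text{drift}(t) + \varepsilon(t)$, where the drift is AR(1) with
  coefficient 0.99 and stationary SD `hrv_sd / 2` (a slow wander
  subordinate to beat-to-beat variability) and $\varepsilon$ is white with
  SD `hrv_sd`, clipped to 30--200 bpm. IBIs are $60/HR(t)$ at the running
  beat time.
* **Heart sounds.** Each beat contributes an S1 and an S2 Gabor wavelet
  (40 Hz centre frequency, $\sigma \approx 16.7$ ms, so roughly 100 ms of
  support -- squarely inside the 16--80 Hz analysis band), with S2 at 0.33
  of the local IBI after S1 and roughly half its amplitude. Defaults:
  30 µm / 15 µm peak. Channels see the same events through gains
  1.0/0.9/0.8/0.7, emulating the different geometry of four adjacent
  radar units.
* **Ectopic beats.** A beat drawn as VES (ventricular extrasystole)
  arrives ~40% early and is followed by a compensatory pause; SVES arrive
  ~20% early. Each ectopic therefore perturbs *two* adjacent IBIs, so an
  ectopic fraction $p$ yields an affected-beat fraction of about $2p$ --
  the quantity `arrhythmia_burden()` reports and the basis of whole-patient
  exclusion above 20%.
* **Noise.** `channel_snr` is the in-band (16--80 Hz) power ratio of the
  heart-sound displacement to the demodulated noise floor. This is the
  quantity the signal quality index (SQI) estimates downstream. It is
  deliberately *not* the carrier-to-noise ratio: at 24 GHz one radian of
  phase is about a millimetre of displacement, so any carrier-referenced
  noise figure loose enough to be interesting would bury a 30-µm wavelet
  entirely.
* **Artifacts, absence, reference.** Motion artifacts are 2--8 mm smooth
  bumps at a configurable hourly rate; absence intervals zero the
  displacement; the reference channel is the true beat sequence plus
  Gaussian timing jitter (nominal 1000 Hz resolution, emulating a
  beat-synchronized ECG).

All randomness flows from one integer seed through per-purpose derived
seeds, so identical configurations give bit-identical recordings.

**What the generator does not emulate:** posture changes and large
voluntary movements (its artifacts are smooth bumps, not broadband
clutter), morphological S1/S2 variability (murmurs, splitting, inotropy
changes), multipath and antenna patterns, and more than one subject. Tests
passing on this generator show the *pipeline logic* is correct under the
stated signal model; they do not certify performance on clinical
recordings.

## Signal processing choices

* **Demodulation.** The DC offset is estimated by an algebraic
  least-squares circle fit (Kåsa normal equations) -- closed-form and
  deterministic -- then the centred phase is unwrapped and scaled by
  $\lambda/4\pi$. A degenerate (zero-radius) I/Q cloud yields a flagged
  all-zero displacement rather than an error, so one dead channel cannot
  abort a multi-channel run.
* **Heart-sound band.** Butterworth band-pass 16--80 Hz, order 4, applied
  forward and backward (`signal::filtfilt`): zero phase, so S1/S2 timing
  is not skewed by group delay. The filter is applied to displacement
  (not raw phase); at these amplitudes the two differ only by the
  $\lambda/4\pi$ scale.
* **Presence.** Per 1-s window, received-power variance is compared with
  the window's own receiver-noise floor, estimated from first differences
  of the I/Q samples (body motion is slow relative to the sampling rate).
  Presence requires a 10 dB margin. A fixed data-derived quantile was
  rejected as baseline because an overnight recording in which the subject
  never leaves bed has no empty-bed windows to anchor it.
* **SQI.** Per half-open window $[t, t+W)$:
  $10\log_{10}(P_{16-80} / P_{noise})$, with the noise floor taken from
  100 Hz--Nyquist and rescaled to the 64-Hz passband width. White noise
  scores 0 dB by construction; the index is monotone in the generator's
  true SNR. It must be computed on the *unfiltered* displacement -- after
  band-passing there is no spectrum left above 100 Hz to estimate noise
  from.

## The segmentation model

Heart sounds are segmented with a four-state hidden semi-Markov model over
the fixed cardiac cycle S1 → systole → S2 → diastole, decoded by
duration-dependent Viterbi (compiled, `src/viterbi_hsmm.cpp`). Features
are the homomorphic and analytic-signal envelopes of the heart-sound band,
resampled to 50 Hz and z-scored -- the classic phonocardiogram front-end.

No training data exist for this setting, so the model is a fixed
parameterization anchored on a coarse HR estimate (autocorrelation peak of
the homomorphic envelope between 0.33 and 2 s; fallback 75 bpm flagged
low-confidence when no peak exceeds 0.2):

| state | duration mean | duration SD |
|---|---|---|
| S1 | 120 ms | 25 ms |
| systole | $0.33\,T - 120$ ms | 10% of mean (floor 25 ms) |
| S2 | 90 ms | 25 ms |
| diastole | remainder of $T$ | 12% of mean (floor 35 ms) |

with $T = 60/\text{coarse HR}$, duration caps at mean + 3 SD, and Gaussian
emissions whose means are high for the sound states (S1 higher than S2)
and low for the interval states. These are configuration, not fitted
parameters; arrhythmic rhythms violate the duration anchoring, which is
why annotated extrasystoles are excluded downstream rather than modelled.

Channel selection follows the study design: the channel with the highest
SQI per window (60 s for overnight interval analysis, 3 s for beat-wise
analysis, 30 s for long-term monitoring), ties to the lowest index.
Decoding always runs on windows of at least 60 s (with 2 s of context on
each side): a 3-s stretch cannot hold enough cardiac cycles for a
duration-anchored decode, so short selection windows only decide *whose*
beats are kept, not how they are found.

## HR aggregation and exclusion rules

Three aggregations mirror the three validation settings: 5-minute
interval means ($60/\overline{IBI}$ over IBIs fully inside the half-open
interval; a mean of intervals, not of instantaneous rates), rolling means
over 10 IBIs timestamped at the closing beat, and non-overlapping 30-beat
(or 30-second) blocks. An interval needs at least 10 IBIs and a present
subject to be valid; 10 is a guard against single-beat intervals, chosen
here since no minimum is inherited from the study design.

Exclusion rules, each idempotent and each stamping exactly one reason per
pair:

* **missing_radar** -- reference values with no radar partner (interval
  join, or no beat within half a local IBI in beat mode).
* **half_double** -- the radar HR lies within 10% (relative) of half or
  double the reference HR, the signature of missed or inserted S1s under
  low SNR. The implemented reading is radar-HR *proximity to* half/double
  of the reference; a literal reading (the rolling-mean *difference*
  lying near half/double) is available via `mode = "difference"`. The
  proximity reading was chosen because it matches the failure mode the
  rule exists to catch.
* **arrhythmia_label / noisy_reference** -- annotated beats poison every
  rolling window that contains them (beat $b$ touches windows closed by
  beats $b$ to $b+k-1$). Patients whose affected-beat fraction exceeds
  20% are excluded wholesale -- the threshold matching the smallest
  wholesale exclusion practised in the validation study design.
* **Global outliers** -- HR outside 25--220 bpm (a generous physiological
  envelope; configurable).
* **Local outliers** -- per segment of 60 values, points farther from the
  segment median than $\max(3 \times 1.4826\,\mathrm{MAD},\ 5\ \text{bpm})$
  are removed, iterated to a fixpoint (at most 10 passes). The 5-bpm floor
  keeps ordinary physiological fluctuation untouchable in quiet segments
  where the MAD collapses; genuine trends (a 10-bpm medication response
  over tens of minutes) move the median with them and survive.

## Agreement statistics and planning

`bland_altman()` reports the mean difference, its sample SD (n − 1
denominator throughout), limits of agreement mean ± 1.96 SD, and the
fractions within ±5 bpm and within the limits. The companion plot is the
*modified* variant: reference HR on x, difference on y. `tost_paired()` /
`tost_from_summary()` implement Schuirmann's two one-sided tests against
±5 bpm with plain Student-t one-sided p-values (no correction), the
90% CI, and Hedges $g(z) = (\bar d / s_d)(1 - 3/(4\,df - 1))$ with the
bounds mapped onto the standardized scale. Equivalence is declared iff
both one-sided tests reject at $\alpha = 0.05$, equivalently iff the 90%
CI sits strictly inside the bounds -- an identity enforced by a property
test. Differences are computed as radar − reference and reported signed.

Planning functions reproduce both a-priori calculations:
`sample_size_loa()` solves $z_{0.975}\,\sigma\sqrt{3/n} \le$ halfwidth in
closed form; `sample_size_tost()` iterates even total sizes of a
parallel-group additive-scale design upward from a normal-approximation
start until the exact noncentral-t TOST power reaches the target. The
parallel-group design is a deliberate reconstruction: a crossover design
cannot produce the planned 28 patients from the stated inputs, while the
parallel additive design does so exactly.

```{r planning}
sample_size_loa(sd = 4, ci_halfwidth = 2.5)
sample_size_tost(sd = 4, bounds = c(-5, 5), theta0 = 1)
```

## A worked small-scale run

```{r run, fig.alt = "Modified Bland-Altman plot of a synthetic run"}
cfg <- sim_config(duration = 900, n_channels = 2, sampling_rate = 500,
                  base_hr = 75, hrv_sd = 2, channel_snr = c(25, 12),
                  artifact_rate = 4, seed = 23)
run <- run_pipeline(cfg, arm = "I", jitter_sd_ms = 5)
run$pairs
if (!is.null(run$bland_altman)) autoplot(run$bland_altman)
```

## Problem sizes and numerical choices

Simulated validation runs in this package use a 500 Hz baseband rate
(default 2000 Hz; anything above the 200 Hz floor represents the 16--80 Hz
band faithfully, and 500 Hz keeps hours-long four-channel runs light).
The package's own acceptance checks use an 8-hour, four-channel overnight
scenario with per-channel SNRs spanning 10--30 dB and 5 ms reference
jitter; shorter seeded scenarios cover each stage in isolation. Other
numerical choices: half-open windows everywhere, seconds from recording
start as the time base, ties in channel selection to the lowest index,
duration caps at mean + 3 SD in the decoder, and a −Inf SQI sentinel
(flagged invalid) for all-zero windows.

## Known limitations

The segmentation model is untrained and rigidly duration-anchored:
abrupt rate changes and arrhythmias degrade it (hence the annotation-driven
exclusions). The SQI is a pure SNR measure; a channel can be loud and
wrong. The generator's idealizations listed above mean that agreement
figures obtained here bound what the logic can do, not what hardware in a
ward achieves. Calibration of radar amplitude to absolute micrometres is
out of scope: the pipeline works in physical units end to end and never
needs the absolute scale.
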