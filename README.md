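# radarhr

Contactless heart-rate monitoring for settings where electrodes are a
burden — a palliative-care ward being the motivating case: continuous-wave
radar units under the bed frame record micrometre-scale chest-surface
vibration through mattress and bedding, and heart rate is estimated from
the first heart sound (S1) without touching the patient. `radarhr`
implements the complete estimation chain and the statistical machinery
needed to validate such a system against an ECG reference, plus a seeded
synthetic radar-bed generator so every stage runs and is tested without
any clinical recordings.

The chain, in the field's standard notation:

* **Interferometric demodulation.** Baseband I/Q encodes chest distance
  via `s(t) = A·exp(i·4π·d(t)/λ) + c + n(t)` (λ ≈ 12.49 mm at 24 GHz). A
  least-squares circle fit removes the DC offset `c`; unwrapped phase times
  λ/4π gives displacement.
* **Heart-sound band.** Zero-phase Butterworth band-pass, 16–80 Hz, where
  S1/S2 valve vibration lives and respiration does not.
* **Channel selection.** Per window (60 / 30 / 3 s depending on the
  analysis), the radar unit with the highest signal quality index
  (SQI = in-band-to-noise-floor power ratio, dB) supplies the beats.
* **Segmentation.** A four-state hidden semi-Markov model
  (S1 → systole → S2 → diastole) with explicit Gaussian state durations
  anchored on a coarse autocorrelation HR estimate, decoded by
  duration-dependent Viterbi (compiled core).
* **HR series.** IBI = time between consecutive S1; aggregated as
  5-minute interval means, rolling 10-IBI means, or 30-beat blocks; then
  exclusion rules (missing radar, half/double detection failures,
  annotated arrhythmia/noise, global 25–220 bpm and local robust-MAD
  outliers).
* **Agreement analysis.** Modified Bland–Altman (difference vs reference,
  limits of agreement mean ± 1.96 σ), OLS of radar on reference,
  Schuirmann two one-sided tests (TOST) against ±5 bpm with Hedges g(z),
  and a-priori sample-size planning for both the limits-of-agreement
  precision criterion and the TOST power criterion.

## A worked example

Simulate a 15-minute, two-channel overnight-style recording and run the
full chain against the jittered reference channel:

```r
library(radarhr)

cfg <- sim_config(duration = 900, n_channels = 2, sampling_rate = 500,
                  base_hr = 75, hrv_sd = 2, channel_snr = c(25, 12),
                  artifact_rate = 4, seed = 23)
run <- run_pipeline(cfg, arm = "I", jitter_sd_ms = 5)
run
#> <radar_hr_run> arm I, 0.2 h, 2 channels, seed 23
#>   1136 detected beats, 3 paired values (3 analysed)
#> Modified Bland-Altman analysis
#>   n = 3 pairs
#>   mean difference 0.027 bpm, SD 0.096 bpm
#>   limits of agreement [-0.16, 0.22] bpm (mean +/- 1.96 SD)
#>   100.00% within +/-5 bpm, 100.00% within the limits of agreement
#> Two one-sided equivalence test (paired)
#>   n = 3, bounds [-5, 5] bpm, alpha = 0.05
#>   estimate 0.027 bpm, 90% CI [-0.135, 0.189]
#>   ...
#>   equivalent: TRUE
```

The 1136 detected beats collapse into three valid 5-minute intervals;
radar HR tracks the reference within a tenth of a bpm on this clean
synthetic scene, every interval falls inside the ±5 bpm clinical band,
and the 90% CI of the mean difference sits far inside the ±5 bpm
equivalence bounds. `tidy()` / `glance()` give the same numbers as one-row
tibbles, `autoplot(run$bland_altman)` draws the modified Bland–Altman
plot, and `write_run(run, dir)` exports beats, paired HRs and a
full-precision JSON report.

Planning a validation study from pilot figures (difference SD 4 bpm):

```r
sample_size_loa(sd = 4, ci_halfwidth = 2.5)
#> A priori sample size (limits-of-agreement precision): n = 30 patients
sample_size_tost(sd = 4, bounds = c(-5, 5), theta0 = 1)
#> A priori sample size (TOST equivalence (parallel groups)): n = 28 patients
#>   achieved power 0.811
```

See `vignettes/radar-heart-rate.Rmd` for the generative model, the HSMM
parameterization, every exclusion rule, and the package's design
decisions and limitations.

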