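---
title: "Brain-state, oscillation and spike-train analysis for medial septal neurons"
author: "septorhythm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state, oscillation and spike-train analysis for medial septal neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septorhythm)
```

## The scientific problem

The medial septum and diagonal band (MSDB) pace hippocampal and
entorhinal theta oscillations. Among its GABAergic projection neurons,
*orchid cells* target the entorhinal cortex and presubiculum and fire
long, accommodating bursts of spikes near the **peak** of dorsal CA1
theta, during locomotion and immobility alike; *Teevra cells*, by
contrast, fire short bursts at the theta **trough** and target CA3. The
analyses in this package quantify a unit's place in that scheme from
three raw ingredients: a reference LFP, the unit's spike times, and the
animal's behavior on a treadmill.

The pipeline runs: behavior segmentation → oscillation/event detection →
per-state burst and rate metrics → circular phase coupling → SWR
modulation → four-criterion classification → group statistics.

## Conventions and units

All times are seconds internally (64-bit doubles); burst durations and
interburst intervals are reported in milliseconds only at the metric
level, matching how such values are conventionally tabulated. Phase is in
degrees with the trough-origin convention — 0° and 360° are the troughs
of the band-passed reference oscillation, so 180° is the peak of a
symmetric cycle. Unavailable values are `NA` throughout, never 0.

The interquartile range of burst timing metrics uses midpoint quantiles
(`quantile(..., type = 5)`, the MATLAB convention). This choice is
deliberate: aggregating the 16 reference cells' per-cell medians with
this convention reproduces the published group IQRs for all group sizes
(even and odd), where hinge-based conventions do not for odd n.

## Parameters

`analysisConfig()` exposes every constant. The defaults are the values
the analyses were designed around:

| parameter | default | meaning |
|---|---|---|
| `thetaBand`, `deltaBand` | 5–12, 2–4 Hz | theta-period detection ratio |
| `midGammaBand` | 55–80 Hz | entorhinal-origin mid-gamma |
| `rippleBand` | 130–230 Hz | sharp-wave ripples |
| `isiMax`, `minBurstSpikes` | 40 ms, 4 | burst rule: >3 spikes, ISIs < 40 ms |
| `gammaAmpSdThreshold` | 1 s.d. | cycle amplitude > mean + 1 s.d. |
| `ripplePowerSdThreshold` | 4 s.d. | ripple power > mean + 4 s.d. |
| `liaSmoothWindow`, `liaDcWindow`, `liaMinInterval` | 0.08, 0.2, 0.2 s | LIA crossing detection |
| `rateWindow` | 1 s | rate and burst-incidence windows |
| `minSwrCount` | 20 | SWR-test eligibility |
| `nShuffles`, `nPermutations` | 1000, 10000 | Monte Carlo sizes |
| `speedCalibration` | 0.6912 m/s per V | analogue speed channel |
| `encoderEdgesPerRev`, `wheelDiameter` | 2000, 0.146 m | wheel geometry |
| `speedInterval` | 10 ms | speed sampling step |
| `peakPhaseWindow` | 90–270° | "around the theta peak" |

Two parameters are the package's own choices where the source analyses
were qualitative. First, locomotion is defined as a movement-flag period
longer than 1 s with mean speed above 1 cm/s (`lmSpeedThreshold`,
`lmMinDuration`); the published state scoring was video-assisted, and a
numeric rule is required for reproducibility. Second, criterion 4's
"around the peak" window defaults to 90–270°, deliberately wide because
identified orchid cells span preferred phases from 130° to 264°.

The burst rule reads "a train of >3 spikes" literally as ≥4 spikes
(`minBurstSpikes = 4`, configurable to 3; the literature is split).
Intraburst frequency is `(n_spikes − 1) / duration` per burst, averaged
over bursts — the quantity is tabulated in the field without a printed
formula, and this definition reproduces the tabulated 75–150 Hz range.

## Filtering and detection numerics

All band-pass filtering is zero-phase forward–backward Butterworth
(order 4 for theta/delta/gamma, order 6 for ripples). Two numerical
safeguards matter:

* **Decimation for narrow low bands.** A 2–4 Hz order-4 IIR at 1 kHz is
  numerically unstable (normalized corner frequencies of 0.004). Bands
  whose upper edge is far below the sampling rate are therefore filtered
  on a decimated copy (moving average + subsample to ~20× the band's
  upper edge) and splined back onto the original grid. Trough times on
  noiseless sinusoids remain within one sample of the analytic times
  (tested).
* **Reflection padding.** Traces are padded with odd-symmetric
  reflections sized by the filter ring-down (~10/bandwidth) before
  `filtfilt`, so detections are invariant to constant offsets and free
  of start/end transients.

Detector definitions where the conventions had to be fixed: gamma "cycle
amplitude" is the peak-to-trough difference per trough-to-trough cycle
(cycles within 50 ms of a trace edge are excluded from both the
statistics and the detections; amplitude variation below a coefficient
of variation of 1e-4 is treated as constant amplitude, so the strict
"> mean + 1 s.d." rule cannot fire on numerical noise). SWR "power" is
the squared analytic-signal (Hilbert) envelope of the band-passed trace
smoothed over 10 ms, windows extend from the threshold crossing out to
where power falls back to the mean, and the event time is the power
maximum. Theta periods use a theta/delta band-power ratio in 1 s sliding
windows (step 1/4 window) with threshold 2.0 and a 0.5 s morphological
closing; troughs are local minima of the band-passed trace separated by
at least half the band's shortest period.

The SWR modulation test is two-sided by doubling the smaller Poisson
tail (capped at 1); both the closed-form Poisson p and the
1000-surrogate shuffle p (same-duration windows re-placed uniformly in
non-theta, non-SWR time) are reported, since the provenance of tabulated
"Poisson p-values" is ambiguous between the two. Sign-test ties are
dropped before setting n; the circular permutation test uses the
(b+1)/(m+1) estimator.

## The synthetic-session generator

`sessionSpec()` encodes the study conditions; `generateSession()` builds
an LFP, a spike train and behavior channels from one seed, with exact
ground truth. The generator emulates:

* state-dependent theta (8 Hz at unit amplitude during LM, 7 Hz at 0.7
  during SM, absent during WS/IM), with the oscillator phase advancing
  continuously so troughs are exact by construction;
* a 3 Hz delta sinusoid plus band-limited (0.5–4.5 Hz) irregular
  activity outside theta states — LIA ground truth is the detector's own
  definition applied to the noiseless slow component;
* a 65 Hz gamma carrier whose envelope is modulated by theta phase with
  a sharpened raised-cosine bump at 180° (the theta peak) and depth 4;
  true gamma events are the carrier troughs whose noiseless cycle
  amplitude exceeds the mean by 1 s.d.;
* 160 Hz, 60 ms ripple events at 0.25 events/s confined to immobility;
* 1/f background noise (amplitude 0.05 of theta), the spectral shape
  chosen because no noise spectrum is published;
* a two-level spike model: per rhythm cycle (true theta cycles in theta
  states, an internal 6.5 Hz rhythm otherwise) a burst is emitted with
  the probability that matches the per-state target rate (55/45/40/40 Hz
  for LM/SM/WS/IM); each burst's center of mass is placed at a von
  Mises(178°, κ = 4) phase, contains Poisson(≈7) spikes, and its ISIs
  start at 1/115 s and grow by 8% per spike (cumulative-maximum
  enforced), giving accommodating 60–120 ms bursts at 75–150 Hz
  intraburst frequency and >3 Hz incidence;
* wheel-encoder counts at ~15 cm/s during LM, sub-second tick pulses
  during SM, and a whisking flag during WS.

A real recording differs from this in ways the tests cannot probe:
electrode drift and unit instability, theta frequency/amplitude
modulation within a state, gamma bursts of entorhinal origin with
variable frequency, EMG and movement artifacts, and spike-sorting
contamination. Passing the recovery tests therefore demonstrates the
correctness of the implementations under the assumed statistical
structure, not robustness to every artifact of real data.

One published observation — bursts occasionally spanning two consecutive
theta cycles — has no published rate; the generator exposes
`cycleSkipProb` (default 0) for it.

With accommodation active, the circular mean of spike phases sits a few
degrees below the burst-placement μ (early spikes are denser), an effect
real accommodating bursts share; parameter-recovery tests therefore
isolate phase with `accommodationDecay = 0`.

## Reference table and classification

`referenceCellMetrics()` ships the published per-cell summary metrics of
8 identified orchid cells, 8 putative orchid cells and 2 septo-
hippocampal cells, with `NA` for unavailable entries and censored
p-values stored at their printed bound (1e-4). Aggregating this table
(`referenceGroupStatistics()`) reproduces the published group
statistics: LM interburst median 157.8 (IQR 42.7) ms vs IM 198.1 (69.7)
ms with all 16 cells shortening their interburst interval during
locomotion; SM vs IM p = 0.0352 and WS vs IM p = 0.5811 (sign tests);
unchanged group burst duration (78.5 vs 82.8 ms, p = 0.2101); firing
rate increases LM over IM in both identified (55.2 vs 39.8 Hz, t₇ ≈
3.9) and putative (61.7 vs 43.4 Hz) groups; and a higher intraburst
frequency during locomotion (109.7 vs 94.8 Hz, t₁₅ = 3.14). These are
recomputed — not stored — by `scripts/acceptance.R` and the test suite.

`classifyOrchid()` returns TRUE for all 8 identified cells and FALSE for
both septo-hippocampal cells. Two putative-cell caveats are inherent to
the printed data: one putative cell's printed LM rate is below its IM
rate, so criterion 3 fails on printed values, and another's immobility
burst incidence is unavailable in the source table, giving an `NA`
verdict (missing data never produce FALSE).

Not reproducible from printed values, and deliberately not asserted
anywhere: the group circular means (178.6° identified, 37.5° Teevra) —
no stated pooling of the per-cell phases recovers them exactly — and the
permutation p = 0.0388 against Teevra cells, whose per-cell phases are
not printed.

## Problem sizes

The test suite and acceptance script use 120–300 s synthetic sessions at
1 kHz, 10,000 random trains for the burst-detector oracle, 10,000
uniform samples for the Rayleigh size check, 100,000-draw Monte Carlo
nulls for the Rayleigh approximation, and 2,000 null simulations for the
SWR test calibration — sizes chosen so each property is measured with
comfortable statistical resolution while the whole suite runs in about
two minutes on one core.

## Known limitations

* State segmentation without a whisking channel cannot produce WS
  epochs; those periods fall into IM, as in recordings scored without
  video.
* The gamma-coupling gate (correlogram/phase test of gamma troughs
  against the theta peak, ±45°) formalizes a qualitative published
  criterion; borderline cells near the gate boundary are refused rather
  than estimated.
* The Rayleigh test assumes independent phase samples; for strongly
  rhythmic event series (e.g. trough trains of narrowband noise) its
  effective sample size is smaller than n and p-values are mildly
  anti-conservative on short traces.
* `detectThetaEpochs` labels whole 1 s windows; theta-onset timing is
  therefore quantized at the window step (250 ms).
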