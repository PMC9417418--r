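---
title: "Methods: sleep EEG features and ocular-dominance plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep EEG features and ocular-dominance plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepod)
```

## The problem

Short-term monocular deprivation (MD) in adult humans paradoxically
*boosts* the deprived eye: a homeostatic gain adjustment, measurable as a
shift in binocular-rivalry dominance durations. sleepod implements the
computational chain linking that plasticity measure to NREM sleep
electrophysiology: the deprivation index from rivalry timelines; detection
and characterization of sleep slow oscillations (SSOs) and sleep spindles
in multichannel EEG; slow-wave-activity and sigma band power; sleep
macrostructure; and region-of-interest (ROI) change-score statistics with
false-discovery-rate control. A seeded synthetic-data module generates
ground-truthed inputs so every stage is testable without any recordings.

## Deprivation index

For each measurement the mean phase duration (MPD, seconds) of each eye's
percept is the arithmetic mean of that percept's phase durations, pooled
across the blocks of the timepoint. The deprivation index is the ratio of
ratios

$$\mathrm{DI} = \frac{\mathrm{MPD}^{base}_{dep}}{\mathrm{MPD}^{post}_{dep}}
  \cdot \frac{\mathrm{MPD}^{post}_{ndep}}{\mathrm{MPD}^{base}_{ndep}},$$

so DI = 1 means no change in the eyes' relative dominance and DI < 1 a
relative boost of the deprived eye. Two conventions are deliberate:

* **Censoring.** A phase truncated by the block end has unknown duration;
  it is excluded from the MPD (it still counts toward total dominance
  time). Including it would bias MPDs downward.
* **Mixed percepts** are tallied separately and never enter eye MPDs.
* **Pooling.** Durations are pooled across a timepoint's blocks before
  averaging (not a mean of per-block means); with two 3-minute blocks per
  timepoint the difference is small, but pooling weights phases equally.

DI is invariant to rescaling all durations and maps to its reciprocal
when baseline and post-deprivation are swapped; both properties are
tested. A DI of exactly 1 (not 0) is the no-change point; the functions
treat statements of "no change" accordingly and test DIs against 1.

## Slow-oscillation detection

Detection operates on a slow-band conditioned copy of each channel
(zero-phase Butterworth band-pass, default 0.1–6 Hz): zero crossings of a
broadband 500 Hz trace would be noise-dominated and the criteria below are
meaningful only for the slow component. On the conditioned signal every
consecutive pair of a negative-going and a positive-going zero crossing is
enumerated; a wave is **full-fledged** when

1. the two crossings are separated by 0.3–1.0 s,
2. the negative peak between them is at or below −80 µV,
3. the negative-to-positive peak amplitude is at least 140 µV.

Zero crossings are sign changes through 0 µV of the referenced voltage —
no local baseline re-estimation — because the criteria are stated in
absolute microvolts. The positive peak is searched from the second
crossing to the next negative-going crossing. `slope+` is the magnitude of
the negative peak divided by the time from that peak to the second zero
crossing (µV/s), the recovery-steepness convention; a maximum-derivative
variant is selectable. Landmarks are reported at sample resolution.

**Clustering.** Full-fledged waves across channels whose negative peaks
chain within 200 ms of each other form one multi-channel event. Channels
without a full-fledged member are *completed* by their closest
timing-valid wave (crossing separation 0.3–1.0 s) whose negative peak lies
within 200 ms of the event reference (the earliest member peak) and whose
amplitudes clear relaxed floors (negative peak ≤ −30 µV, peak-to-peak
≥ 50 µV; both configurable and reported). Chained linkage is the
permissive reading of "delay between negative wave peaks"; singleton
full-fledged waves remain events, so K-complex-like isolated waves are
retained.

Per channel the feature set reports waves/minute of artifact-free NREM
(both all-member and full-fledged-only rates, since either reading of
"detection rate" is defensible), mean peak-to-peak amplitude, mean slope+,
and the sigma-band (9–15 Hz) power in the 1 s window ending at each wave's
first zero crossing — the pre-SSO sigma precursor. The window anchor is
the wave onset (configurable to the negative peak): "preceding the SSO"
most naturally precedes the wave's start. Waves with less than 1 s of
preceding signal are skipped and counted.

## Spindle detection

All NREM signal is band-passed 12–16 Hz with a zero-phase Chebyshev II
design (order 5, stopband edges 11/17 Hz); the measured forward–backward
response is ≥ 30 dB down at 11 and 17 Hz with a passband flat to well
under 1 dB at 14 Hz, comfortably meeting the stated −20 dB specification.
Upper and lower envelopes are built by shape-preserving monotone-Hermite
interpolation through the filtered signal's local maxima and minima
(extrema interpolation rather than rectification or analytic-signal
magnitude, matching envelopes "derived" from the signal; the analytic
alternative is a one-line swap in `amplitude_signal()`), and the
**amplitude signal** is their point-by-point distance.

For each NREM period (≥ 30 s) the mean of the amplitude signal plus twice
its standard deviation is computed; the channel threshold θ is the
period-length-weighted average of these values. Events are fluctuations of
the amplitude signal exceeding **2 × θ**, merged across gaps < 0.25 s and
kept at durations of 0.3–3.0 s. The literal composition — a ×2 multiplier
on top of a mean + 2 SD threshold — is unusually strict, and it is
genuinely ambiguous whether the factor duplicates the +2 SD step; the
multiplier is therefore a parameter (default 2) and
`spindle_sensitivity()` reports event counts at multipliers 1, 1.5, and 2
so the choice is auditable. Per-event sigma power is the mean per-bin dB
power in 12–16 Hz over the event interval; channel metrics are density
(events/min of artifact-free NREM) and mean event power.

## Band power and macrostructure

Artifact-free N2/N3 intervals (stage runs minus masked intervals, via
exact interval arithmetic on a millisecond grid) are tiled into
consecutive non-overlapping 10 s windows; windows crossing a segment
boundary are dropped rather than zero-padded. Per window and channel a
Hamming-windowed FFT power spectrum is computed, each bin is transformed
to dB, and band values average the bins with lo ≤ f < hi (0.1 Hz
resolution at 10 s; the dB-before-averaging order follows the described
processing chain, with a linear-then-dB variant behind a flag). SWA is
0.5–4 Hz and sigma 9–15 Hz; a morning variant (4 s windows,
theta/alpha/low-beta/high-beta/gamma) is available. Doubling the signal
amplitude shifts every band by exactly 20·log₁₀2 ≈ 6.02 dB, which the
tests assert.

Macrostructure from the hypnogram: sleep latency (lights-off to first N2
epoch), WASO, stage durations, REM latency from sleep onset, stage-shift
rate, and fragmentation (transitions to wake plus NREM lightenings per
hour of sleep). Stage depth is ordered W < N1 < N2 < N3 with REM treated
as its own class — transitions into REM are neither deepenings nor
lightenings — following standard scoring conventions.

## Statistics

ROI values are unweighted means over member electrodes (bad channels are
excluded upstream, not interpolated, for night data); change scores are
deprivation-night minus control-night. Associations with the deprivation
index use Spearman correlations (midranks for ties; exact small-sample
p-values where available, t approximation otherwise), with
Benjamini–Hochberg FDR at q = 0.05 over each feature family.
Night comparisons use the paired Wilcoxon signed-rank test (zeros
dropped), timepoint tests are two-tailed one-sample t-tests against
DI = 1 with Cohen's d, and timecourse analyses use one- or two-factor
within-subject ANOVA with partial η² = SS_effect/(SS_effect + SS_error).
Missing data: pairwise deletion for correlations, listwise for the ANOVA,
both logged. A constant DI sample exactly at 1 returns a degenerate
t = 0 / d = 0 result rather than an error; effects whose sum of squares
is numerically zero relative to the total are reported as F = 0.

## The synthetic-data module

`generate_nrem_eeg()` emulates what the detectors assume about NREM data:
a 1/f^α background (spectrally shaped Gaussian noise, α = 1, 20 µV RMS by
default), biphasic slow-oscillation templates (a negative then a positive
half-sine, so every landmark — crossings, peaks, peak-to-peak amplitude —
is analytically known), and spindle packets (sinusoidal carrier under a
raised-cosine envelope). Events are placed without overlap, with a
capacity error when the requested rates cannot fit. One integer seed
fixes every draw.

Event-parameter defaults are chosen for **detector testability**, not as
an amplitude model of real sleep (none is available to fit): injected
events must be unambiguously on the detectable side of the printed
criteria once the analysis chain is applied. Two margin effects drove the
defaults. First, slow-band conditioning attenuates the template ~5 % and
the in-band background at 20 µV RMS is ~14 µV RMS, so slow-oscillation
amplitudes are drawn at K-complex scale (negative peak −110 to −150 µV,
peak-to-peak 190–260 µV) and down-phases at 0.45–0.8 s, keeping all three
criteria satisfied with ≥ 2 SD margin; events drawn *at* the criterion
boundary are undecidable under noise by construction, for any detector.
Second, the spindle threshold is estimated from data that contain the
spindles themselves, so θ self-inflates roughly as amplitude ×
√occupancy; at 2 events/min, 1.2–1.8 s duration and 55–70 µV peak
envelope, the above-2θ fluctuation of every injected packet comfortably
exceeds the 0.3 s minimum. Residual misses at 20 µV noise (~2–4 % of slow
oscillations) are events riding sustained negative slow-noise excursions
that push the first zero crossing beyond the 1.0 s separation criterion —
the criteria-faithful brute-force oracle rejects these identically, and
the equivalence is tested.

What the generator does **not** emulate: non-stationary sleep-depth
dynamics, artifacts and arousals, spindle/SSO phase coupling, traveling
waves across channels (channels are independent by default), non-Gaussian
amplitude distributions. Passing recovery tests therefore demonstrates
detector correctness under the stated signal model, not performance on
real recordings.

Rivalry timelines draw phase durations from gamma distributions
(shape 3.5, scaled to the requested means) — standard rivalry
phenomenology; the underlying study measured rather than modelled
rivalry, so the generative law is a package choice. Mixed interludes are
inserted between dominance phases at the requested expected fraction, and
the block-truncated final phase is flagged for censoring.

`generate_cohort()` couples a latent Gaussian plasticity variable to each
feature change through a Gaussian copula, converting the target Spearman
ρ to the latent Pearson correlation via r = 2 sin(πρ/6) (exact for the
bivariate normal). The deprivation index is a monotone (log-normal)
transform of the latent, so population Spearman correlations are
preserved exactly. At n = 15 the sample Spearman estimator is attenuated
toward zero by a few hundredths; the replicate-mean recovery test bounds
this at ±0.05.

## Problem sizes and numerical choices

The test suite and acceptance script use an 8-channel, 10-minute, 500 Hz
recording for detector recovery, 50 random 30–60 s traces for the
detector/oracle equivalences, 1,000 replicate n = 15 cohorts for the
statistics-stage recovery, and ±0.25 s interval matching throughout —
sizes chosen to give stable estimates at interactive runtimes. Exact
zeros at a crossing count as non-negative; interval arithmetic rounds to
a 1 ms grid; dB transforms floor zero-power bins at 10⁻¹² µV²/Hz;
EEG matrix I/O validates the JSON sidecar (units, labels, sample count)
and refuses ambiguous files rather than guessing.

## Known limitations

* No EDF reader: recordings are exchanged as a documented CSV matrix +
  JSON sidecar pair.
* The shipped 128-channel geodesic ROI layout is an approximation
  (sensors around O1/Oz/O2/POz, Fp1/Fpz/Fp2/AFz, C3/Cz/C4); it is data,
  not code, and should be replaced by the study's exact lists when
  available.
* Detector performance figures quantify recovery under the synthetic
  signal model only.
* The spindle multiplier ambiguity (×2 on mean + 2 SD) is resolved by
  configuration and sensitivity reporting, not by a claim about the
  original method's intent.
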