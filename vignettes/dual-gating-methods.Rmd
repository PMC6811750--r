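---
title: "Dual cardiac and respiratory gating from a chest-worn IMU: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual cardiac and respiratory gating from a chest-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualgate)
```

## The problem

Cardiac and respiratory motion blur PET/CT images. Dual gating sorts
list-mode events into windows of the cardiac cycle (systole vs. diastole)
and of the breathing cycle (e.g. peak inhalation), so that reconstruction
can use only quiescent phases. The conventional instrumentation is an ECG
for the heartbeat plus an optical marker tracker for breathing. A single
six-axis inertial measurement unit (IMU) taped to the sternum can replace
both: the accelerometer and gyroscope see the high-frequency precordial
vibrations of every heartbeat (seismo- and gyrocardiography, SCG/GCG) and,
at the same time, the slow inclination changes of the chest wall produced
by breathing.

`dualgate` implements the complete offline processing chain from a raw
six-axis chest recording to

* heartbeat annotations with adaptive refinement,
* per-segment cardiac cycle length and ejection (systolic) time,
* cardiac gating bins (n − 1 equal systolic bins plus one diastolic bin),
* five chest-inclination respiration channels fused into one curve,
* peak-inhalation triggers and amplitude- or phase-based respiratory bins,
* the validation metrics used to judge all of the above,

plus a seeded synthetic chest-motion simulator so that every stage is
testable without any recorded data.

## Cardiac chain

### Preprocessing

Each cardiac-carrying channel (accelerometer z, dorsoventral; gyroscope y,
superior–inferior) is screened for motion artifacts with non-overlapping
500 ms frames: a frame whose RMS exceeds 3x the median frame RMS marks a
spike, whose actual beginning and end are then refined by walking outward
while a 50 ms amplitude envelope stays above 1.5x the median level. The
spike interior is zeroed (relative to the channel mean — the accelerometer
z axis carries ~9.8 m/s² of gravity, and both the RMS statistics and the
replacement level must ignore that static offset) with a 10 ms taper.
Because body movements shake all axes at once, the pipeline blanks both
cardiac channels over the union of the windows flagged on either.

The channels are then band-passed (accelerometer 4–40 Hz, gyroscope
1–20 Hz; 4th-order Butterworth, forward–backward so event timing is not
shifted) and standardized to zero mean and unit variance.

Two numerical points deserve note. First, a transfer-function Butterworth
band-pass at 0.1–2 Hz on 800 Hz data is numerically unstable in double
precision; when a band lies far below Nyquist the filter therefore runs at
an FIR-decimated rate and the result is linearly interpolated back. Second,
plain forward–backward filtering of a finite record leaves large edge
transients (several times the in-band signal after standardization); all
filtering therefore pads the record by odd reflection over three
low-edge time constants.

### ICA fusion

The two preprocessed channels are modeled as a 2x2 linear mixture of two
latent vibration sources (myocardial wall motion and blood-flow ballistic
forces). A fastICA-style estimator — whitening followed by a symmetric
fixed-point iteration on the fourth-moment contrast — recovers two
components. The cardiac component is chosen by two criteria:

* it must be super-Gaussian (positive excess kurtosis): cardiac burst
  trains are strongly spiky, while sinusoidal interference is
  sub-Gaussian;
* among super-Gaussian candidates, the one whose normalized
  autocorrelation has the more prominent side peak in the physiological
  0.25–2 s lag band wins: a lone residual motion artifact is spiky but has
  no rhythm.

The component's arbitrary sign is fixed so that the median amplitude at
its envelope peaks is positive. Collinear inputs (|r| at machine
tolerance of 1) abort with advice to fall back to single-channel
processing, and non-convergence of the fixed-point iteration is an error,
not a warning.

### Beat detection

The beat detector needs a smooth, non-negative "one lobe per heartbeat"
envelope. We use the analytic-signal magnitude smoothed by a 250 ms moving
average. The window is deliberately wider than the ~100 ms one might first
try: each heartbeat produces a systolic complex and a weaker diastolic
complex 300–400 ms later, and with narrow smoothing the diastolic complex
forms its own envelope lobe and is double-counted.

Envelope peaks are located with automatic multiscale peak detection
(AMPD): sample *i* is a *k*-scale maximum iff it exceeds both its *k*-step
neighbours, the global scale λ minimizes the count of non-maxima marks,
and peaks are maxima at every scale up to λ. Two conventions matter. At
the record boundary, a comparison that would leave the record counts as a
failure for the scale statistic (mirroring the random-filled boundary
entries of the original scalogram formulation) but passes vacuously during
final extraction, so a genuine first or last peak is not discarded. And
the scale cap must stay below the shortest plausible inter-beat interval
(0.6 s at rest): on sparse envelopes the scale statistic is degenerate —
scales beyond the beat period "skip over" neighbouring lobes entirely and
silently drop beats. For efficiency the envelope (band-limited by
construction) is decimated to ~100 Hz for AMPD and each peak is then
refined on the full-rate envelope.

Each envelope peak is relocated to the largest local maximum of the
cardiac signal within ±150 ms and accepted against an adaptive threshold
`THR = N + 0.25 (S − N)` with exponential signal/noise level updates
(`S ← 0.125 p + 0.875 S` on acceptance, `N ← 0.125 p + 0.875 N` on
rejection) and a 0.25 s refractory period that keeps the larger of two
close candidates. Since processing is an offline batch, the signal level
is initialized from the *median* candidate amplitude; initializing from
the first candidate lets a single outlying complex poison the threshold
for the rest of the record.

### Cycle segmentation and cardiac bins

Cardiac periodicity is estimated per non-overlapping 20 s segment from the
normalized autocorrelation up to a 5 s lag. The cycle length is the "first
dominant" side peak: the earliest local maximum within 70% of the tallest,
beyond a 0.25 s physiological floor and above a height floor of 0.1. Taking
the literal argmax occasionally doubles the period, because beat-to-beat
jitter attenuates the two-cycle peak only stochastically; the first-dominant
reading is robust to that.

The ejection (systolic) time is the "semi side-peak" between zero lag and
the cycle peak, left by the diastolic vibrations. Candidates are scored by
*prominence* over a ±25 ms base rather than raw height, must lie at least
50 ms before the cycle peak and within the physiological 0.6 s ejection
bound, and near ties (10%) go to the smaller lag. The reasons: the
systole-to-diastole lag is an exact within-beat distance and always gives
a sharp peak, whereas its mirror image at (cycle − ejection) spans
adjacent beats and is smeared flat by jitter — but carrier-phase
interference in the fused component can leave the sharp true peak with a
low absolute height. Scoring by sharpness rather than height selects the
correct lag in both regimes. If no candidate qualifies, the ejection falls
back to 0.35x the cycle length, matching the typical 300–400 ms
systole-to-diastole delay at resting heart rates; such segments are
flagged. A segment with no qualifying cycle peak at all (e.g. pure noise)
is marked invalid.

Per beat, with onset `b`, successor `b2`, and segment ejection `e`, the
first `n − 1` bin boundaries divide `[b, b + e)` equally and the last bin
spans the diastolic remainder `[b + e, b2)`; an ejection exceeding 90% of
the beat interval is clamped with a warning so the diastolic bin is never
empty.

## Respiratory chain

Chest pitch (about the lateral x axis) and roll (about the longitudinal y
axis) are recovered from the gravity projections:

* pitch `β = arctan(Acc_y / sqrt(Acc_z² + Acc_x²))`,
* roll `α = arctan(Acc_x / sqrt(Acc_z² + Acc_y²))`,

with the small-angle forms `β ≈ Acc_y / g`, `α ≈ Acc_x / g` available for
comparison (`g = 9.80665 m/s²`). The exact forms are the default — they
cost nothing offline. The gyroscope axes are integrated (cumulative
trapezoid) into tilt angles; drift is removed by subtracting the line
through the first and last samples rather than a least-squares line,
because a sine train is not orthogonal to a ramp over a finite record and
least-squares detrending biases sinusoid amplitudes by several percent.
All five channels (ADRx, ADRy from the accelerometer; GDRx, GDRy, GDRz
from the gyroscope) are band-passed to 0.1–2 Hz, centred, and stacked
into a 5 x n measurement matrix.

Polarity is resolved against the band-passed accelerometer z channel
(longitudinal chest movement): any channel correlating negatively with it
is inverted. The correction is idempotent.

The five channels are fused by PCA on the *correlation* (standardized)
matrix: the accelerometer-derived and integrated-gyroscope channels have
different post-filter variances, and covariance-matrix PCA would let scale
rather than shared breathing structure pick the first component. The fused
curve is the projection onto the first eigenvector, sign-fixed against the
polarity reference.

Breath cycles are detected by AMPD on the fused curve (decimated to
~25 Hz) and on its negation; candidates closer than half the median
inter-peak distance to their predecessor are dropped (keeping the larger),
and strict inhalation/exhalation alternation is enforced. Peak-inhalation
trigger times are refined to sub-sample precision by parabolic
interpolation, since trigger-offset statistics live at the tens of
milliseconds scale. Respiratory bins divide either the 5th–95th percentile
amplitude range or each inhalation-to-inhalation phase interval into n
equal parts.

## Evaluation metrics

Beat matching is greedy nearest-first one-to-one within a ±150 ms window
(a flag; the matching window of cardiomechanical literature), from which
sensitivity (TPR), precision (PPV), F1, and the RMS of matched time
differences follow. Heart rate is 60 over the mean inter-beat interval.
The cardiac cycle percentage (CCP) divides summed per-beat ejection times
by summed cycle lengths. Respiration agreement is the Pearson correlation
at the reference rate (the fused 800 Hz curve is resampled down to the
25 Hz surrogate). Trigger offsets match each detected peak-inhalation to
the nearest reference trigger within half the median reference interval
and report the mean and SD of the absolute differences, with unmatched
triggers counted separately.

## The synthetic simulator

`simulate_chest_motion()` generates the statistical structure the pipeline
assumes, with ground truth:

* beat times at `hr_bpm` with Gaussian beat-to-beat jitter; per-beat
  ejection delays at 350 ± 5 ms (within the 300–400 ms physiological
  range);
* two latent cardiac sources — Gabor-like damped oscillations (15 Hz
  accelerometer / 8 Hz gyroscope carriers, ~80 ms support) at each beat,
  plus weaker (0.4x), shorter, higher-frequency diastolic spikes at the
  per-beat ejection delay — mixed with fixed 2x2 weights onto the
  accelerometer z and gyroscope y channels; gyroscope z gets no cardiac
  content (no dorsoventral micro-rotations);
* a breathing trajectory (0.25 Hz with slow rate drift) projected through
  gravity onto all accelerometer axes, matching angular rates on the
  gyroscope axes, and a small dorsoventral proper-acceleration term in
  phase with inhalation (what an optical chest marker would see);
* white sensor noise per channel and raised-cosine whole-body motion
  artifacts at Poisson times.

Defaults are one decision, made once: 60 bpm, 0.5 bpm beat-to-beat SD,
0.04 rad tilt amplitude, 0.1 m/s² / 0.02 rad/s cardiac burst amplitudes
(typical sternal SCG/GCG magnitudes), noise at 5% of each channel's
dynamic RMS, one artifact per minute at 8x channel RMS. The low
beat-to-beat SD (≈8 ms in inter-beat interval) keeps successive complexes
phase-coherent at the burst carrier frequency. This is the simulator's
stand-in for a property of real signals that a random-jitter model cannot
otherwise express: real systolic complexes are morphologically
reproducible from beat to beat, which is what makes short-time
autocorrelation of real SCG work at ordinary heart-rate variability. The
generator emits a ground-truth beat only when the beat's full complex fits
inside the record (0.8 s margin), since a truncated boundary complex has
no complete signature to detect.

`simulate_respiration_set()` generates the situation the PCA fusion
exists for: five inclination channels sharing one breathing trajectory
but with per-axis coupling gains, random polarity, and independent
band-limited noise of axis-dependent strength (mean SNR 3 dB, SD 3 dB),
so that which axis is cleanest varies from recording to recording — the
inter-axis variability reported across subjects in practice. In the
full-IMU simulator this test would be vacuous: with equal relative sensor
noise on every raw channel, integration plus band-passing makes the
gyroscope-derived channels systematically cleanest, and no fixed-weight
fusion can beat a channel that is always best. The channel-level
construction is the honest home of the fusion-dominance property.

### What passing tests do and do not show

The simulator reproduces the pipeline's assumed structure — band-limited
quasi-periodic bursts, gravity-projected tilt, common-mode artifacts — not
real SCG morphology (no AO/AC sub-waves), not BMI-dependent attenuation,
not pathological rhythm (ectopy, fibrillation), and only mildly irregular
breathing. Perfect beat recovery on clean simulations validates the
plumbing and the contracts between stages; it does not predict clinical
sensitivity, which on real recordings is limited by morphology variability
that this generator deliberately does not model.

## Problem sizes and runtime

The shipped tests run the full pipeline on 60 s recordings at 800 Hz
(10 seeds clean, 10 seeds at 6 dB SNR with 2 artifacts/min), 20
respiration-set simulations, 100 AMPD oracle comparisons at lengths up to
500, and 10 cycle-segmentation grids of 60 s; the whole suite completes in
well under a minute on one core. `scripts/acceptance.R` processes a single
3-minute recording at the default study conditions.

## Known limitations

* The envelope stand-in (analytic magnitude + 250 ms moving average) is a
  simple surrogate for a dedicated cardiac enhancement filter; any
  envelope with one dominant lobe per beat can be substituted behind
  `envelope_signal()`.
* The ejection estimate assumes the diastolic complex is visible in the
  autocorrelation; when it is not, the 0.35x-cycle fallback is used and
  flagged, and downstream CCP inherits that assumption.
* AMPD's scale cap bounds the detectable beat rate from below
  (envelope peaks) and breath rate from below (fused curve); tachycardia
  beyond 100 bpm would need a smaller envelope scale cap.
* Everything is offline batch processing; no streaming or prospective
  trigger output.
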