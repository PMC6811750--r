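# dualgate

Dual cardiac and respiratory gating of PET/CT acquisitions from a single
chest-worn six-axis inertial measurement unit (tri-axial accelerometer +
tri-axial gyroscope).

Cardiac and breathing motion blur nuclear-medicine images; gating sorts
acquisition events into quiescent phases of both cycles. Instead of the
usual ECG + optical-marker pair, a single IMU taped to the sternum sees
both the high-frequency precordial vibrations of each heartbeat
(seismo-/gyrocardiography) and the slow chest-inclination changes of
breathing. `dualgate` turns such a recording into heartbeat annotations,
cardiac gating bins, a fused respiration curve, and peak-inhalation
triggers.

## Method at a glance

**Cardiac.** The dorsoventral acceleration `Acc_z` and superior–inferior
angular rate `Gyro_y` are artifact-screened (500 ms frame RMS > 3x median,
spike extents zeroed), band-passed (4–40 Hz / 1–20 Hz, zero-phase), and
standardized. Modeling them as a 2x2 mixture of two latent vibration
sources, a fastICA-style estimator recovers the underlying cardiac motion
signal; beats are located on its smoothed analytic envelope by automatic
multiscale peak detection (AMPD) and refined on the raw component with a
Pan–Tompkins-style adaptive threshold and 0.25 s refractory. Per 20 s
segment, the normalized autocorrelation (lags ≤ 5 s) yields the cardiac
cycle length (first dominant side peak) and the ejection time (sharpest
semi side-peak before it); each beat interval is then split into `n − 1`
equal systolic bins plus one diastolic bin.

**Respiratory.** Chest pitch and roll follow from the gravity projections,

    β = arctan( Acc_y / √(Acc_z² + Acc_x²) ),  α = arctan( Acc_x / √(Acc_z² + Acc_y²) ),

and the gyroscope axes are integrated into tilt angles. The five channels
(ADRx, ADRy, GDRx, GDRy, GDRz), band-passed to 0.1–2 Hz and
polarity-corrected against the dorsoventral reference, are fused by PCA on
their correlation matrix; the first component is the respiration surrogate
from which AMPD-based breath detection emits peak-inhalation triggers and
amplitude- or phase-based bins.

**Evaluation.** Beat TPR/PPV/F1 and RMSE against reference annotations,
heart rate, cardiac cycle percentage (CCP = Σ ejection / Σ cycle), Pearson
correlation of respiration curves at the reference rate, and mean absolute
trigger offsets.

A seeded synthetic chest-motion simulator (`simulate_chest_motion()`,
`simulate_respiration_set()`) generates recordings with ground truth so
the entire pipeline is testable without data.

## Worked example

```r
library(dualgate)

sim <- simulate_chest_motion(sim_config(duration_s = 60, seed = 42))
res <- run_dual_gating(sim$recording, dual_config(seed = 42),
                       ref_beats = sim$truth$beat_times)
res
#> <dual_gating>
#> <beat_set> 58 beats, mean IBI 1.018 s (59.0 bpm)
#> <cycle_segmentation> 3 segments (3 valid), median cycle 1.001 s, median ejection 0.350 s
#>   breaths: 15 inhalation peaks
#>   vs reference: F1 0.974, RMSE 44.5 ms
```

The 60 s recording was simulated at 60 bpm with the default noise and one
motion artifact per minute. The pipeline finds 58 beats (F1 0.974 against
the ground-truth beat times at a ±150 ms window; the artifact blanks the
remainder), estimates the cardiac cycle at 1.001 s and the ejection time at
0.350 s in every 20 s segment — the generating values are 1.0 s and
0.35 s, so the cardiac cycle percentage comes out at 34.9% — and detects
15 breaths of the 0.25 Hz breathing trajectory.

Per-stage functions (`remove_artifacts()`, `bandpass()`, `ica_fuse()`,
`ampd_peaks()`, `refine_beats()`, `segment_cycles()`, `make_cardiac_bins()`,
`extract_respiration()`, `polarity_correct()`, `pca_fuse()`,
`detect_breaths()`, `make_resp_bins()`, `match_beats()`, ...) are exported
individually; see the package vignette for the modeling decisions behind
each.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/dualgate.R simulate --seed 7 --out rec.csv --truth truth.csv
Rscript inst/cli/dualgate.R run --in rec.csv --seed 7 --ref-beats truth.csv --out-dir out/
Rscript inst/cli/dualgate.R selftest --seed 1
```

Subcommands: `simulate`, `preprocess`, `cardiac`, `resp`, `evaluate`,
`run`, `selftest`. Exit codes: 0 success, 2 validation error, 3
numeric/convergence failure. Column names and sensor units (`g` vs `m/s2`,
`deg/s` vs `rad/s`) are configurable through a YAML file passed with
`--config`.

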