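---
title: "Suppressing systemic interference in block-design fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Suppressing systemic interference in block-design fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsreg)
```

## The problem

Continuous-wave fNIRS measures optical-density changes through scalp and
skull, so every channel records, on top of any cortical hemodynamic
response, *systemic physiology*: cardiac pulsation (~1–2 Hz), respiration
(~0.2–0.4 Hz), Mayer waves (~0.1 Hz) and very-low-frequency (VLF)
oscillations at 0.01–0.05 Hz.  For a block design with 10 s task + 15 s
rest, the task fundamental sits at 1/25 s = 0.04 Hz — *inside* the VLF
band.  A low-pass filter removes the fast components but cannot separate
the response from slow systemic activity, and when that activity is
entrained by the task (blood pressure and autonomic tone respond to the
task rhythm) a group analysis will report activation almost everywhere.
`fnirsreg` implements the full chain that addresses this: per-channel
preprocessing, regression of a data-derived systemic regressor built from
*task-unrelated* channels, per-trial GLM β estimation, and group
statistics, together with a synthetic-data generator that reproduces the
interference structure so every stage is testable with known ground
truth.

## Probe geometry

The canonical probe is a 4×5 checkerboard of 10 sources and 10 detectors
at 3 cm pitch spanning 9 cm × 12 cm; the 31 measurement channels are all
nearest-neighbour source–detector pairs (16 horizontal + 15 vertical).
Channel numbers run row-major from the frontal row down, left to right —
chosen because it reproduces the canonical ROI channel groupings (low ids
prefrontal, high ids over somatosensory motor cortex).  The device's own
numbering is only published as a figure, so this convention is documented
rather than guaranteed identical; all ROI logic keys on the channel
lists, not on coordinates.  Midline channels (7, 16, 25) are assigned to
a hemisphere by the ROI lists where those state a side (channel 7 →
right) and default to the left otherwise.  Coordinates are probe-plane cm
with the origin at the top-left optode; no scalp registration is
attempted.

## Preprocessing chain

Each channel is processed independently, in a fixed order:

1. **Median filter**, width 3 samples, to remove jump/drop outliers.  At
   the record edges the window shrinks to the available samples.
2. **Polynomial detrend**, order 2, fitted over the full record by least
   squares.
3. **Z-score**: `(x − mean(x)) / sd(x)` with the *population* SD (divide
   by N).  The choice of denominator is immaterial to every downstream
   statistic (the scale cancels) but is fixed for reproducibility.  The
   Z-score is what cancels the unknown photon pathlength factor L that
   multiplies each channel's reported concentration change.
4. **Zero-phase Butterworth low-pass**, 2nd-order design at 0.08 Hz,
   applied forward and backward (effective 4th-order magnitude response,
   zero phase).  Edges use odd-reflection padding with steady-state DC
   initial conditions, the standard filtfilt convention.  At 7.14 Hz
   sampling this attenuates a 1 Hz cardiac probe by ~90 dB (two-pass)
   while passing 0.04 Hz with no phase shift.

Constant (dead) channels cannot be Z-scored; they are zeroed, flagged,
and excluded from regressor construction and statistics.

## Task-unrelated channel regression

Steps 5–6 of the chain.  For each channel the Pearson correlation *r*
with the raw 0/1 task boxcar (not the HRF-convolved regressor — an
option exists but is off by default) is computed on the preprocessed
series.  Channels with |r| strictly below 0.2 are *task-unrelated*; their
pointwise mean is the systemic regressor.  This is done per hemisphere:
the left regressor is built from left-hemisphere channels only and
regressed (OLS with intercept) out of left-hemisphere channels only, and
vice versa.  Design choices:

* A target channel that contributed to the regressor is still regressed
  against the full regressor (no leave-one-out by default; available as
  an option).  With *m* selected channels this removes ~1/m of the
  channel's own variance — visible in the no-coupling edge case, harmless
  in practice.
* If a hemisphere has no task-unrelated channel the hemisphere is left
  unregressed with a warning.  The threshold is never adapted, because
  changing the threshold changes the method.
* The before/after channel-correlation matrices are returned as the
  standard diagnostic: shared systemic interference shows as uniformly
  high off-diagonal correlation before, which collapses after, while
  genuinely co-active channels stay correlated.

A known limitation, reproduced faithfully: because the regressor is a
mean of finitely many noisy channels, the OLS fit is slightly diluted and
a small fraction of shared interference survives in strongly-coupled
channels.  With realistic selections (≥ ~8 channels per side) this
residue is well below the between-subject noise floor.

## GLM and group statistics

The design matrix has one regressor per trial — the trial's boxcar
convolved with a canonical double-gamma HRF (peak ~6 s, undershoot
~16 s, undershoot ratio 1/6) — plus an intercept; a linear drift column
is optional and off by default since detrending happens upstream.  All
trial columns share one scale, chosen so a single convolved trial peaks
at 1; on Z-scored data the β's are then peak response amplitudes in Z
units.  Estimation is plain OLS with no prewhitening (the reference
implementations' autocorrelation options are not reproduced).  Per-trial
β's are averaged arithmetically per subject × condition × channel; the
trial count is configurable (default 20 per condition — the source
protocol's trial bookkeeping is internally inconsistent between 10, 20
and 4×5, so the count is a parameter, not a constant).

Group statistics:

* Per channel and condition, a one-sample t-test of the subject mean β's
  against zero (two-sided by default), df = n−1, followed by
  Benjamini–Hochberg FDR across the 31 channels of that condition (own
  step-up implementation, cross-checked against two independent oracles
  in the tests).  A channel is *activated* when it survives FDR at
  q = 0.05 **and** t > 0 — activation means an HbO2 increase; a channel
  can be FDR-significant with negative t but is never flagged activated.
* ROI means over the fixed channel lists (PFC, pre-motor/SMA, M1, SMC ×
  hemisphere), then a 2×2 repeated-measures ANOVA with within-subject
  factors task (ME/MI) and hand (left/right).  All effects have 1
  numerator df, so sphericity corrections are moot and each main-effect
  F equals the square of the paired t on the factor margins — asserted
  as a property in the tests.  Effect size is partial eta squared,
  SS_effect/(SS_effect+SS_error).  Post hocs are paired t-tests with
  Bonferroni correction (raw p × number of comparisons, clipped at 1)
  and the mean within-subject difference (MD).

## The synthetic-data generator

Each channel c of a simulated recording is

```
L_c * ( amplitude_c * response + gain_c * shared + local_c + drift_c + noise )
```

* `response`: boxcar ∗ double-gamma HRF, unit single-trial peak; nonzero
  only in the scenario's active channels.  Default amplitude 1 with
  between-subject multiplier N(1, 0.3) truncated at 0.
* `shared`: one sinusoid per physiological band (cardiac 1–2 Hz,
  respiration 0.2–0.4 Hz, Mayer 0.08–0.12 Hz, VLF 0.01–0.05 Hz), random
  frequency and phase per recording, amplitudes 0.4/0.4/1/1 — the slow
  components are comparable to a unit response, which is the regime the
  method is for.  Coupling gains per channel are U(0.4, 1.2).
* `local_c`: one slow sinusoid per channel (random 0.01–0.06 Hz,
  amplitude U(0.5, 1.5)), emulating superficial physiology that is *not*
  shared across the probe.  Without such a term every channel would have
  the same task correlation up to noise and the |r| < 0.2 selection
  would be degenerate — this is a structural requirement of the method's
  premise, not a tuning knob.
* `drift_c`: random quadratic (coefficient SD 0.5); `noise`: white
  Gaussian, SD 0.3; `L_c`: the unknown pathlength factor, U(0.5, 2).

Timing defaults are 20 trials of 10 s task + 15 s rest at 7.14 Hz with
one rest period of lead-in; record length is floored to whole samples.
Per-subject seeds are drawn from the master seed by a fixed-seed
`sample.int`, so groups are bit-reproducible.

### The stress scenario

The `stress-null` scenario adds a shared sinusoid **at the block
frequency (0.04 Hz), phase-locked to the task** (peak 8 s after each
onset, per-subject lag jitter SD 2 s), amplitude 0.4, with no active
channels.  Task-locking is essential and deliberate: a free-running
near-0.04 Hz oscillation with independent random phase per subject
produces per-subject β biases that average to zero across a group, so it
cannot generate the group-level over-activation the method exists to
suppress.  Only an entrained component — task-evoked blood-pressure and
autonomic responses are the physiological reading — biases every subject
in the same direction.  With these defaults, the pipeline *without*
regression falsely activates ~27–31 of 31 channels (the documented
over-activation failure mode), ~80 % of channels remain task-unrelated
(|r| < 0.2), and the pipeline *with* regression returns to FDR-level
false-positive rates.  The amplitude 0.4 was fixed from these premises
before the acceptance assertions were frozen and is not revisited.

### What a green test does not establish

The generator has sinusoidal interference, Gaussian noise, no motion
artifacts, no HbR dynamics, linear superposition, and channel-independent
local physiology.  Real recordings violate all of these to some degree.
Green tests establish that the *implementation* realises the method's
contracts and that the method behaves as described *in the world the
paper assumes*; they do not certify performance on arbitrary hardware or
populations.

## Numerical choices and degenerate inputs

* Butterworth design via bilinear transform with prewarped cutoff;
  coefficients match an independent reference implementation to 1e-12.
* Z-score denominator: population SD.  Scale invariance is exact in
  floating point only for power-of-two factors; for arbitrary positive
  factors downstream artifacts agree to ~1e-10 relative.
* Amplitude-linearity checks run with Z-scoring disabled: with no other
  variance in a channel, Z-scoring removes the overall response amplitude
  by construction, so "β linear in A through the standardising pipeline"
  is not a well-posed claim and the calibration study uses raw units.
* Correlation against the boxcar: a sinusoid at *twice* the block
  frequency is **not** orthogonal to a 40 % duty-cycle boxcar (its second
  harmonic is nonzero); orthogonality tests use half the block frequency
  over whole periods instead.
* Degenerate channels (zero variance before or after detrending) are
  flagged and zeroed; constant regressors degrade to mean removal; an
  empty task-unrelated selection skips the hemisphere with a warning.
* MBLL extinction coefficients ship as an editable three-wavelength table
  (780/805/830 nm) with literature-style values; the source device's
  constants are unpublished, so the table is configuration, not truth.
  The three-wavelength × two-chromophore system is solved per sample by
  least squares.

## Known limitations

* No SNIRF import/export: no HDF5 R binding is available in the target
  environment; the interchange format is headered TSV.
* No wavelet-MDL detrending, short-separation-channel regression, motion
  correction, prewhitening, or anatomical registration — all outside the
  method being implemented.
* Regression dilution (above) means very strong entrained interference
  with very few task-unrelated channels can leave residual group bias;
  the empty-selection fallback warns rather than silently adapting.
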