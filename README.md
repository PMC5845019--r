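# fnirsreg

Systemic interference suppression and activation mapping for
block-design fNIRS.

## The problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemoglobin changes through the scalp, so every channel also carries
systemic physiology: cardiac pulsation (~1–2 Hz), respiration
(~0.2–0.4 Hz), Mayer waves (~0.1 Hz) and very-low-frequency oscillations
(0.01–0.05 Hz).  A block design of 10 s task + 15 s rest has its
fundamental at 1/25 s = **0.04 Hz**, inside the very-low-frequency band:
band-pass filtering cannot separate the response from slow systemic
activity, and task-entrained systemic activity makes a naive group GLM
report activation almost everywhere.

`fnirsreg` is for researchers analysing (or simulating) multichannel
block-design fNIRS who need that interference suppressed before
inference.  It implements, end to end:

* a canonical 31-channel probe geometry (4×5 optode checkerboard, 3 cm
  pitch, 9 × 12 cm) with hemisphere and ROI labels (PFC, pre-motor/SMA,
  M1, SMC);
* modified Beer–Lambert conversion of three-wavelength optical-density
  changes to pathlength-scaled HbO2/HbR/HbT;
* per-channel preprocessing: median filter (width 3) → quadratic detrend
  → Z-score, Z = (x − mean x)/sd x, which cancels the unknown pathlength
  factor L → zero-phase 2nd-order Butterworth low-pass at 0.08 Hz;
* **task-unrelated channel regression**: channels whose correlation with
  the 0/1 task boxcar satisfies |r| < 0.2 are averaged into a systemic
  regressor, built and applied per hemisphere, and removed from every
  channel on that hemisphere by OLS;
* per-trial GLM with a double-gamma HRF: y = Xβ + ε, one regressor per
  trial, β's averaged per subject × condition × channel;
* group statistics: per-channel one-sample t (df = n−1) with
  Benjamini–Hochberg FDR maps, ROI means, 2×2 repeated-measures ANOVA
  (task × hand, F(1, n−1), partial eta squared = SS_eff/(SS_eff+SS_err)),
  Bonferroni-corrected paired post hocs;
* a synthetic-data generator reproducing the interference structure —
  shared sinusoidal systemic components, per-channel slow physiology,
  polynomial drift, white noise, unknown per-channel scale factors, and
  an optional *task-entrained* 0.04 Hz stress component — with known
  ground truth for every stage.

## Worked example

Simulate a 16-subject group with activation in the M1 channels
contralateral to a left-hand task, on top of full systemic interference,
then run the whole pipeline:

```r
library(fnirsreg)

layout <- build_default_layout()
group  <- simulate_group(n_subjects = 16, layout,
                         scenario = "contralateral-M1",
                         seed = 42, conditions = "ME_left")
res <- analyze_group(group)          # preprocess + regression + GLM + stats

subset(res$activation, activated)[, c("condition", "channel", "t", "df", "p_fdr")]
#>  condition channel        t df        p_fdr
#>    ME_left      18 8.714490 15 3.055330e-06
#>    ME_left      21 8.517632 15 3.057636e-06
#>    ME_left      22 7.530621 15 9.292148e-06

group$truths[[1]]$active_channels
#> [1] 18 21 22
```

The three FDR-significant channels (t(15) ≈ 7.5–8.7) are exactly the
simulated right-M1 ground truth; no null channel survives.  The
regression diagnostic for one subject shows the shared interference
collapsing while the data keep their structure:

```r
rep1 <- res$reports[[1]]
mean_offdiag_cor(rep1$cor_before)   # 0.40  mean |r| across channel pairs
mean_offdiag_cor(rep1$cor_after)    # 0.09  after hemispheric regression
```

`make_tmap(res$activation, layout, path = "tmap.png")` writes the
channel-grid t map; `plot_correlation_maps(rep1, "cor.png")` writes the
before/after correlation heat maps.  A command-line front end with
`simulate` and `all` subcommands is installed under
`system.file("cli", "fnirsreg", package = "fnirsreg")`.

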