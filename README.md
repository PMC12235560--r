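# motionbag

Head motion in the scanner attenuates grey-matter estimates from
T1-weighted MRI in the same direction as aging does, so motion does not
just add noise to a brain-age model — it biases its output upward.
`motionbag` is an R package for quantifying that bias on a
repeated-session induced-motion design: every subject is scanned without
induced motion (`STAND`), with low (`HM1`) and with high (`HM2`) induced
motion, each scan carrying an expert visual motion rating (0–5) and a
FreeSurfer Euler number as an automated quality proxy.

It is aimed at researchers who run brain-age-gap (BAG) analyses on
tabular morphometric features (VBM grey-matter density, cortical
thickness) and want to measure, or correct for, the motion confound.

## What it computes

- **Brain age model** — per-feature z-scoring anchored on the training
  cohort, SVD PCA, and linear regression of age on the first *k*
  component scores (`none`/`L1`/`L2` penalties, unpenalized intercept),
  with *k*\* selected by 10-fold cross-validated RMSE.
- **BAG and adjusted BAG** — the raw gap `δ1 = Xβ1 − Y` and its age-bias
  adjustment `δ2 = δ1 − (slope·Y + intercept)`, with the adjustment line
  fitted by OLS on the training cohort's out-of-fold predictions.
- **Euler normalization** — `−ln(−rawEuler + 1)`, a bijection from
  (−∞, 1) to the reals that tames the heavy left tail of raw Euler
  numbers.
- **Motion models** — random-intercept mixed models (REML, `lme4`) of
  adjusted BAG on session / visual rating / normalized Euler, of
  normalized Euler on session / rating, and a per-component motion screen
  with Benjamini–Hochberg FDR correction.
- **Rating reliability** — exact agreement and linearly weighted Cohen's
  kappa for repeated ordinal motion ratings.
- **Synthetic cohorts** — a seeded generator that emulates the
  training + three-session motion design with known ground truth (aging
  direction, motion direction and their overlap, subject random effects,
  truncated-normal severities, noisy ratings, skewed Euler surrogates),
  so every stage is testable by parameter recovery.

## Worked example

```r
library(motionbag)

cfg <- sim_config(seed = 1)          # default synthetic study conditions
res <- run_experiment(cfg, k_range = 1:20)

res$lmm$bag_session
#> Random-intercept LMM: delta2 ~ session + (1 | subject)
#>   363 scans from 121 subjects
#>   (Intercept)      beta =   -0.100  (SE 0.310, t =  -0.32, p = 0.748)
#>   sessionHM1       beta =    0.874  (SE 0.210, t =   4.17, p = 3.9e-05)
#>   sessionHM2       beta =    1.685  (SE 0.210, t =   8.03, p = 1.43e-14)
#>   variance: subject 8.9945, residual 2.6655
#>   adjusted R-squared: conditional 0.852, marginal 0.034
```

Reading: relative to each subject's no-motion scan, low induced motion
inflates the age-bias-adjusted BAG by **0.87 years** and high motion by
**1.69 years** — pure artifact, since the synthetic subjects do not age
between sessions. The visual-rating model gives a dose response of
**0.48 years per rating level** (t = 7.83), and the per-component screen
localizes the effect in one component carrying 16.8% of the training
variance:

```r
res$fdr$session
#> Per-component motion screen (BH FDR, q = 0.05)
#>   sessionHM1       1 component(s) significant (16.8% of training variance)
#>   sessionHM2       1 component(s) significant (16.8% of training variance)
```

The underlying age model is accurate on motion-free data (training CV
r = 0.92, RMSE = 3.61 years, k\* = 8), which is exactly why its errors on
motion-affected scans are systematic rather than random.

`run_pipeline(cfg, out_dir)` writes the full artifact bundle: a model
directory (scaler, PCA, age model, adjustment, CV curve as JSON),
`predictions.csv`, one JSON per mixed model, FDR tables, agreement
statistics and a markdown report, all stamped with the configuration hash
and seed. Real data enter through `load_scan_table()` (TSV features +
CSV metadata) and flow through the same functions.

See `vignettes/motion-and-brain-age.Rmd` for the model details, the
generator's assumptions and the package's design choices.

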