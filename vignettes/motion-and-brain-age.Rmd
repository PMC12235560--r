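---
title: "Quantifying motion-induced inflation of the brain age gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying motion-induced inflation of the brain age gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motionbag)
```

## The problem

The brain age gap (BAG) — the difference between an age predicted from
structural MRI morphometry and the chronological age — is widely used as a
biomarker of brain health. Head motion in the scanner attenuates
grey-matter estimates (lower apparent density, thinner apparent cortex) in
much the same direction as aging does. A model trained on low-motion data
will therefore read a motion-corrupted scan as an *older* brain: motion does
not merely add variance to BAG, it biases it upward. Populations of clinical
interest (older adults, Parkinson's disease, dementia) also move more, so
the bias is confounded with exactly the contrasts BAG studies care about.

`motionbag` implements the full chain needed to quantify this inflation on a
repeated-session induced-motion design in which every subject is scanned
three times — once still (`STAND`), once with low (`HM1`) and once with high
(`HM2`) induced head motion — plus per-scan expert motion ratings (ordinal
0–5) and the FreeSurfer Euler number as an automated quality proxy.

## The model chain

**Age prediction.** Training-cohort features are z-scored per feature
(sample SD, $n-1$ denominator) and reduced by SVD-based PCA. Age is
predicted by linear regression on the first $k$ component scores,

$$\hat Y = X\beta_1,$$

with $X$ including an (unpenalized) intercept column and the component
count $k^\*$ selected by 10-fold cross-validated RMSE over a user-chosen
range, taking the smallest $k$ attaining the minimum (parsimony; a relative
tolerance of $10^{-8}$ treats numerically indistinguishable RMSEs as tied).
L2 regression uses the exact closed form
$(S_c^\top S_c + \lambda I)^{-1} S_c^\top y_c$ on centred data; L1 uses
coordinate descent with the penalty expressed on the total
$\sum_j|\beta_j|$ scale. When $\lambda$ is not given it is chosen by an
inner 5-fold search over 20 log-spaced values.

**BAG and its age-bias adjustment.** The raw gap is
$\delta_1 = X\beta_1 - Y$. Because $\hat Y$ regresses toward the training
mean, $\delta_1$ is mechanically anti-correlated with age; the adjusted gap
residualizes it on age,

$$\delta_2 = \delta_1 - (\beta_2^{(1)} Y + \beta_2^{(0)}),$$

with $\beta_2$ fitted by OLS. By default $\beta_2$ is fitted on the
*training cohort's out-of-fold* $(\delta_1, Y)$ pairs and then applied to
the test cohort. The alternative — refitting on the test sample — recentres
every session jointly and can absorb part of a global motion effect into
the adjustment; anchoring on training CV predictions avoids leaking test
structure and keeps the three sessions comparable. The option
`beta2_sample = "test"` exists for sensitivity checks, and on its own
fitting sample $\delta_2$ has exactly zero mean and zero correlation with
age.

**Out-of-sample projection.** Test scans are standardized with *training*
means and SDs and projected on *training* loadings — never re-centred on
the test data — so session differences in the scores reflect differences in
the scans, not in the normalization.

**Euler normalization.** Raw average Euler numbers (2 − 2·holes, averaged
over hemispheres) are heavily left-skewed; the transform

$$\mathrm{Euler}_{norm} = -\ln(-\mathrm{Euler}_{raw} + 1)$$

maps $(-\infty, 1)$ bijectively onto the reals, is zero at zero, and
compresses the tail so the proxy can serve as a linear covariate.

**Mixed models.** Motion effects are estimated with random-intercept
models fitted by REML (`lme4`):

- adjusted BAG ~ session + (1 | subject), `STAND` as reference;
- adjusted BAG ~ visual rating + (1 | subject), rating continuous;
- adjusted BAG ~ normalized Euler + (1 | subject);
- the same models with normalized Euler as the outcome;
- per-component score ~ session (or rating) + (1 | subject), screened
  across components by Benjamini–Hochberg step-up FDR.

Wald t statistics use residual degrees of freedom
($n_{obs} - n_{fixed}$); Satterthwaite approximations are deliberately not
implemented — with hundreds of scans the difference is negligible, and the
simple convention is reproducible across software. In a calibration study
of 100 null cohorts the per-contrast type-I error at $\alpha = 0.05$ was
6.5%, the expected mild anticonservatism of this convention. Because the
adjusted-$R^2$ convention for mixed models is ambiguous, both a conditional
version (observed vs fitted including predicted random intercepts) and a
marginal one (fixed effects only) are reported.

For the session screen, BH runs separately within the HM1-vs-STAND and
HM2-vs-STAND contrast families, so each contrast has its own rejected set
and its own cumulative explained-variance mass; this matches designs that
report separate low-motion and high-motion component counts.

**Intra-rater agreement.** Exact percent agreement plus linearly weighted
Cohen's kappa on the 6×6 rating table (weights $1 - |i-j|/5$). When both
passes are constant and identical, chance agreement equals observed
agreement; kappa is reported as undefined rather than forced to a number.

## What the synthetic generator emulates

The generator is the package's study design, not a test fixture. Features
follow

$$x_{ij} = \mu_j + a_j (Y_i - \bar Y) + \textstyle\sum_l u_{il} w_{lj}
  + b_j\,m_{is} + \varepsilon_{ij},$$

with a fixed aging direction $a$ (overall magnitude `age_effect_scale`,
negative: grey matter declines with age), low-rank subject structure $W$
(latent factor SD `subject_sd`, shared across a subject's sessions — this
is what makes the random intercept real), a motion direction $b$ whose
cosine with the aging direction is `motion_overlap` (1 by default: motion
mimics aging, the confound of interest; 0 makes it orthogonal), and i.i.d.
noise. Ages are centred at the midpoint of `age_range` so the training and
test cohorts share one reference.

Latent per-scan severities are truncated-normal with session means
`severity_means` (a zero mean denotes a no-induced-motion protocol and
yields exactly zero severity). Ratings are a piecewise-linear map of
severity onto 0–5 (severity 3 and above saturates at 5) with Gaussian
rater noise before rounding — monotone in expectation, noisy in
realization, so session and rating overlap rather than coincide. The Euler
surrogate draws a Gaussian latent on the *normalized* scale,
$e = e_0 - s\,m + \eta$, and returns $1 - \exp(-e)$, making the raw values
left-skewed by construction and the normalization exactly invertible.

Default conditions: 281 training subjects aged 18–50, 121 test subjects ×
3 sessions, 100 features of latent rank 10, `age_effect_scale` −0.03 and
`noise_sd` 0.05 (training CV correlation ≈ 0.92), `motion_bias` −0.03 so
one unit of severity shifts the predicted age by about one year, and
session severity means (0, 1, 2) with SD 0.3 — giving adjusted-BAG session
contrasts of roughly +1 and +2 years, a rating slope near +0.5 years per
level, and Euler session contrasts near −0.7 and −1.5. These magnitudes
sit in the range reported for real induced-motion cohorts. Sex is
generated and stored but enters no model, matching the analysis design.

What the generator does **not** emulate: image-level artifact physics,
non-linear age trajectories, site/scanner effects, age-dependent motion
prevalence (severity is independent of age by construction, which is
precisely what lets the session contrasts be read as pure motion bias),
and heteroscedastic rater behaviour. Passing tests therefore demonstrate
that the *analysis chain* is correct and calibrated, not that any
particular real dataset will show these effect sizes.

## A complete run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)           # the default study conditions
res <- run_experiment(cfg, k_range = 1:20)

res$train_metrics                     # CV r, CV RMSE, selected k*
res$lmm$bag_session                   # adjusted BAG ~ session + (1 | subject)
res$lmm$bag_rating                    # adjusted BAG ~ rating + (1 | subject)
res$fdr$session                       # per-component screen, BH-corrected
res$agreement                         # intra-rater agreement statistics

# or write the full artifact bundle (model/, predictions.csv, lmm_*.json,
# fdr_*.csv, agreement.json, report.md):
run_pipeline(cfg, out_dir = "motionbag-run")
```

Real tables enter through `load_scan_table()` (TSV features keyed by
`scan_id`, CSV metadata with `subject_id`, `age`, and optionally `session`,
`rating`, `euler_raw`), after which the same functions apply unchanged.

## Numerical choices and degenerate inputs

- Zero-variance features are dropped at scaler fit with a warning and
  excluded consistently at apply time.
- PCA loading signs follow the "largest-magnitude entry positive"
  convention so serialized models are reproducible.
- CV folds are a seeded permutation into near-equal parts, shared across
  all candidate $k$; no age stratification (an option left for future
  work).
- The within-session protocol refuses duplicated subjects in the training
  session, gives training-session scans strictly out-of-fold predictions,
  and records fold bookkeeping so the no-self-prediction property is
  verifiable after the fact.
- All randomness flows from one root seed, split per stage with fixed
  offsets; identical configurations are bit-reproducible.
- Model bundles serialize to JSON at full precision and round-trip
  exactly.

## Problem sizes used in the test suite

The suite exercises the chain at sizes chosen to make Monte-Carlo checks
sharp while keeping a laptop run comfortable: 500 replicates of 100
subjects × 3 sessions for mixed-model bias/coverage, 20 seeds of the full
200-subject experiment (biased and null), 100 replicates of the
10-component screen, and 1000 random vectors against the brute-force BH
oracle. The full default experiment runs in about a second.

## Known limitations

- Only random intercepts: no random slopes, crossed effects or
  longitudinal time terms, mirroring the target design.
- The regressor interface is linear (none/L1/L2); kernel and ensemble
  regressors would attach at `train_age_model()`'s signature but are out
  of scope.
- The rating map conflates scan-to-scan and rater noise in one parameter;
  intra-rater agreement is therefore tied to the rating noise level rather
  than independently tunable.
- Euler numbers are simulated on the participant-average scale; per-
  hemisphere aggregation happens upstream of this package.
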