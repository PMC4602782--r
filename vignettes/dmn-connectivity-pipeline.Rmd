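---
title: "Seed-based DMN connectivity analysis for minimal hepatic encephalopathy: methods and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-based DMN connectivity analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Minimal hepatic encephalopathy (MHE) is the mildest form of hepatic
encephalopathy in liver cirrhosis: patients show no overt neurological
signs, and the condition is detectable only with psychometric testing such
as the number connection test A (NCT-A, seconds to completion; longer is
worse) and the digit symbol test (DST, symbols transcribed; fewer is
worse). Because psychometric tests suffer learning effects and depend on
education and eyesight, an objective imaging marker is attractive.
Resting-state fMRI offers one candidate: the default mode network (DMN), a
set of regions — medial prefrontal cortex (MPFC), posterior
cingulate/precuneus (PCC), lateral parietal cortex (LP), superior frontal
and temporal regions — whose low-frequency (0.01–0.08 Hz) BOLD
fluctuations are temporally correlated at rest. DMN coupling weakens
progressively from healthy controls through cirrhotic patients without
encephalopathy (non-HE) to MHE, which makes regional DMN connectivity
strength a candidate diagnostic discriminator between MHE and non-HE.

`dmnfc` implements this analysis as a reusable, fully tested pipeline, and
pairs it with a synthetic-cohort generator so that every inferential claim
the pipeline makes can be validated against planted ground truth.

## The analysis chain

Per subject, with a 4-D BOLD series (240 retained volumes at TR = 2 s on a
3 mm grid) and realignment-derived motion parameters:

1. **Discard** the first 10 volumes (steady-state magnetization).
2. **Motion screening**: exclude a subject whose translations exceed
   1.0 mm or rotations exceed 1.0° on any axis at any volume. Exceedance is
   *strict* — a subject at exactly the printed limit is retained, matching
   the usual "more than" phrasing of exclusion rules.
3. **Smooth** with an isotropic 8 mm FWHM Gaussian
   (σ = FWHM/(2√(2 ln 2)) per axis, converted to voxels; kernel truncated
   at 4σ and renormalized, so constants are preserved).
4. **Nuisance regression**: voxelwise OLS on intercept, the six motion
   parameters, and mean signals of CSF, white matter, and the whole brain;
   the residuals are exactly orthogonal to the design.
5. **Band-pass** 0.01–0.08 Hz with a zero-phase frequency-domain window
   (raised-cosine transitions of width 0.005 Hz; DC removed). Zero-phase
   filtering avoids temporal shifts that would bias lag-zero correlations.

Connectivity mapping uses three spherical seeds (default radius 6 mm) at
the canonical DMN coordinates MPFC (−1, 47, −4), PCC (−5, −49, 40) and left
LP (−45, −67, 36). For each seed the mean in-sphere time series is
correlated with every voxel (Pearson, lag zero), and r maps are
variance-stabilized with Fisher's transform z = atanh(r). The subject's DMN
map is the voxelwise average of the three z maps.

The group-level DMN **conjunction mask** is built from the healthy controls
only: for each seed, a voxelwise one-sample t test of z against zero across
subjects, Benjamini–Hochberg FDR selection at q = 0.05, and a membership
rule requiring a voxel to survive for **at least 2 of the 3 seeds**.
Building the mask from controls only avoids biasing patient–control
comparisons with patient-derived masks.

**A note on the sign of membership.** Network membership is defined by
significantly *positive* mean connectivity (`direction = "positive"` in
`seed_significance_mask()`). This matters: global-signal regression
re-centres the correlation distribution, leaving much of the brain with a
small but *consistently negative* correlation with any seed. A two-sided
membership rule without the sign requirement therefore admits most of the
background into the "network" once the sample is large enough — we measured
~75% of far background entering the mask on a 20-control synthetic cohort —
while the positive rule keeps the background essentially empty without
losing node coverage. Significance itself is still assessed two-sided.

Group inference runs inside the conjunction mask: a voxelwise
covariate-adjusted one-way ANOVA (`z ~ group + age + gender`, treatment
coding with controls as reference, F on (2, n−5) df), followed by post hoc
pairwise t tests restricted to significant clusters. Cluster-level
correction is Monte-Carlo (AlphaSim-style): white Gaussian fields are
smoothed to the FWHM estimated from the ANOVA residuals, standardized by
the *exact per-voxel kernel variance*, thresholded two-sided at the
cluster-forming p, and the minimum extent k is the smallest cluster size
whose null probability of occurring anywhere in the mask is ≤ α. Exact
per-voxel standardization (rather than a global SD) keeps the voxelwise
exceedance rate equal to the forming p at lattice edges too — important on
desk-scale grids where most voxels are edge voxels.

Diagnostics: per-cluster ROI mean z values per subject feed (i) Pearson
correlations with NCT-A and DST across all patients (MHE and non-HE
pooled), and (ii) ROC analysis of MHE vs non-HE with the orientation
"lower connectivity indicates disease", AUC by the trapezoidal rule (equal
to pairwise concordance with ties counted ½), and a Youden-optimal cutoff
with ties broken toward higher specificity. MHE labelling from scores uses
the conventional normative rule: abnormal = beyond 2 control SDs in the
impaired direction, with one abnormal test sufficient.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `n_discard` | 10 volumes | dummy scans removed |
| `translation_limit_mm`, `rotation_limit_deg` | 1.0 / 1.0 | strict motion-exclusion limits |
| `smooth_fwhm_mm` | 8 mm | isotropic smoothing kernel |
| `band_low_hz`, `band_high_hz` | 0.01 / 0.08 Hz | analysis band |
| seed radius | 6 mm | standard sphere for point coordinates |
| `conjunction_q` | 0.05 | FDR rate of the per-seed masks |
| `cluster_forming_p` | 0.01 (two-sided) | voxelwise threshold forming clusters |
| `alpha` | 0.05 | family-wise cluster error rate |
| `n_iterations` | 1000 | Monte-Carlo iterations |
| `connectivity` | 26 | cluster neighbourhood rule |
| `sd_multiplier` | 2 | normative abnormality rule |

The cluster-forming threshold, connectivity rule and iteration count are
deliberately configurable: published descriptions of Monte-Carlo cluster
correction often omit them, and the defaults here (0.01 two-sided,
26-neighbour, 1000 iterations) are the conservative, historically common
choices.

## The synthetic cohort

The generator (`cohort_config()`, `simulate_cohort()`) emulates the
statistical structure of a three-group resting-state study:

* **Acquisition**: 250 volumes at TR 2 s, 10 discarded, 3 mm isotropic
  voxels.
* **Grid**: 24 × 44 × 24 voxels with origin (−60, −76, −22) mm — a compact
  field of view chosen so that all three canonical seed spheres plus
  surrogate SFG and bilateral MTG nodes fit inside with a margin. (A full
  MNI grid would multiply compute by ~20 with no added validity; because
  the grid is left-lateralized, the right-MTG surrogate sits near the
  midline edge at x = +3.)
* **Signal model**: every voxel of every DMN node carries
  √ρ·n(t) + √(1−ρ)·u_v(t), where n(t) is a shared band-limited
  (0.01–0.08 Hz) Gaussian network signal and u_v(t) a voxel-unique
  band-limited signal, the sum rescaled to unit variance. Band-limited
  construction means the planted correlation ρ survives the pipeline's own
  band-pass essentially unchanged. Planted ρ defaults to 0.6 / 0.45 / 0.3
  for HC / non-HE / MHE (the published group ordering without published
  effect sizes leaves these as free simulator parameters), with
  between-subject jitter of SD 0.05.
* **Noise and confounds**: unit-SD broadband Gaussian noise (SNR 1 against
  the network signal), per-voxel linear drift, and two spatially weighted
  shared nuisance signals (0.12 Hz "respiratory" and 0.005 Hz slow sway,
  both outside the analysis band) that the global-mean regressor picks up.
  Motion traces are AR(1) with innovation SD 0.03 mm/°, staying well below
  the exclusion limits unless an outlier is injected deliberately.
* **Neuropsych coupling**: NCT-A mean decreases and DST mean increases
  linearly with the subject's planted connectivity
  (NCT-A = 90 − 80ρ ± 6 s; DST = 20 + 40ρ ± 3), encoding
  "longer time = worse" and "lower score = worse". With the default groups
  this yields control-like NCT-A ≈ 42 s and DST ≈ 44, and MHE-like ≈ 66 s
  and ≈ 32.
* **Determinism**: every subject is generated under a seed mixed from
  (`master_seed`, `subject_seed`), making whole studies bit-reproducible.

What the generator does **not** emulate: hemodynamic response shapes,
cardiac/respiratory aliasing structure, susceptibility dropout, anatomical
tissue geometry (CSF/WM are corner blocks, the whole grid is "brain"), or
multi-site effects. Passing tests therefore demonstrate the statistical
correctness of the pipeline under its own model assumptions — planted
effects are recovered, error rates are controlled — not robustness to every
artifact of real scanner data.

## Validation design and problem sizes

The test suite validates each stage against independent oracles
(brute-force Benjamini–Hochberg, pairwise-concordance AUC, flood-fill
clustering, `lm()`-based voxelwise model fits, an independent Monte-Carlo
implementation of the cluster-extent null), and the statistical guarantees
end to end:

* **Family-wise error**: 200 fully null cohorts (equal ρ in all groups,
  12³ grid, 8 subjects per group, full-length acquisition) are pushed
  through simulation → preprocessing → connectivity mapping → corrected
  ANOVA over the whole brain mask; the fraction of cohorts with any
  significant corrected cluster must lie inside the 95% binomial envelope
  of α = 0.05. The whole-brain analysis mask is used here (the same mask
  the Monte-Carlo null is computed on); the control-derived conjunction
  mask remains the default for scientific runs.
* **Parameter recovery**: one cohort of 20 subjects per group on the
  default grid; significant clusters must sit on the planted nodes, ROI
  means must order HC > non-HE > MHE, the conjunction mask must cover ≥90%
  of node voxels while background beyond one smoothing FWHM stays out, and
  the observed MHE-vs-non-HE AUC must match the Gaussian separation
  Φ(d/√2) computed from the realized ROI values within ±0.05.

These problem sizes (12³ null grids, one 24 × 44 × 24 recovery cohort,
1000-iteration Monte-Carlo) keep the whole validation suite at
minutes-scale on a single CPU while leaving every stage's sample sizes
large enough for the statistical claims being checked.

## Numerical choices and degenerate inputs

* Correlations of zero-variance voxels are missing (`NA`), and missingness
  propagates: a voxel missing for any subject is excluded from group tests.
* |r| = 1 maps to `NA` under the Fisher transform, with a warning.
* Voxels fitted exactly by the group model (e.g. identical values across
  subjects) get F = 0 / t = 0 by definition rather than 0/0.
* The band-pass is implemented as a cached linear operator (the
  frequency-domain window materialized once per series length), applied as
  one matrix product per subject; it is bit-equivalent to the FFT route.
* Cluster labelling is compiled (flood fill in C++); the smoothness
  estimator is the classical first-difference estimator
  FWHM = d·√(−2 ln 2 / ln r₁) with r₁ = 1 − var(Δ)/(2 var), clipped below
  at the voxel size; constant residual maps raise a named error.
* Rotations are screened in degrees as given; no radian auto-detection is
  attempted (silent unit guessing is a correctness hazard).
* Regression precedes filtering, following the order in which the
  preprocessing steps are conventionally described; this is a known
  sensitivity point and the stages are exposed individually for anyone who
  wants the other order.

## Known limitations

* Seed-level significance for the conjunction mask is assessed at the
  group level (one-sample t across subjects), not per subject; with small
  reference groups (< ~6 controls) the mask can be empty, and the
  analysis aborts with a named error rather than silently testing nothing.
* The Monte-Carlo null assumes a stationary Gaussian random field with the
  estimated smoothness; heavy-tailed residuals or strongly non-stationary
  smoothness would degrade its calibration.
* The ROC analysis reports apparent (in-sample) performance; no
  cross-validation or confidence intervals are provided.
* The synthetic phantom's tissue masks are schematic; the pipeline accepts
  caller-supplied masks for real data but performs no segmentation or
  spatial normalization itself — inputs are assumed already in a common
  space.
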