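---
title: "Lesion loads and outcome stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion loads and outcome stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionload)
```

# The problem

After a left-hemisphere stroke, the degree of chronic speech-fluency and
naming impairment varies widely, and raw lesion volume is a mediocre
predictor of it. A better surrogate combines lesion *site* and *size*: the
**lesion load** of a speech-relevant structure, defined as the
probability-weighted volume (in cc) of the intersection between a
patient's binary lesion mask and a canonical probabilistic map of that
structure. The structure of primary interest is the left arcuate
fasciculus (AF), the dorsal white-matter tract linking temporal, parietal
and inferior frontal language regions; comparison maps cover functional
gray matter active during overt speech (fGM), the combined AF+fGM map,
and the ventral-stream extreme capsule (EMC) and uncinate fasciculus
(UF).

This package implements the full analysis chain as tested, reusable
components: canonical-map construction, lesion-load computation, outcome
regressions, and severity stratification, plus a synthetic-data generator
that makes every stage testable without patient data.

# Canonical maps and the lesion-load statistic

Per-subject binary maps (binarized tractography output or thresholded
activation maps, already normalized to a common 2 mm grid) are summed
voxelwise over N healthy controls (N = 12 in the reference study). The
count $I(v) \in \{0, \dots, N\}$ at voxel $v$ gives the probability
$I(v)/N$ that the voxel belongs to the structure. For a binary lesion
mask $L$,

$$\mathrm{LL} = \sum_{v\,:\,L(v) = 1} \frac{I(v)}{N}\, v_{cc},$$

where $v_{cc}$ is the voxel volume in cc (0.008 cc on the default
2 mm isotropic grid). A lesion covering only consensus voxels
($I = N$) contributes its full volume; marginal voxels contribute
proportionally. The statistic is bounded by both the lesion volume and
the map's probability-weighted volume, is monotone under lesion growth,
and is additive over disjoint lesions — all verified as properties
against a brute-force voxel-loop oracle.

Choices worth noting:

* **Percentile thresholding** of pre-binarization tract volumes uses the
  percentile of the *nonzero* value distribution (linear-interpolation
  convention, retention rule $\ge$, with a $10^{-8}$-relative tolerance
  so the limit "percentile $\to 0$ keeps every nonzero voxel" holds in
  floating point). A percentile over all voxels of a mostly-zero tract
  volume would be meaningless; trimming is intended within the tract.
  Thresholding is applied per subject, before binarization.
* **Combined maps** sum per-voxel probabilities capped at 1
  ($p = \min(1, p_A + p_B)$, stored as $\mathrm{round}(pN)$ counts).
  Plain count addition would produce "probabilities" above 1; the capped
  sum is the closest well-defined reading and keeps the lesion-load
  formula interpretable. Reference tables of combined loads are not, in
  general, reproducible from their AF and fGM columns, so no consistency
  rule ties the three columns together.
* **No resampling.** Every cross-volume operation requires an exact grid
  match (shapes identical, affines within $10^{-4}$ mm). Registration is
  an upstream concern; silent resampling would hide registration errors.
* Nearly-binary float masks binarize at 0.5, robust to interpolation
  artifacts.

# Outcome regressions

Behavioral outcomes are conversational speech efficiency (CIUs/min),
speech rate (Words/min), and the 15-item Boston Naming Test (0–15).
Single-load models regress an outcome on one lesion-load column plus age
and months-post-stroke covariates by ordinary least squares. Because
lesion load is volumetric, fluency models enter predictors through a
cube-root transform, which linearizes the load-outcome relationship and
stabilizes variance; naming relates linearly to load, so BNT models use
untransformed predictors. This transform policy is applied to
predictors, never outcomes.

**Outlier handling** is a single pass: fit, drop cases with internally
studentized residual beyond ±2.5 SD, refit once. No iteration. On the
packaged reference cohort this removes one case (CIUs/min model) and
none elsewhere. When the residual standard error is numerically zero
(noiseless synthetic data) the pass is skipped — every standardized
residual would be 0/0.

**Partial correlations** are computed per term from the refitted model as
$r = t/\sqrt{t^2 + \mathrm{df}}$ with the coefficient's sign, which
equals the correlation between the outcome residuals and predictor
residuals after regressing both on all other terms (a test verifies this
equivalence). P-values are two-sided and uncorrected.

**Dorsal–ventral comparison.** The multi-load model regresses an outcome
on AF, EMC and UF loads controlling for total lesion volume (which, being
volumetric, shares the predictors' cube-root transform for fluency
outcomes). This model deliberately uses *all* complete cases, with no
outlier pass: applying the ±2.5 SD pass to this design removes
high-leverage cases in a way that manufactures spurious ventral-tract
significance while halving the AF partial correlation, reversing the
model's qualitative conclusion. The single readout of this model is the
set of per-load partial correlations.

# Severity stratification

**Two-group clustering.** Each behavioral score is split into severe
(lower-scoring) and non-severe groups by exhaustive search over the
$n-1$ interval splits of the sorted scores, minimizing total
within-group sum of squares. For one variable and two groups this is the
exact global optimum of the k-means criterion — an independent k-means
run from both extreme initializations confirms it in tests — and it
removes any seed or ordering dependence that a heuristic streaming
cluster algorithm would introduce. The reported "cutoff band" is the
open interval between the maximum severe and minimum non-severe score.
When published cutoff bands are evaluated directly, `severityFromCutoff`
labels severe every score less than or equal to the band's lower
endpoint (the band's own definition).

**Discriminant accuracy.** A linear discriminant (pooled within-group
variance, priors proportional to group sizes) is fit to the score
against its cluster labels, and its resubstitution accuracy quantifies
how cleanly the cutoff separates the distribution. Resubstitution, not
cross-validation, is the reported quantity by design.

**ROC analysis.** A lesion-load predictor is evaluated against the
severity labels over all decision thresholds; severe is predicted when
the load is at or above threshold (larger load, worse outcome).
Candidate thresholds are midpoints between consecutive distinct
predictor values, plus sentinels below and above the data — the midpoint
convention reproduces published clinical thresholds such as 3.74 cc,
which is exactly the midpoint of two adjacent observed AF loads (3.70
and 3.78 cc). AUC is computed by the trapezoidal rule and equals the
normalized Mann–Whitney U statistic with ties counted half (verified
property). The reported threshold maximizes Youden's
$J = \mathrm{sens} + \mathrm{spec} - 1$; ties break toward higher
specificity. Accuracy at threshold is the raw (unbalanced) proportion
correct. In `stratify()`, a load exactly at threshold is called severe:
for a screening rule the boundary goes to the worse group.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not brain physiology:

* **Tract tubes**: per-subject binary tubes of configurable radius
  around a polyline centerline, with per-subject truncated-normal jitter
  (SD 2 mm by default, clamped at 3 SD so tubes provably stay inside the
  grid) applied to the control points. Aggregation yields a graded map
  with a high-agreement core.
* **Activation blobs**: unions of jittered spheres at cortical nodes,
  intersected with an ellipsoidal-shell gray-matter mask.
* **Lesions**: grown voxel-by-voxel from a seed point by random-priority
  flood fill (each voxel receives an i.i.d. uniform priority; the
  lowest-priority frontier voxel is absorbed until the target volume is
  reached). Masks are 6-connected with irregular, non-convex boundaries,
  which exercises the overlap code far better than ellipsoids. The
  growth kernel is implemented in C++ with a priority queue.
* **Outcomes**: `max(0, beta0 + beta1 * LL^(1/3) + e)` per measure with
  `beta1 < 0`; BNT is rounded and capped at 15, CIUs/min capped at
  Words/min. An optional severe-regime intercept shift (default 0)
  produces explicitly bimodal severity. All floors and caps are recorded
  in the generated truth so calibration studies can account for
  censoring.
* **Severity mixture**: a configurable fraction of patients receives
  large lesions seeded on the tract; the rest receive small off-tract
  lesions.

Default outcome coefficients for the `"cohort"` preset
(`beta0` 45/70/15, `beta1` −19/−26/−5.5, `sigma` 8/12/2.5 for
CIUs/min, Words/min, BNT) were chosen once so that a load-free patient
sits near the healthy-floor of the observed chronic-aphasia score ranges
and the largest loads approach zero scores; they are study conditions,
not tuning knobs. One master seed drives separate child streams (maps,
activations, demographics, lesions, outcome noise), so each stage is
independently reproducible and bit-identical under a fixed seed.

What the generator does **not** emulate: biophysical tractography,
perfusion, right-hemisphere homologs, lesion-induced remote effects, or
the measurement process behind transcription-based fluency scores.
Passing tests on synthetic data therefore validate the *computational*
chain — overlap arithmetic, regression recovery, stratification — not
clinical validity on real cohorts.

# Problem sizes used in the test suite

Deterministic desk-scale statistics run on the packaged 50-patient
table. Property-based checks use: 100 random grids up to $32^3$ for the
brute-force load oracle; 30 cohort-sized instances for the AUC/U
equivalence; and a slope-recovery study of 100 replicate cohorts of
n = 200 on the `"compact"` preset (maps built once and shared across
replicates, which the seed hierarchy makes legitimate), requiring mean
bias of the fitted lesion-load slope below 5 % of truth. The compact
geometry keeps the full suite in the minutes range on one CPU.

# Known limitations

* Two-step streaming cluster analysis (an SPSS heuristic) is replaced by
  the exact 1-D split; on real data the two can disagree about the
  cutoff band, and published bands from such software need not coincide
  with the exact optimum.
* The ±2.5 SD outlier rule identifies cases by refitting once; which
  cases are flagged can differ from other software's case-wise
  diagnostics at the margin, moving single-model $R^2$ in the second
  decimal.
* Lesion masks are treated as given; drawing conventions (e.g. exclusion
  of ventricular dilation) are upstream manual steps with no algorithmic
  counterpart here.
* ROC operating points on 50 patients are step functions: accuracy,
  sensitivity and specificity move in 2 % jumps, so small labeling
  differences shift them visibly even when AUC barely moves.

# A worked run

```{r example, eval = FALSE}
coh <- cohortFixture()
part <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
roc <- rocAnalysis(coh$af_ll_cc, part)
fit <- fitModel(coh, regressionSpec("cius_per_min", "af_ll_cc"))
list(band = cutoffBand(part), auc = auc(roc),
     threshold_cc = thresholdCc(roc), r_squared = rSquared(fit))
```

The end-to-end pipeline (`runFullAnalysis()`) writes `regressions.csv`,
`stratification.csv`, per-curve ROC points and a run log with seed and
version, and refuses to overwrite a non-empty output directory unless
forced; reruns with the same configuration are file-for-file identical.
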