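# lesionload

Voxel-based lesion-load analysis for chronic post-stroke aphasia, in R.

After a left-hemisphere stroke, how severely speech fluency and naming
remain impaired depends less on how *big* the lesion is than on *what*
it hits. This package implements the lesion-load approach for
researchers and clinicians who want a reproducible pipeline from
volumetric imaging to outcome stratification: it builds canonical
probabilistic maps of speech-relevant structures (the arcuate
fasciculus AF, speech-task functional gray matter fGM, their
combination, and the ventral-stream EMC and UF tracts) from
per-subject binary maps, scores each patient's lesion against them,
and relates the scores to behavioral outcomes.

The central statistic is the probability-weighted overlap volume

```
LL = Σ_{v : lesion(v)=1}  I(v)/N · v_cc        [cc]
```

where `I(v)` counts how many of `N` healthy-control subjects' binarized
maps contain voxel `v`, and `v_cc` is the voxel volume (0.008 cc at
2 mm isotropic). Around it the package provides:

* **Volumetric core** — NIfTI I/O (`readVolume`, `writeVolume`), strict
  grid compatibility, S4 classes for intensity/binary volumes, lesion
  masks and probabilistic maps.
* **Canonical mapping** — within-tract percentile thresholding,
  subject-map aggregation, gray-matter masking, capped-sum map
  combination.
* **Lesion loads** — `computeLesionLoad`, `batchLesionLoads`, in cc.
* **Cohort statistics** — cube-root single-load regressions with
  covariates and a ±2.5 SD studentized-residual outlier pass
  (`fitModel`), dorsal–ventral multi-load comparison with partial
  correlations (`fitDorsalVentralComparison`).
* **Stratification** — exact 1-D two-group clustering
  (`twoGroupCluster`), linear-discriminant resubstitution accuracy,
  ROC with Youden-optimal thresholds (`rocAnalysis`), and the ~4 cc
  AF-load severity rule (`stratify`).
* **Synthetic data** — tract tubes, activation blobs, flood-fill
  lesions and cohorts with known outcome models (`syntheticConfig`,
  `generateCohort`, `writeSyntheticStudy`), so the whole chain is
  testable without patient data.
* **Pipeline** — `runFullAnalysis()` orchestrates maps → loads →
  regressions → stratification with a fixed output layout;
  `inst/scripts/lesionload.R` is a thin command-line wrapper.

A 50-patient chronic-aphasia reference cohort ships with the package
(`cohortFixture()`), so all desk-scale statistics are reproducible
offline.

## Worked example

```r
library(lesionload)
coh  <- cohortFixture()                                  # 50 patients
part <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
part
#> SeverityPartition of cius_per_min: 39 severe / 11 non-severe, cutoff band (19, 23.3)

roc <- rocAnalysis(coh$af_ll_cc, part)
roc
#> RocResult: AUC 0.950, threshold 3.74 (sens 0.872, spec 0.909, acc 0.880)

fit <- fitModel(coh, regressionSpec("cius_per_min", "af_ll_cc"))
fit
#> RegressionFit: cius_per_min ~ af_ll_cc + age_years + months_post_stroke
#>   transform cube_root, R^2 = 0.646 (adj 0.623), model p = 3.08e-10, n = 49
#>   excluded outliers: 2

stratify(c(9.75, 0.07), thresholdCc(roc))
#> [1] "severe"     "non_severe"
```

Reading: the automatic cluster split separates 39 severely impaired
speakers (≤ 19 correct information units per minute) from 11 with
non-severe fluency; AF lesion load separates the groups with AUC 0.95
and an optimal decision threshold of 3.74 cc — a patient with an AF
load of 9.75 cc falls in the severe group, one with 0.07 cc does not.
The cube-root regression explains ~65 % of the variance in speech
efficiency after controlling for age and time post-stroke (one outlier
excluded by the residual rule).

The full pipeline over the same cohort:

```r
runFullAnalysis(runConfig(
  cohortCsv = system.file("extdata", "reference_cohort.csv",
                          package = "lesionload"),
  outDir = "results/run1"))
```

writes `regressions.csv`, `stratification.csv`, `roc_points/*.csv` and
a `run.json` log.

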