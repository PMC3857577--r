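Package: lesionload
Title: Probabilistic Tract Lesion Loads and Outcome Stratification in
    Chronic Post-Stroke Aphasia
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for voxel-based lesion-load analysis of chronic
    post-stroke aphasia. Builds canonical probabilistic maps of
    speech-relevant white-matter tracts (arcuate fasciculus, extreme
    capsule, uncinate fasciculus) and functional gray matter from
    per-subject binary maps, computes probability-weighted lesion-overlap
    loads in cc for patient lesion masks, regresses fluency and naming
    outcomes on lesion loads with cube-root predictor transforms and
    studentized-residual outlier screening, and stratifies patients into
    severe and non-severe outcome groups by exact one-dimensional
    two-group clustering, linear discriminant resubstitution, and ROC
    threshold selection. Includes a synthetic-data generator producing
    tract tubes, activation blobs, flood-fill lesion masks, and cohorts
    with known outcome models, so every analysis stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    MASS,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
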