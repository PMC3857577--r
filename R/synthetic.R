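#' Synthetic study configuration
#'
#' Bundles every parameter of the synthetic-data generator, which emulates
#' the inputs the analysis expects: per-subject binary tract "tubes" and
#' activation "blobs" from a healthy-control group, left-hemisphere lesion
#' masks of varying size and site, and behavioral outcomes that decrease
#' monotonically in the cube root of the AF lesion load with a bimodal
#' (severe / non-severe) structure.
#'
#' Two presets are provided. `"cohort"` matches the reference study
#' conditions: a 48 x 56 x 48 grid at 2 mm, 12 map subjects, 50 patients,
#' lesion sizes spanning 12.68-297.27 cc. `"compact"` is a smaller
#' desk-scale geometry (32 x 36 x 32, lesions 0.3-6 cc) used for fast
#' simulation studies such as parameter-recovery runs; it keeps the same
#' generative structure at reduced problem size.
#'
#' The outcome model for each measure is
#' `outcome = max(0, beta0 + beta1 * LL^(1/3) + e)`, `e ~ N(0, sigma)`,
#' with `beta1 < 0` (worse outcomes with larger load). An optional
#' `severeOutcomeShift` (default 0) is added to the intercept of
#' severe-regime patients to produce explicitly bimodal severity
#' structure beyond what the lesion-size mixture induces. BNT scores are
#' additionally rounded and capped at 15, and CIUs/min is capped at
#' Words/min (an information unit is a counted word). Floored / capped
#' outcomes are recorded in the generated truth so calibration studies can
#' account for censoring.
#'
#' One integer seed drives a documented hierarchy of child streams (tract
#' maps, activation maps, demographics, lesions, outcome noise), so each
#' stage is independently reproducible.
#'
#' @param preset `"cohort"` or `"compact"` (see above).
#' @param nPatients number of patients to simulate.
#' @param severityMixture fraction of patients given large, tract-centred
#'   lesions (the severe regime).
#' @param outcomeModel named list of `c(beta0, beta1, sigma)` per measure.
#' @param seed integer master seed.
#' @param ... overrides for any other configuration field (grid shape,
#'   centerlines, radii, jitter, lesion size range, ...).
#' @return A list of class `"SyntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig("compact", nPatients = 20, seed = 7)
#' @export
syntheticConfig <- function(preset = c("cohort", "compact"),
                            nPatients = NULL,
                            severityMixture = 0.5,
                            outcomeModel = NULL,
                            seed = 1L, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "cohort") list(
    gridShape = c(48L, 56L, 48L), spacingMm = 2,
    nMapSubjects = 12L, nPatients = 50L,
    tractCenterline = rbind(c(-36, -42, -2), c(-34, -34, 14),
                            c(-32, -10, 26), c(-36, 16, 14)),
    tractRadiusMm = 4,
    emcCenterline = rbind(c(-30, -34, 4), c(-28, -2, 2), c(-30, 30, 8)),
    ufCenterline = rbind(c(-28, -2, -20), c(-26, 8, -12), c(-24, 34, -2)),
    ventralRadiusMm = 3.5,
    subjectJitterMm = 2,
    activationNodes = list(list(center = c(-32, -6, 24), radius = 8),
                           list(center = c(-34, 16, 10), radius = 8),
                           list(center = c(-34, -36, 6), radius = 7),
                           list(center = c(-4, 0, 38), radius = 7)),
    lesionSizeRangeCc = c(12.68, 297.27),
    severeOutcomeShift = 0,
    outcomeModel = list(
      cius_per_min = c(beta0 = 45, beta1 = -19, sigma = 8),
      words_per_min = c(beta0 = 70, beta1 = -26, sigma = 12),
      bnt = c(beta0 = 15, beta1 = -5.5, sigma = 2.5))
  ) else list(
    gridShape = c(32L, 36L, 32L), spacingMm = 2,
    nMapSubjects = 12L, nPatients = 50L,
    tractCenterline = rbind(c(-22, -26, -2), c(-20, -20, 10),
                            c(-19, -6, 16), c(-22, 10, 9)),
    tractRadiusMm = 3,
    emcCenterline = rbind(c(-18, -20, 2), c(-17, -2, 0), c(-18, 16, 4)),
    ufCenterline = rbind(c(-16, -2, -14), c(-15, 6, -9), c(-14, 20, -2)),
    ventralRadiusMm = 2.5,
    subjectJitterMm = 1.5,
    activationNodes = list(list(center = c(-20, -4, 14), radius = 5),
                           list(center = c(-21, 10, 6), radius = 5),
                           list(center = c(-21, -22, 4), radius = 4)),
    lesionSizeRangeCc = c(0.3, 6),
    severeOutcomeShift = 0,
    outcomeModel = list(
      cius_per_min = c(beta0 = 45, beta1 = -19, sigma = 4),
      words_per_min = c(beta0 = 70, beta1 = -26, sigma = 6),
      bnt = c(beta0 = 15, beta1 = -5.5, sigma = 1.5))
  )
  if (!is.null(nPatients)) cfg$nPatients <- as.integer(nPatients)
  if (!is.null(outcomeModel)) cfg$outcomeModel <- outcomeModel
  cfg$severityMixture <- severityMixture
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  cfg[names(dots)] <- dots
  for (b in cfg$outcomeModel)
    if (b[["beta1"]] >= 0)
      stop("outcome model slope beta1 must be negative: outcomes worsen ",
           "with lesion load")
  structure(cfg, class = "SyntheticConfig")
}

# deterministic child seeds below 2^31 so each generation stage has its
# own reproducible stream
.childSeed <- function(seed, k) {
  (as.numeric(seed) + k * 1000003) %% (2^31 - 2) + 1
}

.configGrid <- function(config) {
  VoxelGrid(config$gridShape, spacing = rep(config$spacingMm, 3))
}

# truncated-normal jitter: displacement clamped at 3 SD so tubes cannot
# leave a grid that accommodates centerline + radius + 3 SD
.jitter <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -3 * sd), 3 * sd)
}

# mark all voxels within radiusMm of a world point; strict -> error when
# the sphere is clipped by the grid boundary
.markSphere <- function(arr, grid, centerWorld, radiusMm, strict = TRUE) {
  vc <- drop(.worldToVoxel(grid, centerWorld))
  spacing <- sqrt(colSums(grid@affine[1:3, 1:3]^2))
  rv <- radiusMm / spacing
  lo <- floor(vc - rv); hi <- ceiling(vc + rv)
  if (strict && (any(lo < 0) || any(hi > grid@shape - 1L)))
    stop("geometry error: structure of radius ", radiusMm,
         " mm exits the grid at world (",
         paste(round(centerWorld, 1), collapse = ", "), ")")
  lo <- pmax(lo, 0); hi <- pmin(hi, grid@shape - 1L)
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  w <- .voxelToWorld(grid, box)
  d2 <- (w[, 1] - centerWorld[1])^2 + (w[, 2] - centerWorld[2])^2 +
    (w[, 3] - centerWorld[3])^2
  sel <- box[d2 <= radiusMm^2, , drop = FALSE]
  arr[sel + 1L] <- 1
  arr
}

# rasterize a tube of given radius around a polyline of world-mm control
# points, sampled at ~1 mm steps
.rasterTube <- function(grid, pts, radiusMm) {
  arr <- array(0, dim = grid@shape)
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts[s, ]; b <- pts[s + 1L, ]
    len <- sqrt(sum((b - a)^2))
    nstep <- max(2L, ceiling(len))
    for (t in seq(0, 1, length.out = nstep)) {
      arr <- .markSphere(arr, grid, a + t * (b - a), radiusMm,
                         strict = TRUE)
    }
  }
  arr
}

#' Generate per-subject binary tract maps
#'
#' Simulates the binarized output of per-subject tractography: for each of
#' `nMapSubjects` control subjects, the tract centerline control points are
#' displaced by independent truncated-normal jitter (SD
#' `subjectJitterMm`, clamped at 3 SD) and a tube of radius
#' `tractRadiusMm` is rasterized around the jittered polyline. With zero
#' jitter all subjects produce the identical tube; with positive jitter the
#' aggregated map has a high-agreement core and graded margins.
#'
#' @param config a [syntheticConfig()].
#' @param centerline optional replacement centerline (world-mm control
#'   points, one per row); defaults to the config tract centerline.
#' @param radiusMm optional replacement tube radius.
#' @param seedOffset child-stream offset (distinct structures use distinct
#'   offsets so their jitters are independent).
#' @return List of `nMapSubjects` [BinaryVolume] objects.
#' @export
generateSubjectTractMaps <- function(config,
                                     centerline = config$tractCenterline,
                                     radiusMm = config$tractRadiusMm,
                                     seedOffset = 1L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  grid <- .configGrid(config)
  set.seed(.childSeed(config$seed, seedOffset))
  lapply(seq_len(config$nMapSubjects), function(s) {
    pts <- centerline +
      matrix(.jitter(length(centerline), config$subjectJitterMm),
             nrow = nrow(centerline))
    BinaryVolume(.rasterTube(grid, pts, radiusMm), grid)
  })
}

#' Generate per-subject activation maps
#'
#' Simulates binarized, thresholded speech-task activation maps: per
#' subject, a union of spherical blobs at the configured activation nodes
#' with jittered centers. Blobs may be clipped by the grid boundary
#' (cortical nodes lie near the brain edge).
#'
#' @inheritParams generateSubjectTractMaps
#' @return List of [BinaryVolume] objects.
#' @export
generateSubjectActivationMaps <- function(config, seedOffset = 2L) {
  stopifnot(inherits(config, "SyntheticConfig"))
  grid <- .configGrid(config)
  set.seed(.childSeed(config$seed, seedOffset))
  lapply(seq_len(config$nMapSubjects), function(s) {
    arr <- array(0, dim = grid@shape)
    for (node in config$activationNodes) {
      ctr <- node$center + .jitter(3, config$subjectJitterMm)
      arr <- .markSphere(arr, grid, ctr, node$radius, strict = FALSE)
    }
    BinaryVolume(arr, grid)
  })
}

#' Synthetic gray-matter mask
#'
#' An ellipsoidal shell (outer brain ellipsoid minus a scaled inner core)
#' standing in for a standard gray-matter mask: activation blobs near the
#' cortical surface intersect it, deep white matter does not.
#'
#' @param config a [syntheticConfig()].
#' @param innerScale relative size of the white-matter core (default
#'   0.55).
#' @return A [BinaryVolume].
#' @export
syntheticGrayMatterMask <- function(config, innerScale = 0.55) {
  grid <- .configGrid(config)
  half <- (grid@shape - 1) / 2 * config$spacingMm
  idx <- as.matrix(expand.grid(i = seq_len(grid@shape[1]) - 1L,
                               j = seq_len(grid@shape[2]) - 1L,
                               k = seq_len(grid@shape[3]) - 1L))
  w <- .voxelToWorld(grid, idx)
  r2 <- (w[, 1] / half[1])^2 + (w[, 2] / half[2])^2 + (w[, 3] / half[3])^2
  inner <- r2 / innerScale^2
  arr <- array(0, dim = grid@shape)
  arr[idx + 1L] <- as.numeric(r2 <= 1 & inner > 1)
  BinaryVolume(arr, grid)
}

#' Grow a synthetic lesion mask
#'
#' Grows a 6-connected lesion region voxel-by-voxel from a seed point by
#' random-priority flood fill: every voxel receives an i.i.d. uniform
#' priority and the frontier voxel with the smallest priority is absorbed
#' at each step until the region reaches the target volume (within one
#' voxel). Random priorities give irregular, non-convex boundaries like
#' real infarcts, which exercises the overlap code far better than
#' ellipsoids would.
#'
#' @param config a [syntheticConfig()].
#' @param targetCc target lesion volume in cc.
#' @param centerWorld seed point in world mm.
#' @param seed integer seed for the priority field.
#' @return A [LesionMask] with `patientId = "synthetic"`.
#' @export
generateLesionMask <- function(config, targetCc, centerWorld, seed) {
  stopifnot(inherits(config, "SyntheticConfig"), targetCc > 0)
  grid <- .configGrid(config)
  vvc <- grid@voxelVolumeCc
  nTarget <- as.integer(ceiling(targetCc / vvc - 1e-9))
  vc <- round(drop(.worldToVoxel(grid, centerWorld)))
  if (any(vc < 0) || any(vc > grid@shape - 1L))
    stop("geometry error: lesion seed point outside the grid")
  if (nTarget > prod(grid@shape))
    stop("geometry error: target lesion volume exceeds the grid")
  set.seed(seed)
  pri <- stats::runif(prod(grid@shape))
  start <- 1L + vc[1] + grid@shape[1] * (vc[2] + grid@shape[2] * vc[3])
  idx <- grow_region_cpp(as.integer(grid@shape), as.integer(start),
                         nTarget, pri)
  arr <- array(0, dim = grid@shape)
  arr[idx] <- 1
  LesionMask(arr, grid, "synthetic")
}

# point at parameter t in [0,1] along a polyline (by arc length)
.polylinePoint <- function(pts, t) {
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  target <- t * cum[length(cum)]
  s <- max(1L, findInterval(target, cum, rightmost.closed = TRUE))
  s <- min(s, nrow(pts) - 1L)
  frac <- (target - cum[s]) / seg[s]
  pts[s, ] + frac * (pts[s + 1L, ] - pts[s, ])
}

#' Build the canonical map set for a synthetic study
#'
#' Aggregates per-subject tubes/blobs into the five canonical maps used by
#' the analysis: AF, fGM (gray-matter masked), combined AF+fGM, EMC and
#' UF.
#'
#' @param config a [syntheticConfig()].
#' @return Named list of [ProbabilisticMap] objects.
#' @export
generateCanonicalMaps <- function(config) {
  af <- aggregateSubjectMaps(generateSubjectTractMaps(config), "AF")
  fgm <- maskGrayMatter(
    aggregateSubjectMaps(generateSubjectActivationMaps(config), "fGM"),
    syntheticGrayMatterMask(config))
  emc <- aggregateSubjectMaps(
    generateSubjectTractMaps(config, centerline = config$emcCenterline,
                             radiusMm = config$ventralRadiusMm,
                             seedOffset = 3L), "EMC")
  uf <- aggregateSubjectMaps(
    generateSubjectTractMaps(config, centerline = config$ufCenterline,
                             radiusMm = config$ventralRadiusMm,
                             seedOffset = 4L), "UF")
  list(AF = af, fGM = fgm, `AF+fGM` = combineMaps(af, fgm),
       EMC = emc, UF = uf)
}

#' Generate a complete synthetic cohort
#'
#' Produces a full synthetic study: canonical maps, per-patient lesion
#' masks, lesion loads (computed with [computeLesionLoad()], so the cohort
#' table is exactly self-consistent with the stored volumes), and
#' behavioral outcomes drawn from the configured outcome models. A
#' `severityMixture` fraction of patients receives large lesions seeded on
#' the tract centerline (the severe regime); the rest receive small
#' lesions seeded in an off-tract anterior-ventral site.
#'
#' @param config a [syntheticConfig()].
#' @param maps optional precomputed map set from [generateCanonicalMaps()]
#'   (the maps depend only on the config, so simulation studies can build
#'   them once and reuse them across replicate cohorts).
#' @return A list of class `"SyntheticCohort"` with elements `cohort`
#'   (data.frame in the standard schema), `lesionMasks` (named list of
#'   [LesionMask]), `maps`, and `truth` (generating parameters, per-patient
#'   regimes and target sizes, and censoring records).
#' @export
generateCohort <- function(config, maps = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(maps)) maps <- generateCanonicalMaps(config)
  n <- config$nPatients
  grid <- .configGrid(config)

  set.seed(.childSeed(config$seed, 5L))  # demographics stream
  gender <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.2, 0.8))
  age <- round(pmin(pmax(stats::rnorm(n, 55, 11), 25), 80))
  months <- round(6 + stats::rexp(n, rate = log(2) / 10), 0)

  set.seed(.childSeed(config$seed, 6L))  # lesion stream
  k <- round(config$severityMixture * n)
  severe <- sample(rep(c(TRUE, FALSE), c(k, n - k)))
  lo <- config$lesionSizeRangeCc[1]; hi <- config$lesionSizeRangeCc[2]
  targets <- ifelse(severe,
                    lo + (0.4 + 0.6 * stats::runif(n)) * (hi - lo),
                    lo + 0.25 * stats::runif(n) * (hi - lo))
  centers <- matrix(0, n, 3)
  half <- (grid@shape - 1) / 2 * config$spacingMm
  for (i in seq_len(n)) {
    centers[i, ] <- if (severe[i]) {
      .polylinePoint(config$tractCenterline, stats::runif(1)) +
        .jitter(3, 2)
    } else {
      # anterior-ventral, off the dorsal tract
      .polylinePoint(config$ufCenterline, stats::runif(1)) + .jitter(3, 3)
    }
    centers[i, ] <- pmin(pmax(centers[i, ], -0.9 * half), 0.9 * half)
  }
  lesionSeeds <- sample.int(2^31 - 2, n)
  lesions <- vector("list", n)
  ids <- sprintf("S%02d", seq_len(n))
  for (i in seq_len(n)) {
    les <- generateLesionMask(config, targets[i], centers[i, ],
                              seed = lesionSeeds[i])
    les@patientId <- ids[i]
    lesions[[i]] <- les
  }
  names(lesions) <- ids

  loadOf <- function(les, map) computeLesionLoad(les, map)$load_cc
  af <- vapply(lesions, loadOf, 0, maps$AF)
  fgm <- vapply(lesions, loadOf, 0, maps$fGM)
  affgm <- vapply(lesions, loadOf, 0, maps$`AF+fGM`)
  emc <- vapply(lesions, loadOf, 0, maps$EMC)
  uf <- vapply(lesions, loadOf, 0, maps$UF)
  lesvol <- vapply(lesions, computeLesionVolume, 0)

  set.seed(.childSeed(config$seed, 7L))  # outcome noise stream
  cr <- cubeRoot(af)
  shift <- config$severeOutcomeShift * severe
  draw <- function(b) b[["beta0"]] + shift + b[["beta1"]] * cr +
    stats::rnorm(n, 0, b[["sigma"]])
  ciusRaw <- draw(config$outcomeModel$cius_per_min)
  wordsRaw <- draw(config$outcomeModel$words_per_min)
  bntRaw <- draw(config$outcomeModel$bnt)
  words <- pmax(0, wordsRaw)
  cius <- pmin(pmax(0, ciusRaw), words)
  bnt <- pmin(pmax(0, round(bntRaw)), 15)
  censored <- data.frame(
    patient_id = ids,
    cius_floored = ciusRaw < 0, cius_capped = ciusRaw > words,
    words_floored = wordsRaw < 0,
    bnt_floored = bntRaw < 0, bnt_capped = bntRaw > 15,
    stringsAsFactors = FALSE)

  cohort <- data.frame(
    patient_id = ids, gender = gender, age_years = age,
    months_post_stroke = months, bnt = bnt,
    words_per_min = words, cius_per_min = cius,
    lesion_volume_cc = lesvol, af_ll_cc = af, fgm_ll_cc = fgm,
    af_fgm_ll_cc = affgm, emc_ll_cc = emc, uf_ll_cc = uf,
    stringsAsFactors = FALSE)

  structure(list(
    cohort = cohort, lesionMasks = lesions, maps = maps,
    truth = list(config = config, severe = stats::setNames(severe, ids),
                 targetCc = stats::setNames(targets, ids),
                 outcomeModel = config$outcomeModel,
                 censored = censored)),
    class = "SyntheticCohort")
}

#' Write a synthetic study to disk
#'
#' Materializes a generated study as files: canonical maps (NIfTI +
#' sidecar JSON), the gray-matter mask, per-patient lesion masks, the
#' cohort CSV in the standard schema, and the generating truth as JSON.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if needed).
#' @param force overwrite an existing non-empty directory.
#' @return The generated `"SyntheticCohort"`, invisibly.
#' @export
writeSyntheticStudy <- function(config, dir, force = FALSE) {
  if (dir.exists(dir) && length(dir(dir)) && !force)
    stop("output directory ", dir, " is not empty; use force = TRUE")
  dir.create(file.path(dir, "maps"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "lesions"), showWarnings = FALSE)
  study <- generateCohort(config)
  for (nm in names(study$maps))
    writeProbabilisticMap(study$maps[[nm]],
                          file.path(dir, "maps",
                                    paste0(gsub("\\+", "_", nm), ".nii.gz")))
  writeVolume(syntheticGrayMatterMask(config),
              file.path(dir, "maps", "gm_mask.nii.gz"))
  for (nm in names(study$lesionMasks))
    writeVolume(study$lesionMasks[[nm]],
                file.path(dir, "lesions", paste0(nm, ".nii.gz")))
  utils::write.csv(study$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  truth <- study$truth
  truth$config <- unclass(truth$config)
  truth$config$activationNodes <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(study)
}
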