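#' @useDynLib lesionload, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

.AFFINE_TOL <- 1e-4

#' VoxelGrid: geometry of a volumetric image
#'
#' A `VoxelGrid` pairs an array shape with a 4x4 voxel-to-world affine
#' (NIfTI sform convention, mm units, 0-based voxel indices) and caches the
#' voxel volume in cc. All cross-volume operations in the package require an
#' exact grid match; no resampling is ever performed.
#'
#' @slot shape integer(3), voxels per axis.
#' @slot affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @slot voxelVolumeCc volume of one voxel in cc,
#'   `abs(det(affine[1:3, 1:3])) / 1000`.
#'
#' @param shape integer(3) array extents.
#' @param affine 4x4 voxel-to-world matrix. If `NULL`, an axis-aligned
#'   MNI-like affine is built from `spacing`, with negative x scale and the
#'   world origin at the grid centre.
#' @param spacing numeric(3) voxel edge lengths in mm (default 2 mm
#'   isotropic, so 0.008 cc per voxel).
#' @return A `VoxelGrid` object.
#' @examples
#' g <- VoxelGrid(c(8, 8, 8))
#' voxelVolumeCc(g)   # 0.008
#' @export
VoxelGrid <- function(shape, affine = NULL, spacing = c(2, 2, 2)) {
  shape <- as.integer(shape)
  if (is.null(affine)) {
    spacing <- rep_len(as.numeric(spacing), 3L)
    affine <- diag(c(-spacing[1], spacing[2:3], 1))
    # origin at grid centre, MNI-like orientation (x decreasing with index)
    affine[1:3, 4] <- -affine[1:3, 1:3] %*% ((shape - 1) / 2)
  }
  affine <- unname(as.matrix(affine))
  new("VoxelGrid", shape = shape, affine = affine,
      voxelVolumeCc = abs(det(affine[1:3, 1:3])) / 1000)
}

setClass("VoxelGrid",
  representation(shape = "integer", affine = "matrix",
                 voxelVolumeCc = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@shape) != 3L || any(object@shape < 1L) ||
        anyNA(object@shape))
      msg <- c(msg, "shape must be three positive integers")
    a <- object@affine
    if (!is.numeric(a) || !identical(dim(a), c(4L, 4L)) || anyNA(a))
      msg <- c(msg, "affine must be a finite 4x4 numeric matrix")
    else {
      if (max(abs(a[4, ] - c(0, 0, 0, 1))) > .AFFINE_TOL)
        msg <- c(msg, "last affine row must be (0, 0, 0, 1)")
      vv <- abs(det(a[1:3, 1:3])) / 1000
      if (vv <= 0)
        msg <- c(msg, "affine spatial part is singular")
      else if (abs(object@voxelVolumeCc - vv) > 1e-9)
        msg <- c(msg, "voxelVolumeCc inconsistent with affine determinant")
    }
    if (length(msg)) msg else TRUE
  })

#' Volumetric data classes
#'
#' `BrainVolume` is the virtual parent of all voxel-data classes: an array of
#' per-voxel values tied to a [VoxelGrid]. `IntensityVolume` holds arbitrary
#' finite real values (e.g. FA or connectivity-probability volumes before
#' binarization); `BinaryVolume` restricts values to \{0, 1\};
#' `LesionMask` is a `BinaryVolume` carrying a patient identifier.
#'
#' @slot grid the [VoxelGrid].
#' @slot values numeric array with `dim` equal to the grid shape.
#' @slot patientId (`LesionMask` only) patient identifier.
#'
#' @name BrainVolume-classes
#' @aliases IntensityVolume-class BinaryVolume-class LesionMask-class
#'   BrainVolume-class
NULL

setClass("BrainVolume",
  representation("VIRTUAL", grid = "VoxelGrid", values = "array"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
      return("values array shape does not match grid shape")
    TRUE
  })

setClass("IntensityVolume", contains = "BrainVolume",
  validity = function(object) {
    if (!all(is.finite(object@values)))
      return("all voxel values must be finite")
    TRUE
  })

setClass("BinaryVolume", contains = "BrainVolume",
  validity = function(object) {
    v <- object@values
    if (!all(v == 0 | v == 1))
      return("binary volume values must all be exactly 0 or 1")
    TRUE
  })

setClass("LesionMask", contains = "BinaryVolume",
  representation(patientId = "character"),
  validity = function(object) {
    if (length(object@patientId) != 1L || is.na(object@patientId))
      return("patientId must be a single non-missing string")
    TRUE
  })

#' @rdname BrainVolume-classes
#' @param values numeric array of per-voxel values.
#' @param grid a [VoxelGrid] whose shape matches `dim(values)`.
#' @return A volume object of the corresponding class.
#' @examples
#' g <- VoxelGrid(c(4, 4, 4))
#' iv <- IntensityVolume(array(rnorm(64), c(4, 4, 4)), g)
#' bv <- BinaryVolume(array(0, c(4, 4, 4)), g)
#' @export
IntensityVolume <- function(values, grid) {
  new("IntensityVolume", grid = grid,
      values = array(as.numeric(values), dim = grid@shape))
}

#' @rdname BrainVolume-classes
#' @export
BinaryVolume <- function(values, grid) {
  new("BinaryVolume", grid = grid,
      values = array(as.numeric(values), dim = grid@shape))
}

#' @rdname BrainVolume-classes
#' @param patientId patient identifier attached to a lesion mask.
#' @export
LesionMask <- function(values, grid, patientId) {
  new("LesionMask", grid = grid,
      values = array(as.numeric(values), dim = grid@shape),
      patientId = as.character(patientId))
}

#' ProbabilisticMap: canonical voxelwise overlap counts
#'
#' A canonical probabilistic map stores, per voxel, the number of healthy
#' control subjects (out of `nSubjects`) whose binarized tract or activation
#' map contains that voxel. The probability that a voxel belongs to the
#' structure is `counts / nSubjects`.
#'
#' @slot grid the [VoxelGrid].
#' @slot counts integer array of overlap counts in `0..nSubjects`.
#' @slot nSubjects number of contributing subjects.
#' @slot label map label, e.g. `"AF"`, `"fGM"`, `"AF+fGM"`.
#'
#' @param counts integer array of per-voxel overlap counts.
#' @param grid a [VoxelGrid].
#' @param nSubjects number of subjects summed into `counts`.
#' @param label map label.
#' @return A `ProbabilisticMap`.
#' @examples
#' g <- VoxelGrid(c(4, 4, 4))
#' pm <- ProbabilisticMap(array(0L, c(4, 4, 4)), g, nSubjects = 12, label = "AF")
#' @export
ProbabilisticMap <- function(counts, grid, nSubjects, label = "map") {
  new("ProbabilisticMap", grid = grid,
      counts = array(as.integer(round(counts)), dim = grid@shape),
      nSubjects = as.integer(nSubjects), label = as.character(label))
}

setClass("ProbabilisticMap",
  representation(grid = "VoxelGrid", counts = "array",
                 nSubjects = "integer", label = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@counts), as.integer(object@grid@shape)))
      msg <- c(msg, "counts array shape does not match grid shape")
    if (length(object@nSubjects) != 1L || object@nSubjects < 1L)
      msg <- c(msg, "nSubjects must be a single positive integer")
    else if (any(object@counts < 0L) || any(object@counts > object@nSubjects))
      msg <- c(msg, "counts must lie in 0..nSubjects at every voxel")
    if (length(msg)) msg else TRUE
  })

#' SeverityPartition: a two-group split of a behavioral score
#'
#' Result of [twoGroupCluster()]: an interval split of a one-dimensional
#' score into a severe (lower-scoring) and a non-severe group. The cutoff
#' band is the open interval between the maximum severe score and the
#' minimum non-severe score, mirroring how behavioral cutoff ranges are
#' reported clinically.
#'
#' @slot variable name of the behavioral measure.
#' @slot labels character vector, `"severe"`/`"non_severe"` per observation.
#' @slot scores the clustered scores, in input order.
#' @slot cutoffBand numeric(2): (max severe score, min non-severe score).
#' @slot nSevere,nNonSevere group sizes.
#' @name SeverityPartition-class
#' @aliases SeverityPartition
NULL

setClass("SeverityPartition",
  representation(variable = "character", labels = "character",
                 scores = "numeric", cutoffBand = "numeric",
                 nSevere = "integer", nNonSevere = "integer"),
  validity = function(object) {
    msg <- character()
    sev <- object@labels == "severe"
    if (!all(object@labels %in% c("severe", "non_severe")))
      msg <- c(msg, "labels must be 'severe' or 'non_severe'")
    if (length(object@scores) != length(object@labels))
      msg <- c(msg, "scores and labels lengths differ")
    if (sum(sev) != object@nSevere || sum(!sev) != object@nNonSevere)
      msg <- c(msg, "group counts inconsistent with labels")
    if (sum(sev) > 0 && sum(!sev) > 0) {
      lo <- max(object@scores[sev]); hi <- min(object@scores[!sev])
      if (!(lo < hi))
        msg <- c(msg, "severe scores must all lie below non-severe scores")
      if (abs(object@cutoffBand[1] - lo) > 1e-9 ||
          abs(object@cutoffBand[2] - hi) > 1e-9)
        msg <- c(msg, "cutoffBand must be (max severe, min non-severe)")
    }
    if (length(msg)) msg else TRUE
  })

#' RocResult: ROC analysis of a lesion-load classifier
#'
#' Result of [rocAnalysis()]: the area under the ROC curve (equal to the
#' normalized Mann-Whitney U statistic), the Youden-optimal decision
#' threshold on the predictor (in cc for lesion loads), and operating
#' characteristics at that threshold. Severe outcome is predicted when the
#' predictor is greater than or equal to the threshold.
#'
#' @slot auc area under the ROC curve, in `[0, 1]`.
#' @slot thresholdCc Youden-optimal decision threshold (predictor units).
#' @slot sensitivity,specificity,accuracy operating characteristics at the
#'   threshold; accuracy is the raw (unbalanced) proportion correct.
#' @slot nPoints number of distinct operating points evaluated.
#' @slot curve data.frame of (threshold, sensitivity, specificity) for all
#'   candidate thresholds, exportable for plotting.
#' @name RocResult-class
#' @aliases RocResult
NULL

setClass("RocResult",
  representation(auc = "numeric", thresholdCc = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 accuracy = "numeric", nPoints = "integer",
                 curve = "data.frame"),
  validity = function(object) {
    ok <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
    msg <- character()
    if (!ok(object@auc)) msg <- c(msg, "auc must be a single value in [0,1]")
    if (!ok(object@sensitivity) || !ok(object@specificity) ||
        !ok(object@accuracy))
      msg <- c(msg, "sensitivity/specificity/accuracy must lie in [0,1]")
    if (length(msg)) msg else TRUE
  })

#' RegressionFit: an outcome-on-lesion-load regression
#'
#' Result of [fitModel()]: an ordinary least-squares fit of a behavioral
#' outcome on (optionally cube-root-transformed) lesion-load predictors plus
#' covariates, after a single studentized-residual outlier pass.
#'
#' @slot outcome,predictors,covariates model specification columns.
#' @slot transform `"cube_root"` or `"identity"` (predictor transform).
#' @slot rSquared,adjRSquared,pValueModel overall model fit statistics.
#' @slot coefficients data.frame of per-term estimate, p-value and partial
#'   correlation with the outcome controlling all other terms.
#' @slot partialR named partial correlations for the predictor terms.
#' @slot nUsed rows entering the final fit.
#' @slot excludedIds patient ids removed by the outlier pass.
#' @slot fit the underlying `lm` object of the final fit.
#' @name RegressionFit-class
#' @aliases RegressionFit
NULL

setClass("RegressionFit",
  representation(outcome = "character", predictors = "character",
                 covariates = "character", transform = "character",
                 rSquared = "numeric", adjRSquared = "numeric",
                 pValueModel = "numeric", coefficients = "data.frame",
                 partialR = "numeric", nUsed = "integer",
                 excludedIds = "character", fit = "ANY"),
  validity = function(object) {
    msg <- character()
    if (!is.na(object@rSquared) &&
        (object@rSquared < 0 || object@rSquared > 1))
      msg <- c(msg, "rSquared must lie in [0,1]")
    if (length(object@partialR) && any(abs(object@partialR) > 1 + 1e-9))
      msg <- c(msg, "partial correlations must lie in [-1,1]")
    if (length(msg)) msg else TRUE
  })
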