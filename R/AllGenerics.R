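#' Accessors for volumetric and analysis classes
#'
#' Standard accessor generics. `voxelGrid()` returns the [VoxelGrid] of a
#' volume or map; `voxelValues()` the value array; `voxelCounts()` the
#' overlap-count array of a [ProbabilisticMap]; `probabilities()` the
#' per-voxel probability array `counts / nSubjects`; `voxelVolumeCc()` the
#' voxel volume in cc. `severityLabels()` and `cutoffBand()` read a
#' [SeverityPartition]; `auc()`, `thresholdCc()` and `rocCurve()` read a
#' [RocResult]; `rSquared()`, `partialR()` and `excludedIds()` read a
#' [RegressionFit].
#'
#' @param x an object of the appropriate class.
#' @return The slot value described above.
#' @name accessors
#' @examples
#' g <- VoxelGrid(c(4, 4, 4))
#' voxelVolumeCc(g)
NULL

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))
#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))
#' @rdname accessors
#' @export
setGeneric("voxelCounts", function(x) standardGeneric("voxelCounts"))
#' @rdname accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname accessors
#' @export
setGeneric("voxelVolumeCc", function(x) standardGeneric("voxelVolumeCc"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))
#' @rdname accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))
#' @rdname accessors
#' @export
setGeneric("mapLabel", function(x) standardGeneric("mapLabel"))
#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("severityLabels", function(x) standardGeneric("severityLabels"))
#' @rdname accessors
#' @export
setGeneric("cutoffBand", function(x) standardGeneric("cutoffBand"))
#' @rdname accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
#' @rdname accessors
#' @export
setGeneric("thresholdCc", function(x) standardGeneric("thresholdCc"))
#' @rdname accessors
#' @export
setGeneric("rocCurve", function(x) standardGeneric("rocCurve"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))
#' @rdname accessors
#' @export
setGeneric("partialR", function(x) standardGeneric("partialR"))
#' @rdname accessors
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

setMethod("voxelGrid", "BrainVolume", function(x) x@grid)
setMethod("voxelGrid", "ProbabilisticMap", function(x) x@grid)
setMethod("voxelValues", "BrainVolume", function(x) x@values)
setMethod("voxelCounts", "ProbabilisticMap", function(x) x@counts)
setMethod("probabilities", "ProbabilisticMap",
          function(x) x@counts / x@nSubjects)
setMethod("voxelVolumeCc", "VoxelGrid", function(x) x@voxelVolumeCc)
setMethod("voxelVolumeCc", "BrainVolume", function(x) x@grid@voxelVolumeCc)
setMethod("voxelVolumeCc", "ProbabilisticMap",
          function(x) x@grid@voxelVolumeCc)
setMethod("gridShape", "VoxelGrid", function(x) x@shape)
setMethod("gridShape", "BrainVolume", function(x) x@grid@shape)
setMethod("gridShape", "ProbabilisticMap", function(x) x@grid@shape)
setMethod("gridAffine", "VoxelGrid", function(x) x@affine)
setMethod("gridAffine", "BrainVolume", function(x) x@grid@affine)
setMethod("gridAffine", "ProbabilisticMap", function(x) x@grid@affine)
setMethod("nSubjects", "ProbabilisticMap", function(x) x@nSubjects)
setMethod("mapLabel", "ProbabilisticMap", function(x) x@label)
setMethod("patientId", "LesionMask", function(x) x@patientId)
setMethod("severityLabels", "SeverityPartition", function(x) x@labels)
setMethod("cutoffBand", "SeverityPartition", function(x) x@cutoffBand)
setMethod("auc", "RocResult", function(x) x@auc)
setMethod("thresholdCc", "RocResult", function(x) x@thresholdCc)
setMethod("rocCurve", "RocResult", function(x) x@curve)
setMethod("rSquared", "RegressionFit", function(x) x@rSquared)
setMethod("partialR", "RegressionFit", function(x) x@partialR)
setMethod("excludedIds", "RegressionFit", function(x) x@excludedIds)

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s, voxel volume %.4g cc\n",
              paste(object@shape, collapse = " x "),
              object@voxelVolumeCc))
})

setMethod("show", "BrainVolume", function(object) {
  cat(sprintf("%s %s: %d / %d voxels nonzero\n", class(object),
              paste(object@grid@shape, collapse = " x "),
              sum(object@values != 0), length(object@values)))
  if (is(object, "LesionMask"))
    cat(sprintf("  patient %s, lesion volume %.2f cc\n", object@patientId,
                sum(object@values) * object@grid@voxelVolumeCc))
})

setMethod("show", "ProbabilisticMap", function(object) {
  cat(sprintf(
    "ProbabilisticMap '%s' (N = %d subjects), %s grid\n  %d voxels with count > 0, max count %d\n",
    object@label, object@nSubjects,
    paste(object@grid@shape, collapse = " x "),
    sum(object@counts > 0L), max(object@counts)))
})

setMethod("show", "SeverityPartition", function(object) {
  cat(sprintf(
    "SeverityPartition of %s: %d severe / %d non-severe, cutoff band (%g, %g)\n",
    object@variable, object@nSevere, object@nNonSevere,
    object@cutoffBand[1], object@cutoffBand[2]))
})

setMethod("show", "RocResult", function(object) {
  cat(sprintf(
    "RocResult: AUC %.3f, threshold %.3g (sens %.3f, spec %.3f, acc %.3f)\n",
    object@auc, object@thresholdCc, object@sensitivity,
    object@specificity, object@accuracy))
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit: %s ~ %s%s\n", object@outcome,
              paste(object@predictors, collapse = " + "),
              if (length(object@covariates))
                paste0(" + ", paste(object@covariates, collapse = " + "))
              else ""))
  cat(sprintf("  transform %s, R^2 = %.3f (adj %.3f), model p = %.3g, n = %d\n",
              object@transform, object@rSquared, object@adjRSquared,
              object@pValueModel, object@nUsed))
  if (length(object@excludedIds))
    cat("  excluded outliers:", paste(object@excludedIds, collapse = ", "),
        "\n")
})
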