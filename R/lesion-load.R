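#' Compute the probability-weighted lesion load of one lesion on one map
#'
#' The lesion load (LL) is the central statistic of the package: the
#' probability-weighted volume, in cc, of the intersection between a binary
#' lesion mask and a canonical probabilistic map,
#' \deqn{LL = \sum_{v: lesion(v) = 1} \frac{counts(v)}{N} \times v_{cc},}
#' where `counts(v)/N` is the probability that voxel `v` belongs to the
#' structure and `v_cc` is the voxel volume in cc. A lesion covering only
#' voxels where all N subjects agree contributes its full volume; voxels
#' seen in fewer subjects contribute proportionally less.
#'
#' @param lesion a [LesionMask].
#' @param map a [ProbabilisticMap] on the same grid.
#' @return A one-row `data.frame` with columns `patient_id`, `map_label`,
#'   `load_cc`, `lesion_volume_cc` and `weighted_voxels` (the raw
#'   probability-weighted voxel count, `load_cc / voxel volume`).
#' @examples
#' g <- VoxelGrid(c(10, 10, 10))
#' m <- ProbabilisticMap(array(12L, c(10, 10, 10)), g, 12, "AF")
#' les <- LesionMask(array(c(rep(1, 500), rep(0, 500)), c(10, 10, 10)), g, "p1")
#' computeLesionLoad(les, m)$load_cc  # 500 voxels x 1.0 x 0.008 cc = 4 cc
#' @export
computeLesionLoad <- function(lesion, map) {
  stopifnot(is(lesion, "LesionMask"), is(map, "ProbabilisticMap"))
  assertSameGrid(lesion, map)
  vvc <- lesion@grid@voxelVolumeCc
  inside <- lesion@values == 1
  if (!any(inside))
    warning("empty lesion mask for patient ", lesion@patientId,
            "; lesion load is 0")
  weighted <- sum(map@counts[inside]) / map@nSubjects
  data.frame(patient_id = lesion@patientId, map_label = map@label,
             load_cc = weighted * vvc,
             lesion_volume_cc = sum(inside) * vvc,
             weighted_voxels = weighted,
             stringsAsFactors = FALSE)
}

#' Total lesion volume in cc
#'
#' @param lesion a [LesionMask].
#' @return Lesion volume in cc (voxel count times voxel volume).
#' @examples
#' g <- VoxelGrid(c(20, 20, 20))
#' v <- array(0, c(20, 20, 20)); v[seq_len(1585)] <- 1
#' computeLesionVolume(LesionMask(v, g, "p44"))  # 1585 * 0.008 = 12.68 cc
#' @export
computeLesionVolume <- function(lesion) {
  stopifnot(is(lesion, "LesionMask"))
  sum(lesion@values) * lesion@grid@voxelVolumeCc
}

#' Lesion loads for every lesion x map pair
#'
#' Overlays each patient lesion mask on each canonical map and tabulates
#' the loads, one row per (patient, map) in deterministic order (patient,
#' then map label).
#'
#' @param lesions list of [LesionMask] objects.
#' @param maps list of [ProbabilisticMap] objects, all on the lesions' grid.
#' @return A `data.frame`, rows ordered by patient id then map label, with
#'   the columns of [computeLesionLoad()].
#' @export
batchLesionLoads <- function(lesions, maps) {
  stopifnot(is.list(lesions), length(lesions) > 0L,
            is.list(maps), length(maps) > 0L)
  rows <- list()
  for (les in lesions) {
    for (m in maps) {
      row <- tryCatch(computeLesionLoad(les, m), error = function(e)
        stop("lesion load failed for patient ", patientId(les), " on map ",
             mapLabel(m), ": ", conditionMessage(e), call. = FALSE))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$patient_id, out$map_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
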