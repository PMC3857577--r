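#' Threshold a volume at a percentile of its nonzero values
#'
#' Trims weak voxels from a tract or activation volume before binarization:
#' voxels whose value is greater than or equal to the given percentile of
#' the *nonzero* value distribution are kept. The percentile is taken over
#' nonzero voxels only because tract volumes are mostly zero, and uses the
#' linear-interpolation convention (`stats::quantile` type 7). The default
#' 50th percentile removes the weaker half of within-tract voxels,
#' suppressing extraneous fibers.
#'
#' @param vol an [IntensityVolume] with at least one positive voxel.
#' @param percentile percentile in (0, 100); default 50.
#' @return A nonempty [BinaryVolume].
#' @examples
#' g <- VoxelGrid(c(2, 2, 1))
#' v <- IntensityVolume(array(c(1, 2, 3, 4), c(2, 2, 1)), g)
#' sum(voxelValues(thresholdPercentile(v, 50)))  # 2 voxels (values 3, 4)
#' @export
thresholdPercentile <- function(vol, percentile = 50) {
  stopifnot(is(vol, "IntensityVolume"),
            percentile > 0, percentile < 100)
  nz <- vol@values[vol@values > 0]
  if (length(nz) == 0L)
    stop("cannot threshold an all-zero volume: no nonzero voxels")
  cut <- stats::quantile(nz, percentile / 100, type = 7, names = FALSE)
  # tolerance so that values equal to the percentile point up to float
  # error are retained (e.g. the minimum as percentile -> 0)
  tol <- 1e-8 * max(abs(nz))
  BinaryVolume(as.numeric(vol@values >= cut - tol), vol@grid)
}

#' Aggregate per-subject binary maps into a canonical probabilistic map
#'
#' Sums binarized subject maps voxelwise: the count at each voxel is the
#' number of subjects whose map contains it, and the per-voxel probability
#' is count / N. This is how canonical tract and functional-activation maps
#' are built from healthy-control groups (here typically N = 12).
#'
#' @param maps list of [BinaryVolume] objects on one shared grid.
#' @param label label for the resulting map (e.g. `"AF"`).
#' @return A [ProbabilisticMap] with `nSubjects = length(maps)`.
#' @export
aggregateSubjectMaps <- function(maps, label = "map") {
  if (!is.list(maps) || length(maps) == 0L)
    stop("maps must be a nonempty list of BinaryVolume objects")
  stopifnot(all(vapply(maps, is, logical(1), "BinaryVolume")))
  for (m in maps[-1]) assertSameGrid(maps[[1]], m)
  counts <- Reduce(`+`, lapply(maps, voxelValues))
  ProbabilisticMap(counts, maps[[1]]@grid, nSubjects = length(maps),
                   label = label)
}

#' Restrict a probabilistic map to gray matter
#'
#' Zeroes counts outside a binary gray-matter mask, leaving `nSubjects`
#' unchanged. Used to confine functional activation maps to gray matter
#' before lesion-load calculation.
#'
#' @param map a [ProbabilisticMap].
#' @param gm a [BinaryVolume] gray-matter mask on the same grid.
#' @return The masked [ProbabilisticMap].
#' @export
maskGrayMatter <- function(map, gm) {
  stopifnot(is(map, "ProbabilisticMap"), is(gm, "BinaryVolume"))
  assertSameGrid(map, gm)
  ProbabilisticMap(map@counts * gm@values, map@grid,
                   nSubjects = map@nSubjects, label = map@label)
}

#' Combine two probabilistic maps
#'
#' Forms the combined structural-functional map (e.g. AF + fGM) by summing
#' per-voxel probabilities, capped at 1 so the result remains a
#' probability: `p = min(1, pA + pB)`, stored as `counts = round(p * N)`.
#' Both maps must be built from the same number of subjects.
#'
#' @param a,b [ProbabilisticMap] objects on one grid with equal
#'   `nSubjects`.
#' @return A [ProbabilisticMap] labelled `"a+b"`.
#' @export
combineMaps <- function(a, b) {
  stopifnot(is(a, "ProbabilisticMap"), is(b, "ProbabilisticMap"))
  assertSameGrid(a, b)
  if (a@nSubjects != b@nSubjects)
    stop("cannot combine maps with different subject counts (",
         a@nSubjects, " vs ", b@nSubjects, ")")
  n <- a@nSubjects
  p <- pmin(1, (a@counts + b@counts) / n)
  ProbabilisticMap(round(p * n), a@grid, nSubjects = n,
                   label = paste0(a@label, "+", b@label))
}

#' Write / read a canonical probabilistic map
#'
#' Maps are stored as integer-count NIfTI volumes with a JSON sidecar
#' (`<path>.json`) recording the label and the number of contributing
#' subjects.
#'
#' @param map a [ProbabilisticMap].
#' @param path NIfTI output path.
#' @return `writeProbabilisticMap`: `path`, invisibly.
#'   `readProbabilisticMap`: the [ProbabilisticMap].
#' @export
writeProbabilisticMap <- function(map, path) {
  stopifnot(is(map, "ProbabilisticMap"))
  writeVolume(IntensityVolume(map@counts, map@grid), path)
  jsonlite::write_json(list(label = map@label, n_subjects = map@nSubjects),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProbabilisticMap
#' @export
readProbabilisticMap <- function(path) {
  vol <- readVolume(path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar JSON for probabilistic map: ", side)
  meta <- jsonlite::read_json(side)
  ProbabilisticMap(vol@values, vol@grid, nSubjects = meta$n_subjects,
                   label = meta$label)
}
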