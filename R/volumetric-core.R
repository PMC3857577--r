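#' Read a 3-D NIfTI volume
#'
#' Reads a NIfTI-1 file into an [IntensityVolume], taking the grid from the
#' file header (sform/qform affine, 0-based voxel indices). Only 3-D images
#' are accepted; the package never resamples, so all volumes entering an
#' analysis must already share one grid.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [IntensityVolume].
#' @seealso [writeVolume()], [readLesionMask()], [assertSameGrid()]
#' @export
readVolume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("failed to read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image but ", path, " has ", length(d),
         " dimensions (", paste(d, collapse = " x "), ")")
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  grid <- VoxelGrid(d, affine = matrix(as.numeric(aff), 4, 4))
  IntensityVolume(array(as.numeric(img), dim = d), grid)
}

#' Write a volume to NIfTI
#'
#' Writes any [BrainVolume-classes] object as a NIfTI-1 file, storing the
#' grid affine in both sform and qform.
#'
#' @param vol an `IntensityVolume`, `BinaryVolume` or `LesionMask`.
#' @param path output path (`.nii` or `.nii.gz`); parent directory must
#'   exist.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "BrainVolume"))
  if (!dir.exists(dirname(path)))
    stop("cannot write volume: directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(vol@values)
  aff <- vol@grid@affine
  RNifti::pixdim(img) <- sqrt(colSums(aff[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Check that two volumes share one grid
#'
#' Voxelwise overlap is only defined on a shared grid. This check passes
#' silently iff the shapes are identical and the affines agree within
#' 1e-4 mm; otherwise it raises an error describing both grids.
#'
#' @param a,b volumes or probabilistic maps.
#' @return `TRUE`, invisibly, on success.
#' @export
assertSameGrid <- function(a, b) {
  ga <- voxelGrid(a); gb <- voxelGrid(b)
  fmt <- function(g)
    sprintf("shape %s, affine [%s]", paste(g@shape, collapse = "x"),
            paste(signif(t(g@affine[1:3, ]), 6), collapse = " "))
  if (!identical(ga@shape, gb@shape) ||
      max(abs(ga@affine - gb@affine)) > .AFFINE_TOL)
    stop("grid mismatch between volumes:\n  first:  ", fmt(ga),
         "\n  second: ", fmt(gb), call. = FALSE)
  invisible(TRUE)
}

#' Binarize a nearly-binary volume
#'
#' Masks stored as floats can carry interpolation artifacts; values above
#' the threshold map to 1, the rest to 0.
#'
#' @param vol an [IntensityVolume].
#' @param threshold binarization cut, default 0.5.
#' @return A [BinaryVolume].
#' @export
binarize <- function(vol, threshold = 0.5) {
  stopifnot(is(vol, "BrainVolume"))
  BinaryVolume(as.numeric(vol@values > threshold), vol@grid)
}

#' Read a binary lesion mask
#'
#' Reads a NIfTI lesion mask, binarizes it (values > 0.5 become 1), and tags
#' it with a patient identifier. Defaults the identifier to the file name
#' stem.
#'
#' @param path NIfTI file path.
#' @param patientId patient identifier; default: file name without
#'   extension.
#' @return A [LesionMask].
#' @export
readLesionMask <- function(path, patientId = NULL) {
  if (is.null(patientId))
    patientId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vol <- readVolume(path)
  bin <- binarize(vol)
  LesionMask(bin@values, bin@grid, patientId)
}

# world <-> voxel coordinate helpers (0-based voxel indices)
.voxelToWorld <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  t(grid@affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

.worldToVoxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(grid@affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}
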