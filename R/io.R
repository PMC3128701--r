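#' Read a binary lesion mask from a NIfTI-1 file
#'
#' Values must be two-valued \{0, v > 0\} (or all zero); they are binarised
#' by thresholding at > 0. A continuous volume with more than two distinct
#' values is rejected as not being a mask. If `referenceGrid` is supplied
#' the file's grid must match it (dims identical, affines within `tol`);
#' mismatches raise an error naming both affines — no resampling is done.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param referenceGrid optional [VolumeGrid-class] the mask must live on.
#' @param subjectId subject id; default the file name minus extensions.
#' @param tol affine comparison tolerance.
#' @return a [LesionMask-class].
#' @export
readMask <- function(path, referenceGrid = NULL, subjectId = NULL,
                     tol = 1e-4) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("expected a 3D volume in ", path, call. = FALSE)
  vals <- unique(as.vector(arr))
  nz <- vals[vals != 0]
  if (length(nz) > 1L)
    stop("not a binary mask: ", path, " has values {",
         paste(signif(sort(vals), 4), collapse = ", "), "}", call. = FALSE)
  if (length(nz) == 1L && nz < 0)
    stop("mask values must be nonnegative in ", path, call. = FALSE)
  grid <- gridFromNifti(img)
  if (!is.null(referenceGrid)) stopIfGridMismatch(grid, referenceGrid, tol)
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  lesionMask(subjectId, grid, which(arr > 0))
}

gridFromNifti <- function(img) {
  aff <- unname(structure(RNifti::xform(img), imagedim = NULL, code = NULL))
  attributes(aff) <- list(dim = c(4L, 4L))
  voxelGrid(dim(as.array(img)), abs(RNifti::pixdim(img)[1:3]), aff)
}

niftiFromGrid <- function(arr, grid, descrip = "") {
  img <- RNifti::asNifti(arr)
  aff <- grid@affine
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::pixdim(img) <- grid@voxelSize
  if (nzchar(descrip)) img$descrip <- descrip
  img
}

#' Sentinel value marking untested voxels in written p-value maps
#' @export
UNTESTED_SENTINEL <- -1

#' Write / read a statistical map as NIfTI
#'
#' `writeStatMap` writes the raw p-value volume (untested voxels encoded as
#' the sentinel `-1`, recorded in the NIfTI description field) plus a
#' companion binary significance volume at `<path stem>_sig.nii(.gz)`.
#' `readStatMap` reverses this, restoring `NA` at sentinel voxels.
#'
#' @param map a [StatMap-class].
#' @param path output path for the p-value volume (.nii or .nii.gz).
#' @return `writeStatMap` invisibly returns the two paths written;
#'   `readStatMap` returns a [StatMap-class].
#' @export
writeStatMap <- function(map, path) {
  parr <- map@p
  parr[is.na(parr)] <- UNTESTED_SENTINEL
  img <- niftiFromGrid(parr, map@grid,
                       descrip = sprintf("p-map; untested=%g",
                                         UNTESTED_SENTINEL))
  RNifti::writeNifti(img, path, datatype = "double")
  sigPath <- statMapCompanionPath(path)
  sigImg <- niftiFromGrid(array(as.integer(map@significant),
                                map@grid@dims),
                          map@grid, descrip = "significance mask")
  RNifti::writeNifti(sigImg, sigPath, datatype = "uint8")
  invisible(c(p = path, significance = sigPath))
}

statMapCompanionPath <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_sig\\1", path)
}

#' @rdname writeStatMap
#' @export
readStatMap <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- gridFromNifti(img)
  parr <- array(as.vector(img), grid@dims)
  parr[parr == UNTESTED_SENTINEL] <- NA_real_
  sig <- array(as.vector(RNifti::readNifti(statMapCompanionPath(path))) > 0,
               grid@dims)
  new("StatMap", grid = grid, p = parr, significant = sig)
}

#' Write a lesion mask as NIfTI
#'
#' @param mask a [LesionMask-class].
#' @param path output .nii or .nii.gz path.
#' @export
writeMask <- function(mask, path) {
  img <- niftiFromGrid(maskArray(mask), mask@grid,
                       descrip = paste0("lesion mask ", mask@subjectId))
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Score-weighted lesion volume
#'
#' Represents a patient's behavioural score painted over their lesion: the
#' score value at every lesioned voxel, zero elsewhere. This dense
#' representation is retained for visualisation and interoperability; the
#' statistics consume the raw score lists directly, which is numerically
#' equivalent.
#'
#' @param mask a [LesionMask-class].
#' @param score a finite scalar score.
#' @return a numeric 3D array on the mask's grid.
#' @export
weightByScore <- function(mask, score) {
  if (!is.numeric(score) || length(score) != 1L || !is.finite(score))
    stop("score must be a single finite number", call. = FALSE)
  a <- array(0, mask@grid@dims)
  a[mask@indices] <- score
  a
}
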