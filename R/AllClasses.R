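#' @import methods
NULL

#' VolumeGrid: a shared standard-space sampling grid
#'
#' Describes the common 3D grid on which all lesion masks and statistical
#' maps live: voxel dimensions, voxel size in millimetres, and the 4x4
#' affine mapping 0-based voxel indices to MNI millimetre coordinates.
#'
#' @slot dims integer(3), voxels per axis.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (all > 0).
#' @slot affine 4x4 numeric matrix, voxel (0-based, homogeneous) to mm.
#' @seealso [voxelGrid()], [voxelToWorld()], [worldToVoxel()]
#' @export
setClass("VolumeGrid",
  representation(dims = "integer", voxelSize = "numeric", affine = "matrix"))

setValidity("VolumeGrid", function(object) {
  msg <- character()
  if (length(object@dims) != 3L || any(object@dims < 1L))
    msg <- c(msg, "dims must be three integers >= 1")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three strictly positive reals")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else {
    if (max(abs(object@affine[4, ] - c(0, 0, 0, 1))) > 1e-8)
      msg <- c(msg, "affine last row must be (0, 0, 0, 1)")
    if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
      msg <- c(msg, "affine must be invertible")
  }
  if (length(msg)) msg else TRUE
})

#' LesionMask: one patient's binary lesion on a VolumeGrid
#'
#' The lesion is stored sparsely as sorted 1-based linear indices into the
#' grid array; [voxelCoordinates()] recovers 0-based (i,j,k) triples and
#' [lesionVolume()] the volume in cubic millimetres.
#'
#' @slot subjectId character(1).
#' @slot grid a [VolumeGrid-class].
#' @slot indices sorted unique integer linear indices of lesioned voxels.
#' @seealso [lesionMask()], [readMask()]
#' @export
setClass("LesionMask",
  representation(subjectId = "character", grid = "VolumeGrid",
                 indices = "integer"))

setValidity("LesionMask", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-NA string")
  n <- prod(object@grid@dims)
  if (length(object@indices) &&
      (min(object@indices) < 1L || max(object@indices) > n))
    msg <- c(msg, "lesion indices fall outside the grid")
  if (is.unsorted(object@indices, strictly = TRUE) && length(object@indices) > 1L)
    msg <- c(msg, "lesion indices must be sorted and unique")
  if (length(msg)) msg else TRUE
})

#' OverlapMap: per-voxel lesion count across a cohort
#'
#' The "maximum overlap map": for every voxel, the number of cohort lesions
#' covering it.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot counts integer 3D array of lesion counts, `dim == dims(grid)`.
#' @slot subjectIds the subject ids whose masks were superimposed.
#' @seealso [buildOverlapMap()]
#' @export
setClass("OverlapMap",
  representation(grid = "VolumeGrid", counts = "array",
                 subjectIds = "character"))

setValidity("OverlapMap", function(object) {
  msg <- character()
  if (!identical(dim(object@counts), as.integer(object@grid@dims)))
    msg <- c(msg, "counts array does not match grid dims")
  if (any(object@counts < 0) || max(object@counts) > length(object@subjectIds))
    msg <- c(msg, "counts must lie in [0, number of subjects]")
  if (length(msg)) msg else TRUE
})

#' Subregion: voxels sharing one exact lesion-coverage pattern
#'
#' The unit of statistical testing: a maximal set of voxels lesioned in
#' exactly the same subjects and no others. Voxels with the same pattern
#' form one subregion even when spatially disconnected.
#'
#' @slot pattern character vector of covering subject ids.
#' @slot grid a [VolumeGrid-class].
#' @slot indices integer linear voxel indices.
#' @slot sizeMm3 numeric(1), volume in cubic mm.
#' @slot centroidMni numeric(3), voxel-count centroid mapped to MNI mm.
#' @seealso [partitionSubregions()]
#' @export
setClass("Subregion",
  representation(pattern = "character", grid = "VolumeGrid",
                 indices = "integer", sizeMm3 = "numeric",
                 centroidMni = "numeric"))

setValidity("Subregion", function(object) {
  msg <- character()
  if (!length(object@pattern)) msg <- c(msg, "empty coverage pattern")
  if (!length(object@indices)) msg <- c(msg, "subregion has no voxels")
  if (anyDuplicated(object@pattern)) msg <- c(msg, "duplicate subject ids")
  if (length(msg)) msg else TRUE
})

#' StatMap: per-voxel significance map from subregion testing
#'
#' Each tested voxel inherits the raw p-value of its coverage-pattern
#' subregion; untested voxels (fewer than `minOverlap` lesions) are `NA`.
#' `significant` marks voxels of subregions surviving Holm correction.
#'
#' @slot grid a [VolumeGrid-class].
#' @slot p numeric 3D array of raw p-values, NA where untested.
#' @slot significant logical 3D array.
#' @seealso [runAnacom()], [writeStatMap()]
#' @export
setClass("StatMap",
  representation(grid = "VolumeGrid", p = "array", significant = "array"))

setValidity("StatMap", function(object) {
  msg <- character()
  d <- as.integer(object@grid@dims)
  if (!identical(dim(object@p), d) || !identical(dim(object@significant), d))
    msg <- c(msg, "array dims do not match grid")
  pv <- object@p[!is.na(object@p)]
  if (length(pv) && (any(pv <= 0) || any(pv > 1)))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (any(object@significant & is.na(object@p)))
    msg <- c(msg, "significant voxels must have been tested")
  if (length(msg)) msg else TRUE
})

setMethod("show", "VolumeGrid", function(object) {
  cat(sprintf("VolumeGrid: %s voxels at %s mm\n",
              paste(object@dims, collapse = " x "),
              paste(format(object@voxelSize), collapse = " x ")))
})

setMethod("show", "LesionMask", function(object) {
  cat(sprintf("LesionMask '%s': %d voxels (%.1f mm^3) on %s grid\n",
              object@subjectId, length(object@indices),
              lesionVolume(object),
              paste(object@grid@dims, collapse = "x")))
})

setMethod("show", "OverlapMap", function(object) {
  cat(sprintf("OverlapMap of %d lesions: max overlap %d, %d voxels covered\n",
              length(object@subjectIds), max(object@counts),
              sum(object@counts > 0)))
})

setMethod("show", "Subregion", function(object) {
  cat(sprintf(
    "Subregion: %d voxels (%.1f mm^3), %d subjects, centroid MNI (%s)\n",
    length(object@indices), object@sizeMm3, length(object@pattern),
    paste(round(object@centroidMni), collapse = ", ")))
})

setMethod("show", "StatMap", function(object) {
  cat(sprintf("StatMap: %d tested voxels, %d significant\n",
              sum(!is.na(object@p)), sum(object@significant)))
})
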