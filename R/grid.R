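#' Construct a VolumeGrid
#'
#' @param dims integer(3), voxels per axis.
#' @param voxelSize numeric(3) or numeric(1), voxel edge length(s) in mm.
#' @param affine optional 4x4 voxel-to-mm affine (0-based voxel indices).
#'   When absent, an axis-aligned affine is built with the grid centre at
#'   the MNI origin and positive x to the right (neurological convention).
#' @return a [VolumeGrid-class] object.
#' @examples
#' g <- voxelGrid(c(20, 20, 20), 2)
#' voxelToWorld(g, c(0, 0, 0))
#' @export
voxelGrid <- function(dims, voxelSize = c(1, 1, 1), affine = NULL) {
  dims <- as.integer(dims)
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  if (is.null(affine)) {
    affine <- diag(c(voxelSize, 1))
    affine[1:3, 4] <- -(dims - 1L) / 2 * voxelSize
  }
  new("VolumeGrid", dims = dims, voxelSize = voxelSize,
      affine = unname(as.matrix(affine)))
}

#' @rdname voxelGrid
#' @param grid,x a [VolumeGrid-class].
#' @export
gridDims <- function(grid) grid@dims

#' @rdname voxelGrid
#' @export
voxelSize <- function(grid) grid@voxelSize

#' @rdname voxelGrid
#' @export
gridAffine <- function(grid) grid@affine

#' @rdname voxelGrid
#' @export
voxelVolume <- function(grid) prod(grid@voxelSize)

#' Map voxel indices to world (MNI) coordinates and back
#'
#' `voxelToWorld` applies the grid affine to 0-based voxel index triples;
#' `worldToVoxel` applies the inverse. Both accept a length-3 vector or an
#' n x 3 matrix and return the same shape.
#'
#' @param grid a [VolumeGrid-class].
#' @param ijk 0-based voxel indices (vector or n x 3 matrix).
#' @param xyz world mm coordinates (vector or n x 3 matrix).
#' @return coordinates in the other frame.
#' @export
voxelToWorld <- function(grid, ijk) {
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, ncol = 3L)
  out <- cbind(m, 1) %*% t(grid@affine[1:3, , drop = FALSE])
  if (is.matrix(ijk)) out else drop(out)
}

#' @rdname voxelToWorld
#' @export
worldToVoxel <- function(grid, xyz) {
  m <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3L)
  inv <- solve(grid@affine)
  out <- cbind(m, 1) %*% t(inv[1:3, , drop = FALSE])
  if (is.matrix(xyz)) out else drop(out)
}

#' Compare two grids for compatibility
#'
#' Grids match when dims are identical and affines agree elementwise within
#' `tol`. Mismatched grids are rejected throughout the package — masks are
#' assumed pre-normalised to one template, and resampling is deliberately
#' not performed.
#'
#' @param a,b [VolumeGrid-class] objects.
#' @param tol absolute tolerance on affine entries.
#' @export
gridsCompatible <- function(a, b, tol = 1e-4) {
  identical(a@dims, b@dims) && max(abs(a@affine - b@affine)) <= tol
}

stopIfGridMismatch <- function(a, b, tol = 1e-4) {
  if (!gridsCompatible(a, b, tol))
    stop("grid mismatch between volumes:\n  affine A = [",
         paste(signif(t(a@affine[1:3, ]), 6), collapse = " "),
         "]\n  affine B = [",
         paste(signif(t(b@affine[1:3, ]), 6), collapse = " "), "]",
         call. = FALSE)
  invisible(TRUE)
}

## linear index <-> 0-based ijk triples
linearToIjk <- function(grid, idx) {
  d <- grid@dims
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(i, j, k)
}

ijkToLinear <- function(grid, ijk) {
  d <- grid@dims
  as.integer(ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3]) + 1L)
}

#' Construct a LesionMask
#'
#' @param subjectId subject identifier.
#' @param grid a [VolumeGrid-class].
#' @param x either a 3D binary array on the grid, an integer vector of
#'   1-based linear voxel indices, or an n x 3 matrix of 0-based (i,j,k)
#'   voxel index triples.
#' @return a [LesionMask-class].
#' @export
lesionMask <- function(subjectId, grid, x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    stopifnot(identical(dim(x), as.integer(grid@dims)))
    idx <- which(x != 0)
  } else if (is.matrix(x)) {
    idx <- ijkToLinear(grid, x)
  } else {
    idx <- as.integer(x)
  }
  new("LesionMask", subjectId = as.character(subjectId), grid = grid,
      indices = sort(unique(as.integer(idx))))
}

#' LesionMask accessors
#'
#' @param mask a [LesionMask-class].
#' @return `lesionVolume`: volume in cubic millimetres;
#'   `voxelCoordinates`: n x 3 matrix of 0-based voxel indices;
#'   `lesionIndices`: 1-based linear indices; `subjectId`: the id;
#'   `maskArray`: dense binary 3D array.
#' @export
lesionVolume <- function(mask) length(mask@indices) * voxelVolume(mask@grid)

#' @rdname lesionVolume
#' @export
voxelCoordinates <- function(mask) linearToIjk(mask@grid, mask@indices)

#' @rdname lesionVolume
#' @export
lesionIndices <- function(mask) mask@indices

#' @rdname lesionVolume
#' @export
subjectId <- function(mask) mask@subjectId

#' @rdname lesionVolume
#' @export
maskArray <- function(mask) {
  a <- array(0L, mask@grid@dims)
  a[mask@indices] <- 1L
  a
}
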