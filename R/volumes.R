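#' @useDynLib tractatlas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd var
NULL

# Package-wide convention: tensors are stored per voxel as the 6 unique
# components of the symmetric 3x3 matrix in lower-triangular order
# (Dxx, Dxy, Dyy, Dxz, Dyz, Dzz).  Voxel index (i,j,k) maps to world
# coordinates (mm) as affine %*% c(i-1, j-1, k-1, 1): the affine uses
# 0-based indices as in NIfTI, R arrays are 1-based.

TENSOR_COMP_NAMES <- c("Dxx", "Dxy", "Dyy", "Dxz", "Dyz", "Dzz")

#' Scalar image volume
#'
#' A 3-D scalar image with a voxel-to-world affine (mm) and a validity mask.
#'
#' @param values numeric 3-D array.
#' @param affine 4x4 voxel-to-world matrix (mm, 0-based voxel indices).
#' @param mask logical 3-D array of valid voxels; default all finite values.
#' @return object of class `scalar_volume` with fields `shape`, `affine`,
#'   `values`, `mask`.
#' @export
scalar_volume <- function(values, affine = diag(4), mask = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  affine <- validate_affine(affine)
  if (is.null(mask)) mask <- array(is.finite(values), dim(values))
  stopifnot(identical(dim(mask), dim(values)))
  structure(list(shape = dim(values), affine = affine,
                 values = values, mask = mask),
            class = "scalar_volume")
}

#' Diffusion tensor volume
#'
#' A 3-D grid of symmetric 3x3 diffusion tensors (mm^2/s) stored as a 4-D
#' array whose last axis holds the 6 unique components in the order
#' Dxx, Dxy, Dyy, Dxz, Dyz, Dzz.
#'
#' @param tensors numeric 4-D array `(nx, ny, nz, 6)`.
#' @param affine 4x4 voxel-to-world matrix (mm).
#' @param mask logical 3-D array; voxels with non-finite components are
#'   dropped from the mask with a warning.
#' @return object of class `tensor_volume`.
#' @export
tensor_volume <- function(tensors, affine = diag(4), mask = NULL) {
  stopifnot(is.array(tensors), length(dim(tensors)) == 4L,
            dim(tensors)[4] == 6L)
  affine <- validate_affine(affine)
  shape <- dim(tensors)[1:3]
  finite <- array(rowSums(!is.finite(matrix(tensors, ncol = 6L))) == 0L,
                  shape)
  if (is.null(mask)) {
    mask <- finite
  } else {
    stopifnot(identical(dim(mask), shape))
    bad <- sum(mask & !finite)
    if (bad > 0L) {
      warning(sprintf("%d in-mask voxels with non-finite tensors excluded",
                      bad))
      mask <- mask & finite
    }
  }
  structure(list(shape = shape, affine = affine,
                 tensors = tensors, mask = mask),
            class = "tensor_volume")
}

#' Dense deformation field
#'
#' Per-voxel 3-vector displacement in mm, world frame, on the target grid:
#' a point at world position `x` on the target grid maps to `x + u(x)` in
#' the source space (pull-back convention; resampling a source image onto
#' the target grid samples it at the mapped positions).
#'
#' @param disp numeric 4-D array `(nx, ny, nz, 3)`, mm.
#' @param affine 4x4 voxel-to-world matrix of the target grid.
#' @param source_space,target_space free-form space tags used to validate
#'   transform chains.
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(disp, affine = diag(4),
                              source_space = "source",
                              target_space = "target") {
  stopifnot(is.array(disp), length(dim(disp)) == 4L, dim(disp)[4] == 3L)
  affine <- validate_affine(affine)
  structure(list(shape = dim(disp)[1:3], affine = affine, disp = disp,
                 source_space = source_space, target_space = target_space),
            class = "deformation_field")
}

#' Affine world-to-world transform
#'
#' @param matrix 4x4 matrix mapping world (mm) points of the target space
#'   to world points of the source space (same pull-back convention as
#'   [deformation_field()]).
#' @param source_space,target_space space tags.
#' @return object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, source_space = "source",
                             target_space = "target") {
  stopifnot(is.matrix(matrix), all(dim(matrix) == c(4L, 4L)))
  if (abs(det(matrix[1:3, 1:3])) < 1e-12)
    stop("affine transform is singular")
  if (det(matrix[1:3, 1:3]) <= 0)
    stop("affine transform must preserve orientation (positive determinant)")
  structure(list(matrix = matrix, source_space = source_space,
                 target_space = target_space),
            class = "affine_transform")
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)), all(is.finite(affine)))
  if (abs(det(affine[1:3, 1:3])) < 1e-12) stop("singular voxel-to-world affine")
  affine
}

#' Voxel size of an affine (mm per voxel along each axis)
#' @param affine 4x4 voxel-to-world matrix.
#' @return length-3 numeric.
#' @export
voxel_size <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b)) stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

# World coordinates (n x 3, mm) of every voxel of a grid, column-major order.
grid_world <- function(shape, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1,
                               j = seq_len(shape[2]) - 1,
                               k = seq_len(shape[3]) - 1))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

# World (mm) -> continuous 1-based voxel coordinates.
world_to_voxel <- function(points, affine) {
  points <- rbind_pts(points)
  inv <- solve(affine)
  sweep(points %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+") + 1
}

# Continuous 1-based voxel coordinates -> world (mm).
voxel_to_world <- function(vox, affine) {
  vox <- rbind_pts(vox) - 1
  sweep(vox %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

rbind_pts <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %s, voxel %s mm, %d in-mask>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(voxel_size(x$affine), 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume %s, voxel %s mm, %d in-mask>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(voxel_size(x$affine), 3), collapse = "x"),
              sum(x$mask)))
  invisible(x)
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field %s: %s -> %s, max |u| %.3g mm>\n",
              paste(x$shape, collapse = "x"), x$target_space,
              x$source_space, max(sqrt(rowSums(matrix(x$disp, ncol = 3)^2)))))
  invisible(x)
}
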