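#' 3D volume on a physical grid
#'
#' A `volume_grid` couples a 3D array of voxel values with a 4x4 affine that
#' maps zero-based voxel indices `(i, j, k)` to physical coordinates in mm
#' (the NIfTI convention). All geometric computation in this package happens
#' in physical mm; voxel indices appear only at I/O boundaries.
#'
#' @param data numeric/integer/logical 3D array.
#' @param affine 4x4 numeric matrix, last row `(0, 0, 0, 1)`; maps
#'   homogeneous zero-based voxel indices to mm. Defaults to
#'   `diag(c(spacing, 1))` with `origin` as translation.
#' @param spacing length-3 voxel size in mm, used only when `affine` is NULL.
#' @param origin length-3 world position of voxel `(0, 0, 0)`, used only when
#'   `affine` is NULL.
#' @return An object of class `volume_grid` with elements `data` and `affine`.
#' @export
volume_grid <- function(data, affine = NULL, spacing = c(1, 1, 1),
                        origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last affine row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine is singular")
  structure(list(data = data, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$data)
  sp <- grid_spacing(x)
  cat(sprintf("<volume_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3]))
  invisible(x)
}

#' Voxel size along each array axis
#'
#' Column norms of the affine's linear part, in mm. For rigid (rotation-only)
#' affines these are the physical voxel edge lengths.
#'
#' @param grid a [volume_grid].
#' @return length-3 numeric vector, mm.
#' @export
grid_spacing <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Map zero-based voxel indices to world mm
#'
#' @param grid a [volume_grid].
#' @param ijk0 n x 3 matrix of zero-based voxel indices (may be fractional).
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk0) {
  ijk0 <- matrix(ijk0, ncol = 3)
  sweep(ijk0 %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4], `+`)
}

#' Map world mm to zero-based (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of zero-based fractional voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(grid$affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], `+`)
}

#' World coordinates of selected voxel centers
#'
#' @param grid a [volume_grid].
#' @param which logical array matching `dim(grid$data)`, or NULL for all
#'   voxels.
#' @return n x 3 matrix of mm coordinates of the selected voxel centers.
#' @export
voxel_centers <- function(grid, which = NULL) {
  d <- dim(grid$data)
  if (is.null(which)) {
    idx <- seq_len(prod(d))
  } else {
    stopifnot(identical(dim(which), d))
    idx <- which(which)
  }
  ijk <- arrayInd(idx, d) - 1L
  voxel_to_world(grid, ijk)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) <= tol
}

assert_same_grid <- function(a, b) {
  if (!same_grid(a, b))
    stop("volumes are not on the same grid (dimensions/affine differ)")
  invisible(TRUE)
}

as_binary_array <- function(grid, what = "mask") {
  v <- grid$data
  u <- unique(as.vector(v))
  if (!all(u %in% c(0, 1)))
    stop(sprintf("%s must be binary (values 0/1); found values: %s",
                 what, paste(utils::head(setdiff(u, c(0, 1)), 5), collapse = ", ")))
  array(v != 0, dim = dim(v))
}
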