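#' Voxel grid: a discretized brain space
#'
#' A `voxel_grid` couples an array shape with a 4x4 affine mapping 0-based
#' voxel indices to world millimetre coordinates (NIfTI convention).  All
#' volumes in the pipeline -- ALE maps, Z maps, expression maps, cluster and
#' atlas label maps -- live on such a grid.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param affine 4x4 numeric matrix, invertible; maps `c(i, j, k, 1)` with
#'   0-based indices to `c(x, y, z, 1)` in mm.
#' @return An object of class `voxel_grid` with elements `shape`, `affine`
#'   and `voxel_volume` (mm^3, the absolute determinant of the linear part).
#' @export
voxel_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- unname(as.matrix(affine))
  stopifnot(identical(dim(affine), c(4L, 4L)))
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps)
    stop("grid affine must be invertible")
  structure(
    list(shape = shape, affine = affine, voxel_volume = abs(det3)),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %dx%dx%d, voxel %.3g mm^3>\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_volume))
  invisible(x)
}

#' Default Talairach-aligned analysis grid
#'
#' Axis-aligned isotropic grid whose voxel centres cover the requested
#' bounding box (defaults span +/-90, +/-126 and +/-72 mm, a generous
#' Talairach-space brain box).
#'
#' @param voxel_mm isotropic voxel edge in mm (default 2).
#' @param xlim,ylim,zlim numeric length-2 world extents in mm.
#' @return a [voxel_grid()].
#' @export
default_grid <- function(voxel_mm = 2,
                         xlim = c(-90, 90), ylim = c(-126, 126),
                         zlim = c(-72, 72)) {
  stopifnot(voxel_mm > 0)
  n <- function(lim) as.integer(floor(diff(range(lim)) / voxel_mm)) + 1L
  shape <- c(n(xlim), n(ylim), n(zlim))
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- c(min(xlim), min(ylim), min(zlim))
  voxel_grid(shape, affine)
}

#' World-mm coordinates of every voxel centre
#'
#' @param grid a [voxel_grid()].
#' @return an `prod(shape)` x 3 matrix in R array (column-major) order.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape) - 1L
  ijk1 <- cbind(idx, 1)
  xyz <- ijk1 %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world mm coordinates to (fractional, 1-based) voxel indices
#' @param grid a [voxel_grid()].
#' @param xyz n x 3 matrix of mm coordinates.
#' @return n x 3 matrix of 1-based fractional indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  inv <- solve(grid$affine)
  ijk <- cbind(xyz, 1) %*% t(inv)
  ijk[, 1:3, drop = FALSE] + 1
}

#' Do two grids coincide?
#' @param a,b voxel grids.
#' @param tol affine tolerance in mm.
#' @export
same_grid <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

#' Scalar volume on a voxel grid
#'
#' @param grid a [voxel_grid()].
#' @param values numeric array matching `grid$shape` (a scalar is recycled).
#' @param mask logical array marking in-brain voxels; by default the
#'   finite-value support of `values`.
#' @return an object of class `brain_volume` with elements `grid`, `values`
#'   and `mask`.  Values must be finite wherever the mask is `TRUE`.
#' @export
brain_volume <- function(grid, values, mask = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (length(values) == 1L) values <- array(values, dim = grid$shape)
  values <- array(as.numeric(values), dim = grid$shape)
  if (is.null(mask)) {
    mask <- is.finite(values)
  } else {
    if (length(mask) == 1L) mask <- array(mask, dim = grid$shape)
    mask <- array(as.logical(mask), dim = grid$shape)
  }
  if (any(!is.finite(values[mask])))
    stop("volume has non-finite values inside its mask")
  structure(list(grid = grid, values = values, mask = mask),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<brain_volume %dx%dx%d, %d in-mask voxels, range [%.4g, %.4g]>\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              sum(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

# internal: check two volumes share a grid, else dimension error
check_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a$grid, b$grid))
    stop(sprintf("dimension error: %s are defined on different grids", what))
  invisible(TRUE)
}

#' Ellipsoidal brain mask volume
#'
#' A smooth stand-in for a brain mask: voxels whose world coordinates fall
#' inside an axis-aligned ellipsoid centred at `centre` with the given
#' semi-axes.  Used by the synthetic-data generators and tests.
#'
#' @param grid a [voxel_grid()].
#' @param semi_axes numeric length 3, ellipsoid semi-axes in mm.
#' @param centre numeric length 3, ellipsoid centre in mm.
#' @return a `brain_volume` of 0/1 values whose mask marks the ellipsoid.
#' @export
ellipsoid_mask <- function(grid, semi_axes = c(70, 88, 60),
                           centre = c(0, 0, 0)) {
  xyz <- grid_coords(grid)
  u <- sweep(xyz, 2, centre)
  inside <- (u[, 1] / semi_axes[1])^2 + (u[, 2] / semi_axes[2])^2 +
    (u[, 3] / semi_axes[3])^2 <= 1
  m <- array(inside, dim = grid$shape)
  brain_volume(grid, array(as.numeric(m), grid$shape), mask = m)
}
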