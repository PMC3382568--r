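#' Acquisition geometry for a sparse-sampling fMRI grid
#'
#' Bundles the voxel grid, voxel size, the voxel-to-world affine and a brain
#' mask.  World coordinates are in mm (MNI-like axes); voxel indices are
#' 1-based, so world = affine %*% c(i - 1, j - 1, k - 1, 1).
#'
#' @param grid_shape Integer triple, voxels per axis (each >= 8).
#' @param voxel_size Numeric triple, voxel edge lengths in mm (> 0).
#' @param origin World-mm coordinate of the centre of voxel (1,1,1).  Ignored
#'   when `affine` is given.
#' @param affine Optional 4x4 voxel-to-world matrix; defaults to a diagonal
#'   scaling by `voxel_size` translated to `origin`.
#' @param mask Optional logical array of dimension `grid_shape`.  Defaults to
#'   the full grid minus a one-voxel border.
#' @return An object of class `acq_geometry`.
#' @export
acq_geometry <- function(grid_shape, voxel_size = c(3, 3, 3),
                         origin = c(0, 0, 0), affine = NULL, mask = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L)
  if (any(grid_shape < 8L))
    stop("all grid dimensions must be >= 8")
  if (any(voxel_size <= 0))
    stop("voxel sizes must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    affine[1:3, 4] <- origin
  }
  affine <- unname(as.matrix(affine))
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (is.null(mask)) {
    mask <- array(FALSE, grid_shape)
    mask[2:(grid_shape[1] - 1L),
         2:(grid_shape[2] - 1L),
         2:(grid_shape[3] - 1L)] <- TRUE
  }
  if (!is.logical(mask) || !all(dim(mask) == grid_shape))
    stop("mask must be a logical array of dimension grid_shape")
  if (!any(mask))
    stop("mask is empty")
  structure(
    list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
         affine = affine, mask = mask),
    class = "acq_geometry"
  )
}

#' Default desk-scale geometry covering the planted region centres
#'
#' A 38x40x42 grid of 3-mm isotropic voxels whose field of view contains all
#' default 6-mm region spheres (world extent roughly x in \[-69, 42\],
#' y in \[-75, 42\], z in \[-57, 66\] mm), with a box mask inset one voxel
#' from the grid edge.
#'
#' @return An `acq_geometry`.
#' @export
default_geometry <- function() {
  acq_geometry(grid_shape = c(38L, 40L, 42L), voxel_size = c(3, 3, 3),
               origin = c(-69, -75, -57))
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat("acq_geometry:", paste(x$grid_shape, collapse = " x "),
      "voxels @", paste(x$voxel_size, collapse = " x "), "mm;",
      sum(x$mask), "voxels in mask\n")
  invisible(x)
}

#' Map voxel indices to world mm and back
#'
#' @param geometry An `acq_geometry`.
#' @param voxels Integer matrix (n x 3) of 1-based voxel indices, or a
#'   length-3 vector.
#' @return `voxel_to_world`: an n x 3 matrix of world-mm coordinates.
#' @export
voxel_to_world <- function(geometry, voxels) {
  v <- rbind_coords(voxels)
  h <- cbind(v - 1, 1) %*% t(geometry$affine)
  h[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @param world Numeric matrix (n x 3) of world-mm coordinates, or a
#'   length-3 vector.
#' @return `world_to_voxel`: an n x 3 matrix of (fractional) 1-based voxel
#'   indices.
#' @export
world_to_voxel <- function(geometry, world) {
  w <- rbind_coords(world)
  h <- cbind(w, 1) %*% t(solve(geometry$affine))
  h[, 1:3, drop = FALSE] + 1
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot(ncol(x) == 3L)
  x
}

#' Voxel volume in cubic mm
#' @param geometry An `acq_geometry`.
#' @return Scalar mm^3 per voxel.
#' @export
voxel_volume <- function(geometry) prod(geometry$voxel_size)

#' World coordinates of every in-mask voxel centre
#' @param geometry An `acq_geometry`.
#' @return n_mask x 3 matrix.
#' @keywords internal
mask_world_coords <- function(geometry) {
  idx <- which(geometry$mask)
  voxel_to_world(geometry, arrayInd(idx, geometry$grid_shape))
}

same_geometry <- function(a, b) {
  identical(a$grid_shape, b$grid_shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size)) &&
    isTRUE(all.equal(a$affine, b$affine)) &&
    identical(a$mask, b$mask)
}
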