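#' Gaussian FWHM to sigma
#' @param fwhm Full width at half maximum.
#' @return Standard deviation of the equivalent Gaussian.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# One-axis smoothing matrix: row i holds the truncated (4 sigma), renormalized
# Gaussian kernel centred on voxel i.  sigma_vox in voxel units.
gaussian_kernel_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- ceiling(4 * sigma_vox)
  off <- -r:r
  w <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

# Cache of per-axis kernel matrices for a geometry + fwhm.
smoothing_kernels <- function(geometry, fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  lapply(1:3, function(a)
    gaussian_kernel_matrix(geometry$grid_shape[a],
                           sigma / geometry$voxel_size[a]))
}

# Apply separable per-axis kernels to a 3-D array.
apply_kernels <- function(vol, kernels) {
  d <- dim(vol)
  vol <- array(kernels[[1]] %*% matrix(vol, d[1], d[2] * d[3]), d)
  vol <- aperm(vol, c(2, 1, 3))
  vol <- array(kernels[[2]] %*% matrix(vol, d[2], d[1] * d[3]),
               c(d[2], d[1], d[3]))
  vol <- aperm(vol, c(2, 1, 3))
  array(matrix(vol, d[1] * d[2], d[3]) %*% t(kernels[[3]]), d)
}

#' Spatially smooth a volume with a separable Gaussian kernel
#'
#' The kernel standard deviation per axis is `fwhm / (2 sqrt(2 ln 2))` mm
#' converted to voxels by the axis voxel size; the kernel is truncated at
#' 4 sigma and renormalized, so a constant image is unchanged and the total
#' of a delta image is preserved.  With `mask_renorm = TRUE` smoothing is
#' additionally renormalized inside the brain mask (smooth(x * m) /
#' smooth(m)), which avoids attenuation at the mask edge on small grids.
#' `fwhm = 0` is the identity.
#'
#' @param vol 3-D numeric array matching the geometry grid.
#' @param fwhm Smoothing kernel FWHM in mm (>= 0).
#' @param geometry An `acq_geometry`.
#' @param mask_renorm Renormalize within the mask (default TRUE).
#' @return Smoothed array (zero outside the mask when `mask_renorm`).
#' @export
gaussian_smooth <- function(vol, fwhm, geometry, mask_renorm = TRUE) {
  stopifnot(fwhm >= 0, all(dim(vol) == geometry$grid_shape))
  if (fwhm == 0) return(vol)
  kernels <- smoothing_kernels(geometry, fwhm)
  if (!mask_renorm) return(apply_kernels(vol, kernels))
  m <- geometry$mask + 0
  num <- apply_kernels(vol * m, kernels)
  den <- apply_kernels(m, kernels)
  out <- array(0, dim(vol))
  out[geometry$mask] <- num[geometry$mask] / den[geometry$mask]
  out
}

#' Convert a run's trial volumes to percent signal change
#'
#' Computes psc = 100 (v - b) / b voxelwise, where the baseline b is the
#' voxelwise mean over the run's null trials (`baseline = "null_mean"`,
#' the default — the sparse-sampling design has no within-trial baseline) or
#' over all the run's volumes (`"run_mean"`).  PSC is invariant to a global
#' multiplicative rescaling of the run.
#'
#' @param volumes List of 3-D arrays, or a 4-D array with trials along the
#'   fourth dimension (one acquired volume per trial).
#' @param is_null Logical per-trial vector flagging null (rest) trials;
#'   required for `"null_mean"`.
#' @param geometry An `acq_geometry`.
#' @param baseline `"null_mean"` or `"run_mean"`.
#' @return List with `psc` (list of 3-D arrays, zero outside the mask) and
#'   `baseline` (the baseline volume).
#' @export
percent_signal_change <- function(volumes, is_null = NULL, geometry,
                                  baseline = c("null_mean", "run_mean")) {
  baseline <- match.arg(baseline)
  volumes <- as_volume_list(volumes, geometry)
  if (baseline == "null_mean") {
    if (is.null(is_null) || !any(is_null))
      stop("baseline = 'null_mean' needs at least one null trial")
    stopifnot(length(is_null) == length(volumes))
    base_set <- volumes[is_null]
  } else {
    base_set <- volumes
  }
  b <- Reduce(`+`, base_set) / length(base_set)
  bad <- sum(b[geometry$mask] <= 0)
  if (bad > 0)
    stop("baseline not positive at ", bad, " in-mask voxel(s)")
  msk <- geometry$mask
  psc <- lapply(volumes, function(v) {
    out <- array(0, dim(v))
    out[msk] <- 100 * (v[msk] - b[msk]) / b[msk]
    out
  })
  list(psc = psc, baseline = b)
}

as_volume_list <- function(volumes, geometry) {
  if (is.array(volumes) && length(dim(volumes)) == 4L) {
    stopifnot(all(dim(volumes)[1:3] == geometry$grid_shape))
    volumes <- lapply(seq_len(dim(volumes)[4]),
                      function(i) volumes[, , , i])
  }
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  for (v in volumes) stopifnot(all(dim(v) == geometry$grid_shape))
  volumes
}

#' Smooth then convert a run to percent signal change
#'
#' The standard preprocessing applied to each run before any classification:
#' spatial smoothing of the raw volumes followed by PSC conversion
#' (order configurable via `smooth_first = FALSE`).  Slice-time/motion
#' correction and template normalization do not apply to synthetic volumes
#' and are deliberate no-ops here.
#'
#' @inheritParams percent_signal_change
#' @param fwhm Smoothing FWHM in mm (default 6).
#' @param smooth_first Smooth raw volumes before PSC (default TRUE).
#' @return As [percent_signal_change()].
#' @export
preprocess_run <- function(volumes, is_null, geometry, fwhm = 6,
                           baseline = "null_mean", smooth_first = TRUE) {
  volumes <- as_volume_list(volumes, geometry)
  if (smooth_first && fwhm > 0) {
    kernels <- smoothing_kernels(geometry, fwhm)
    m <- geometry$mask + 0
    den <- apply_kernels(m, kernels)
    msk <- geometry$mask
    volumes <- lapply(volumes, function(v) {
      out <- array(0, dim(v))
      out[msk] <- apply_kernels(v * m, kernels)[msk] / den[msk]
      out
    })
  }
  res <- percent_signal_change(volumes, is_null, geometry, baseline)
  if (!smooth_first && fwhm > 0)
    res$psc <- lapply(res$psc, gaussian_smooth, fwhm = fwhm,
                      geometry = geometry)
  res
}
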