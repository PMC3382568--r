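connectivity_offsets <- function(connectivity) {
  face <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  edge <- rbind(c(1, 1, 0), c(1, -1, 0), c(1, 0, 1),
                c(1, 0, -1), c(0, 1, 1), c(0, 1, -1))
  corner <- rbind(c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
  switch(connectivity,
         "face" = face,
         "face+edge" = rbind(face, edge),
         "face+edge+corner" = rbind(face, edge, corner),
         stop("unknown connectivity: ", connectivity))
}

#' Label connected components of a voxel set
#'
#' Union-find connected-component labelling of a set of voxels in a 3-D
#' grid at face (6-neighbour), face+edge (18) or face+edge+corner (26)
#' connectivity.
#'
#' @param idx Linear (1-based) indices of the voxels in the set.
#' @param grid_shape Integer triple.
#' @param connectivity One of `"face"`, `"face+edge"`,
#'   `"face+edge+corner"`.
#' @return Integer cluster id per element of `idx` (ids are 1..n_clusters).
#' @export
label_clusters <- function(idx, grid_shape, connectivity = "face") {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  offs <- connectivity_offsets(connectivity)   # half-space offsets
  coords <- arrayInd(idx, grid_shape)
  pos <- integer(prod(grid_shape))
  pos[idx] <- seq_len(n)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  d1 <- grid_shape[1]; d12 <- d1 * grid_shape[2]
  for (o in seq_len(nrow(offs))) {
    nc <- coords + matrix(offs[o, ], n, 3, byrow = TRUE)
    ok <- nc[, 1] >= 1 & nc[, 1] <= grid_shape[1] &
          nc[, 2] >= 1 & nc[, 2] <= grid_shape[2] &
          nc[, 3] >= 1 & nc[, 3] <= grid_shape[3]
    if (!any(ok)) next
    nidx <- (nc[ok, 3] - 1) * d12 + (nc[ok, 2] - 1) * d1 + nc[ok, 1]
    j <- pos[nidx]
    hit <- j > 0L
    src <- which(ok)[hit]; dst <- j[hit]
    for (e in seq_along(src)) {
      a <- find(src[e]); b <- find(dst[e])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots))
}

#' Monte-Carlo minimum cluster size for familywise correction
#'
#' Simulates null volumes of Gaussian noise smoothed to `noise_fwhm` inside
#' the mask, thresholds |z| at the two-tailed `voxel_p` quantile, and
#' records the maximum cluster size per iteration.  The minimum surviving
#' size is the `ceiling((1 - corrected_alpha) * n_iter)`-th order statistic
#' of those maxima plus one: observed clusters at least that large occur
#' under the null with familywise probability about `corrected_alpha`.
#'
#' @param geometry An `acq_geometry`.
#' @param voxel_p Two-tailed per-voxel threshold (default 0.01).
#' @param corrected_alpha Familywise alpha (default 0.05).
#' @param n_iter Number of null simulations (>= 100; default 1000).
#' @param noise_fwhm Spatial smoothness of the null noise in mm.
#' @param connectivity Cluster connectivity (default `"face"`).
#' @param seed RNG seed.
#' @return List with `min_voxels`, `min_mm3`, and the simulated `max_sizes`.
#' @export
monte_carlo_cluster_threshold <- function(geometry, voxel_p = 0.01,
                                          corrected_alpha = 0.05,
                                          n_iter = 1000L, noise_fwhm = 6,
                                          connectivity = "face",
                                          seed = 1L) {
  stopifnot(voxel_p > 0, voxel_p < 1,
            corrected_alpha > 0, corrected_alpha < 1, n_iter >= 100L)
  msk_idx <- which(geometry$mask)
  if (length(msk_idx) < 100L)
    warning("mask has fewer than 100 voxels; null distribution unstable")
  kernels <- if (noise_fwhm > 0) smoothing_kernels(geometry, noise_fwhm)
  sdmap <- if (noise_fwhm > 0)
    noise_sd_map(kernels, geometry$grid_shape)
  zcrit <- stats::qnorm(1 - voxel_p / 2)
  set.seed(as.integer(seed))
  grid <- geometry$grid_shape
  max_sizes <- vapply(seq_len(n_iter), function(i) {
    vol <- if (noise_fwhm > 0) draw_noise(kernels, grid, sdmap)
           else array(stats::rnorm(prod(grid)), grid)
    supra <- msk_idx[abs(vol[msk_idx]) > zcrit]
    if (length(supra) == 0L) return(0L)
    cl <- label_clusters(supra, grid, connectivity)
    max(tabulate(cl))
  }, integer(1))
  k <- sort(max_sizes)[ceiling((1 - corrected_alpha) * n_iter)] + 1L
  list(min_voxels = k, min_mm3 = k * voxel_volume(geometry),
       max_sizes = max_sizes)
}

#' Threshold a group t-map and extract cluster-corrected regions
#'
#' Applies the two-tailed t quantile at `voxel_p` with the map's df,
#' labels connected components separately for positive (MT-associated) and
#' negative (LT-associated) excursions, and flags clusters reaching the
#' Monte-Carlo minimum size as survivors.  Sub-threshold clusters are kept
#' in the table with `survived = FALSE` (uncorrected report).
#'
#' @param tmap A `group_tmap`.
#' @param voxel_p Two-tailed per-voxel threshold (default 0.01).
#' @param min_cluster_voxels Minimum surviving cluster size in voxels, from
#'   [monte_carlo_cluster_threshold()].
#' @param connectivity Cluster connectivity (default `"face"`).
#' @return A `roi_set`: `table` (name, sign, n_voxels, volume_mm3, peak
#'   t and world coordinates, survived), `voxels` (list of linear index
#'   vectors), `labels` (integer volume over surviving regions), plus
#'   `geometry` and `min_cluster_voxels`.  An empty set is valid.
#' @export
threshold_and_cluster <- function(tmap, voxel_p = 0.01,
                                  min_cluster_voxels = 1L,
                                  connectivity = "face") {
  stopifnot(inherits(tmap, "group_tmap"), tmap$df >= 1L)
  geom <- tmap$geometry
  tcrit <- stats::qt(1 - voxel_p / 2, tmap$df)
  tv <- tmap$t
  tv[is.na(tv)] <- 0
  rows <- list(); voxsets <- list()
  for (sgn in c(1, -1)) {
    supra <- which(geom$mask & (sgn * tv > tcrit))
    if (length(supra) == 0L) next
    cl <- label_clusters(supra, geom$grid_shape, connectivity)
    assoc <- if (sgn > 0) tmap$convention[["positive"]]
             else tmap$convention[["negative"]]
    sizes <- tabulate(cl)
    for (ci in order(sizes, decreasing = TRUE)) {
      vox <- supra[cl == ci]
      peak <- vox[which.max(abs(tv[vox]))]
      pk_world <- voxel_to_world(geom, arrayInd(peak, geom$grid_shape))
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("%s_%d", assoc, sum(vapply(rows, function(r)
          r$sign == assoc, logical(1))) + 1L),
        sign = assoc,
        n_voxels = length(vox),
        volume_mm3 = length(vox) * voxel_volume(geom),
        peak_t = tv[peak],
        peak_x = pk_world[1], peak_y = pk_world[2], peak_z = pk_world[3],
        survived = length(vox) >= min_cluster_voxels
      )
      voxsets[[length(voxsets) + 1L]] <- vox
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), sign = character(),
               n_voxels = integer(), volume_mm3 = numeric(),
               peak_t = numeric(), peak_x = numeric(), peak_y = numeric(),
               peak_z = numeric(), survived = logical())
  labels <- array(0L, geom$grid_shape)
  surv <- which(tab$survived)
  for (k in seq_along(surv)) labels[voxsets[[surv[k]]]] <- k
  structure(list(table = tab, voxels = voxsets, labels = labels,
                 geometry = geom, voxel_p = voxel_p,
                 min_cluster_voxels = min_cluster_voxels,
                 convention = tmap$convention),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat("roi_set:", nrow(x$table), "cluster(s),",
      sum(x$table$survived), "surviving (min size",
      x$min_cluster_voxels, "voxels)\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Surviving regions of a roi_set
#' @param roiset A `roi_set`.
#' @return A list with `names`, `signs` and `voxels` for survivors only.
#' @export
surviving_rois <- function(roiset) {
  keep <- which(roiset$table$survived)
  list(names = roiset$table$name[keep],
       signs = roiset$table$sign[keep],
       voxels = roiset$voxels[keep])
}
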