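test_that("connected components follow the chosen connectivity", {
  grid <- c(3, 3, 3)
  # two voxels sharing a face
  idx <- c(1, 2)                     # (1,1,1) and (2,1,1)
  cl <- label_clusters(idx, grid, "face")
  expect_equal(length(unique(cl)), 1)
  # diagonal (edge) neighbours split under face connectivity
  idx2 <- c(1, 5)                    # (1,1,1) and (2,2,1)
  expect_equal(length(unique(label_clusters(idx2, grid, "face"))), 2)
  expect_equal(length(unique(label_clusters(idx2, grid, "face+edge"))), 1)
  # corner neighbours
  idx3 <- c(1, 14)                   # (1,1,1) and (2,2,2)
  expect_equal(length(unique(label_clusters(idx3, grid, "face+edge"))), 2)
  expect_equal(
    length(unique(label_clusters(idx3, grid, "face+edge+corner"))), 1)
  expect_length(label_clusters(integer(0), grid), 0)
})

test_that("labelling agrees with the igraph oracle on random sets", {
  skip_if_not_installed("igraph")
  set.seed(14)
  grid <- c(8, 8, 8)
  for (i in 1:10) {
    idx <- which(runif(prod(grid)) < 0.2)
    ours <- label_clusters(idx, grid, "face")
    orc <- igraph_cluster_oracle(idx, grid, "face")
    # same partition: cluster sizes and co-membership match
    expect_equal(sort(tabulate(ours)), sort(tabulate(orc)))
    expect_true(all((outer(ours, ours, "==") ==
                       outer(orc, orc, "=="))))
  }
})

test_that("null max-cluster distribution matches the independent-voxel oracle", {
  skip_if_not_installed("igraph")
  grid <- c(4, 4, 4)
  mask <- array(FALSE, c(8, 8, 8)); mask[1:4, 1:4, 1:4] <- TRUE
  geom <- acq_geometry(c(8, 8, 8), c(3, 3, 3), mask = mask)
  p <- 0.05
  mc <- suppressWarnings(
    monte_carlo_cluster_threshold(geom, voxel_p = p,
                                  corrected_alpha = 0.05,
                                  n_iter = 4000, noise_fwhm = 0,
                                  seed = 5))
  orc <- bernoulli_max_cluster_oracle(grid, p, 4000, seed = 6)
  bins <- function(v) c(sum(v == 0), sum(v == 1), sum(v == 2),
                        sum(v >= 3))
  tab <- rbind(bins(mc$max_sizes), bins(orc))
  keep <- colSums(tab) > 0
  chi <- suppressWarnings(chisq.test(tab[, keep]))
  expect_gt(chi$p.value, 0.001)
})

test_that("Monte-Carlo threshold is deterministic and monotone", {
  geom <- tiny_geometry(12)
  a <- monte_carlo_cluster_threshold(geom, n_iter = 300, noise_fwhm = 6,
                                     seed = 2)
  b <- monte_carlo_cluster_threshold(geom, n_iter = 300, noise_fwhm = 6,
                                     seed = 2)
  expect_identical(a$min_voxels, b$min_voxels)
  expect_equal(a$min_mm3, a$min_voxels * 27)
  # non-decreasing in smoothness
  smoother <- monte_carlo_cluster_threshold(geom, n_iter = 300,
                                            noise_fwhm = 12, seed = 2)
  expect_gte(smoother$min_voxels, a$min_voxels)
  # non-increasing in voxel_p (stricter voxel threshold)
  stricter <- monte_carlo_cluster_threshold(geom, voxel_p = 0.001,
                                            n_iter = 300, noise_fwhm = 6,
                                            seed = 2)
  expect_lte(stricter$min_voxels, a$min_voxels)
  small_mask <- array(FALSE, c(8, 8, 8))
  small_mask[1:4, 1:4, 1:4] <- TRUE
  expect_warning(
    monte_carlo_cluster_threshold(
      acq_geometry(c(8, 8, 8), c(3, 3, 3), mask = small_mask),
      n_iter = 100, noise_fwhm = 0, seed = 1),
    "100 voxels")
})

test_that("thresholding and clustering a toy t-map is hand-checkable", {
  geom <- tiny_geometry(9)
  tarr <- array(0, geom$grid_shape)
  df <- 19
  tcrit <- qt(1 - 0.01 / 2, df)
  # two face-adjacent positive voxels -> one MT cluster of 2
  tarr[4, 4, 4] <- tcrit + 1
  tarr[5, 4, 4] <- tcrit + 0.5
  # two diagonal negative voxels -> two LT clusters of 1
  tarr[3, 7, 3] <- -(tcrit + 2)
  tarr[4, 8, 4] <- -(tcrit + 1)
  tm <- as_group_tmap(tarr, geom, df)
  rs <- threshold_and_cluster(tm, voxel_p = 0.01, min_cluster_voxels = 2)
  expect_equal(nrow(rs$table), 3)
  mt <- rs$table[rs$table$sign == "MT", ]
  expect_equal(mt$n_voxels, 2)
  expect_true(mt$survived)
  expect_equal(mt$volume_mm3, 54)
  lt <- rs$table[rs$table$sign == "LT", ]
  expect_equal(lt$n_voxels, c(1, 1))
  expect_false(any(lt$survived))
  # the peak of the MT cluster is its largest-|t| voxel in world mm
  expect_equal(unname(c(mt$peak_x, mt$peak_y, mt$peak_z)),
               drop(voxel_to_world(geom, c(4, 4, 4))),
               ignore_attr = TRUE)
  # sub-minimum survivors: a 12-voxel cluster dies under a 13-voxel
  # minimum (324 vs >327 mm^3 at 3 mm voxels)
  tarr2 <- array(0, geom$grid_shape)
  tarr2[3:6, 4:6, 5] <- tcrit + 1          # 12 face-connected voxels
  rs2 <- threshold_and_cluster(as_group_tmap(tarr2, geom, df),
                               voxel_p = 0.01, min_cluster_voxels = 13)
  expect_equal(rs2$table$n_voxels, 12)
  expect_equal(rs2$table$volume_mm3, 324)
  expect_false(rs2$table$survived)
  # an empty set is valid
  rs3 <- threshold_and_cluster(as_group_tmap(array(0, geom$grid_shape),
                                             geom, df))
  expect_equal(nrow(rs3$table), 0)
})
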