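test_that("noise-free volumes are exactly piecewise constant", {
  cfg <- tiny_synth_config(
    ground_truth = tiny_ground_truth(noise_sd = 0))
  ds <- generate_subject(cfg, seed = 3)
  rois <- stutterMVPA:::planted_roi_voxels(cfg)
  trials <- ds$runs[[1]]$trials
  vols <- ds$runs[[1]]$volumes
  mt <- which(trials$type == "MT")[1]
  lt <- which(trials$type == "LT")[1]
  nul <- which(trials$is_null)[1]
  b <- cfg$ground_truth$baseline
  # MT trial: active inside the MT region only
  expect_equal(vols[[mt]][rois[[1]]$voxels],
               rep(b * 1.01, length(rois[[1]]$voxels)))
  expect_equal(vols[[mt]][rois[[2]]$voxels],
               rep(b, length(rois[[2]]$voxels)))
  expect_equal(vols[[lt]][rois[[1]]$voxels[1]], b)
  expect_equal(vols[[lt]][rois[[2]]$voxels[1]], b * 1.01)
  # everywhere outside both regions: baseline
  outside <- setdiff(seq_len(prod(cfg$geometry$grid_shape)),
                     c(rois[[1]]$voxels, rois[[2]]$voxels))
  expect_true(all(vols[[mt]][outside] == b))
  expect_true(all(vols[[nul]] == b))
})

test_that("same config and seed give bit-identical datasets", {
  cfg <- tiny_synth_config()
  d1 <- generate_subject(cfg, seed = 11)
  d2 <- generate_subject(cfg, seed = 11)
  expect_identical(d1, d2)
  d3 <- generate_subject(cfg, seed = 12)
  expect_false(identical(d1$runs[[1]]$volumes[[1]],
                         d3$runs[[1]]$volumes[[1]]))
})

test_that("reference-cohort counts produce the expected label totals", {
  cfg <- tiny_synth_config(counts = reference_cohort()[1, ])
  ds <- generate_subject(cfg, seed = 2, subject_id = 1)
  types <- unlist(lapply(ds$runs, function(r) r$trials$type))
  # patient 1: PAUSE 18 + MR 4 -> 22 LT; PWR 9 + PRO 1 + BREAK 1 -> 11 MT
  expect_equal(sum(types == "LT"), 22)
  expect_equal(sum(types == "MT"), 11)
  expect_equal(sum(types == "WWR"), 2)
  expect_equal(length(types), cfg$n_task + cfg$n_null)
  expect_equal(sum(types == "NULL"), cfg$n_null)
  expect_length(ds$runs, 2)
})

test_that("sample_counts returns printed rows verbatim and resamples reproducibly", {
  fixed <- sample_counts(mode = "fixed")
  expect_equal(nrow(fixed), 20)
  expect_equal(unlist(fixed[20, ], use.names = FALSE),
               c(7, 1, 0, 66, 10, 0))
  expect_equal(unlist(fixed[1, ], use.names = FALSE),
               c(18, 4, 2, 9, 1, 1))
  r1 <- sample_counts(mode = "resample", n = 12, seed = 9)
  r2 <- sample_counts(mode = "resample", n = 12, seed = 9)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 12)
  expect_error(sample_counts(data.frame(PAUSE = 1), mode = "fixed"),
               "columns")
})

test_that("resampled cohorts keep the empirical LT mean within sampling error", {
  # mean LT count of the source table is 17.7 with SD 6.8; the mean of
  # 20 bootstrapped rows has SE ~1.5, so 200 replicate means straddle it
  means <- vapply(1:200, function(i) {
    s <- sample_counts(mode = "resample", n = 20, seed = i)
    mean(s$PAUSE + s$MR)
  }, numeric(1))
  expect_lt(abs(mean(means) - 17.7), 0.5)
})

test_that("cohort generation is deterministic with derived seeds", {
  cfg <- tiny_synth_config(counts = sample_counts(mode = "fixed")[1:3, ],
                           n_task = 40, n_null = 12)
  c1 <- generate_cohort(3, cfg, master_seed = 7)
  c2 <- generate_cohort(3, cfg, master_seed = 7)
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(c1$manifest$subject_seeds, 7 + 1:3)
  expect_length(c1$subjects, 3)
  expect_equal(sum(vapply(c1$subjects, function(s) length(s$runs),
                          integer(1))), 6)
  expect_error(generate_cohort(1, cfg, 1), ">= 2")
})

test_that("generator rejects invalid ground truth", {
  gt <- tiny_ground_truth()
  gt$baseline <- -1
  cfg <- tiny_synth_config()
  cfg$ground_truth <- gt
  expect_error(generate_subject(cfg, seed = 1), "baseline")
  gt2 <- tiny_ground_truth()
  gt2$roi_specs[[1]]$center <- c(500, 500, 500)   # outside the grid
  cfg2 <- tiny_synth_config()
  cfg2$ground_truth <- gt2
  expect_error(generate_subject(cfg2, seed = 1), "mt_roi")
  expect_error(
    default_ground_truth(radius = 0), "radius")
})

test_that("empirical noise SD and smoothness match the generating model", {
  geom <- tiny_geometry(16)
  cfg <- synth_config(geometry = geom,
                      ground_truth = tiny_ground_truth(noise_sd = 0.02,
                                                       noise_fwhm = 6),
                      counts = data.frame(PAUSE = 0, MR = 0, WWR = 0,
                                          PWR = 0, PRO = 0, BREAK = 0),
                      n_task = 0, n_null = 120)
  ds <- generate_subject(cfg, seed = 21)
  vols <- c(ds$runs[[1]]$volumes, ds$runs[[2]]$volumes)
  V <- vapply(vols, function(v) as.vector(v), numeric(prod(dim(vols[[1]]))))
  sds <- apply(V, 1, sd)
  # voxelwise SD converges to noise_sd * baseline (tolerance 3/sqrt(n))
  n <- length(vols)
  expect_lt(abs(mean(sds) / 2 - 1), 3 / sqrt(n))
  expect_true(all(abs(sds / 2 - 1) < 6 / sqrt(n)))
  # spatial smoothness from lag-1 neighbour correlations:
  # r(d) = exp(-d^2 / (4 sigma^2)) for white noise smoothed by sigma
  d <- dim(vols[[1]])
  cors <- numeric(0)
  for (v in vols[1:40]) {
    cors <- c(cors, cor(as.vector(v[-d[1], , ]), as.vector(v[-1, , ])))
  }
  sigma_hat <- sqrt(-3^2 / (4 * log(mean(cors))))
  fwhm_hat <- 2.3548 * sigma_hat
  expect_lt(abs(fwhm_hat - 6) / 6, 0.2)
})
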