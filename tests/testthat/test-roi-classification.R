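make_roiset <- function(geom, voxel_lists, signs) {
  tab <- data.frame(
    name = paste0(signs, "_", seq_along(voxel_lists)),
    sign = signs,
    n_voxels = vapply(voxel_lists, length, integer(1)),
    volume_mm3 = vapply(voxel_lists, length, integer(1)) * 27,
    peak_t = 5, peak_x = 0, peak_y = 0, peak_z = 0,
    survived = TRUE)
  structure(list(table = tab, voxels = voxel_lists,
                 labels = array(0L, geom$grid_shape), geometry = geom,
                 voxel_p = 0.01, min_cluster_voxels = 1L,
                 convention = c(negative = "LT", positive = "MT")),
            class = "roi_set")
}

test_that("region-mean features are exact on constructed volumes", {
  geom <- tiny_geometry(10)
  rs <- make_roiset(geom, list(1:10 + 100L, 400:420), c("MT", "LT"))
  const <- array(3.5, geom$grid_shape)
  X <- extract_features(list(const, const), rs)
  expect_equal(dim(X), c(2L, 2L))
  expect_true(all(X == 3.5))
  v <- array(0, geom$grid_shape)
  v[1:10 + 100L] <- 1.0
  X2 <- extract_features(list(v), rs)
  expect_equal(unname(X2[1, ]), c(1, 0))
  expect_identical(colnames(X2), rs$table$name)
})

test_that("confusion-matrix identities hold on random counts", {
  set.seed(10)
  for (i in 1:50) {
    cts <- rmultinom(1, sample(10:60, 1), prob = runif(4, 0.05, 1))
    r <- stutterMVPA:::performance_report(cts[1], cts[2], cts[3], cts[4])
    expect_equal(r$TP + r$FN + r$FP + r$TN, r$n)
    if (r$TP + r$FN > 0)
      expect_equal(r$sensitivity, r$TP / (r$TP + r$FN))
    if (r$TN + r$FP > 0)
      expect_equal(r$specificity, r$TN / (r$TN + r$FP))
    expect_equal(r$generalization, (r$TP + r$TN) / r$n)
    # generalization = weighted mix of sensitivity and specificity
    if (r$TP + r$FN > 0 && r$TN + r$FP > 0)
      expect_equal(r$generalization,
                   (r$sensitivity * (r$TP + r$FN) +
                      r$specificity * (r$TN + r$FP)) / r$n)
  }
  r <- stutterMVPA:::performance_report(9, 1, 0, 10)
  expect_equal(r$sensitivity, 0.90)
  expect_equal(r$specificity, 1.00)
  expect_equal(r$generalization, 0.95)
})

test_that("LOOCV is perfect on well-separated features", {
  set.seed(12)
  X <- rbind(matrix(rnorm(20, -3, 0.3), 10, 2),
             matrix(rnorm(20, 3, 0.3), 10, 2))
  labs <- rep(c("LT", "MT"), each = 10)
  rep_ <- loocv(X, labs)
  expect_equal(rep_$generalization, 1.0)
  expect_equal(rep_$TP, 10)
  expect_equal(rep_$TN, 10)
  expect_equal(nrow(rep_$predictions), 20)
  # LT is the positive class of the report
  expect_true(all(rep_$predictions$true[1:10] == "LT"))
})

test_that("LOOCV on shuffled labels hovers at chance", {
  set.seed(13)
  X <- rbind(matrix(rnorm(16, -2, 0.5), 8, 2),
             matrix(rnorm(16, 2, 0.5), 8, 2))
  gens <- vapply(1:60, function(i) {
    labs <- sample(rep(c("LT", "MT"), each = 8))
    loocv(X, labs, C = 10)$generalization
  }, numeric(1))
  expect_lt(abs(mean(gens) - 0.5), 0.06)
})

test_that("LOOCV rejects class-deficient inputs", {
  X <- matrix(rnorm(8), 4, 2)
  expect_error(loocv(X, c("LT", "LT", "LT", "MT")), "2 trials")
})

test_that("final model keeps MT positive and labels stored", {
  set.seed(14)
  X <- rbind(matrix(rnorm(10, -1), 5, 2), matrix(rnorm(10, 1), 5, 2))
  labs <- rep(c("LT", "MT"), each = 5)
  m <- final_model(X, labs)
  expect_identical(m$labels, c("LT", "MT"))
  expect_gt(mean(decision_value(m, X[6:10, ])), 0)
})

test_that("region-weight group tests report direction and arithmetic", {
  m1 <- structure(list(w = c(a = 2, b = 0, c = -1)), class = "linear_svm")
  m2 <- structure(list(w = c(a = 4, b = 0, c = -3)), class = "linear_svm")
  tt <- roi_weight_ttests(list(m1, m2))
  expect_equal(tt$t[tt$roi == "a"], 3.0, tolerance = 1e-12)
  expect_identical(tt$higher_in[tt$roi == "a"], "MT")
  expect_identical(tt$higher_in[tt$roi == "c"], "LT")
  # all-zero weights: no direction, no t
  expect_true(is.na(tt$t[tt$roi == "b"]))
  expect_true(is.na(tt$higher_in[tt$roi == "b"]))
  expect_error(roi_weight_ttests(list(m1)), "at least 2")
})

test_that("group metric t-test against chance", {
  r <- group_metric_ttest(c(0.6, 0.8), chance = 0.5)
  expect_equal(r$t, 2.0, tolerance = 1e-12)
  expect_false(r$degenerate)
  # all subjects at ceiling: degenerate, no t
  r2 <- group_metric_ttest(rep(1, 20), chance = 0.5)
  expect_true(r2$degenerate)
  expect_true(is.na(r2$t))
  expect_match(r2$note, "constant at 1")
  # values symmetric around chance: t = 0
  r3 <- group_metric_ttest(c(0.4, 0.6, 0.3, 0.7), chance = 0.5)
  expect_equal(r3$t, 0, tolerance = 1e-12)
  expect_error(group_metric_ttest(0.7), "at least 2")
})
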