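test_that("single-code trials map to their symptom's type", {
  expect_identical(classify_trial("PWR"), "MT")
  expect_identical(classify_trial("PRO"), "MT")
  expect_identical(classify_trial("BREAK"), "MT")
  expect_identical(classify_trial("PAUSE"), "LT")
  expect_identical(classify_trial("MR"), "LT")
  expect_identical(classify_trial("WWR"), "WWR")
  expect_identical(classify_trial(character(0)), "FLUENT")
})

test_that("mixed-type trials are excluded and fluent markers are inert", {
  expect_identical(classify_trial(c("PAUSE", "PRO")), "EXCLUDED")
  expect_identical(classify_trial(c("MR", "BREAK")), "EXCLUDED")
  expect_identical(classify_trial(c("WWR", "PAUSE")), "EXCLUDED")
  expect_identical(classify_trial(c("WWR", "PWR")), "EXCLUDED")
  expect_identical(classify_trial("PLANNING_PAUSE"), "FLUENT")
  expect_identical(
    classify_trial(c("PLANNING_PAUSE", "PREPAUSAL_PROLONGATION")),
    "FLUENT")
  # fluent-equivalent codes never change a stutter classification
  expect_identical(classify_trial(c("PAUSE", "PLANNING_PAUSE")), "LT")
  expect_identical(classify_trial(c("PWR", "PREPAUSAL_PROLONGATION")),
                   "MT")
  expect_error(classify_trial("SNORT"), "SNORT")
})

test_that("classification is total and deterministic on the code power set", {
  vocab <- symptom_vocabulary()
  n <- length(vocab)
  for (m in 0:(2^n - 1)) {
    codes <- vocab[bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0]
    lab1 <- classify_trial(codes)
    expect_true(lab1 %in% trial_types())
    expect_identical(classify_trial(rev(codes)), lab1)
    # consistency with the membership rules
    core <- setdiff(codes, c("PLANNING_PAUSE", "PREPAUSAL_PROLONGATION"))
    kinds <- (any(core %in% c("PAUSE", "MR"))) +
      (any(core %in% c("PWR", "PRO", "BREAK"))) + ("WWR" %in% core)
    expected <- if (length(core) == 0) "FLUENT"
      else if (kinds > 1) "EXCLUDED"
      else if ("WWR" %in% core) "WWR"
      else if (any(core %in% c("PAUSE", "MR"))) "LT" else "MT"
    expect_identical(lab1, expected)
  }
})

test_that("classify_trials parses comma-separated transcripts", {
  tab <- classify_trials(data.frame(
    trial_id = 1:4,
    symptom_codes = c("", "PAUSE,MR", "WWR", "PAUSE, PRO")))
  expect_identical(tab$type, c("FLUENT", "LT", "WWR", "EXCLUDED"))
})

test_that("count summaries reproduce the reference cohort statistics", {
  s <- summarize_counts(reference_cohort())
  ts <- s$type_stats
  expect_equal(ts$mean[ts$type == "LT"], 17.7, tolerance = 1e-12)
  expect_equal(round(ts$sd[ts$type == "LT"], 2), 6.81)
  expect_equal(round(ts$sd[ts$type == "MT"], 2), 16.38)
  expect_equal(round(ts$sd[ts$type == "WWR"], 2), 1.36)
  # every printed subtype mean/SD cell within rounding
  st <- s$subtype_stats
  printed_mean <- c(PAUSE = 15, MR = 3, WWR = 2, PWR = 13, PRO = 4)
  printed_sd <- c(PAUSE = 5.93, MR = 2.75, WWR = 1.36, PWR = 14.79,
                  PRO = 3.52, BREAK = 0.94)
  for (nm in names(printed_mean))
    expect_equal(round(st$mean[st$subtype == nm]), unname(printed_mean[nm]))
  for (nm in names(printed_sd))
    expect_equal(round(st$sd[st$subtype == nm], 2), unname(printed_sd[nm]))
})

test_that("summaries handle degenerate inputs", {
  z <- data.frame(PAUSE = 0, MR = 0, WWR = 0, PWR = 0, PRO = 0, BREAK = 0)
  s <- summarize_counts(z)
  expect_true(all(s$type_stats$mean == 0))
  expect_true(all(s$type_stats$sd == 0))
})

test_that("signed-rank test matches the base-R route and is symmetric", {
  s <- summarize_counts(reference_cohort())$per_subject
  res <- wilcoxon_signed_rank(s$lt, s$mt)
  ref <- stats::wilcox.test(s$lt, s$mt, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  flipped <- wilcoxon_signed_rank(s$mt, s$lt)
  expect_equal(res$Z, flipped$Z, tolerance = 1e-12)
  expect_equal(res$p, flipped$p, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "degenerate")
})

test_that("exact signed-rank p matches full sign-flip enumeration", {
  x <- c(1, 1, 2); y <- c(2, 3, 5)
  res <- wilcoxon_signed_rank(x, y, exact = TRUE)
  expect_equal(res$W, 0)
  expect_equal(res$p, 0.25)
  set.seed(42)
  for (i in 1:5) {
    a <- sample(1:50, 8); b <- sample(1:50, 8)
    if (all(a == b)) next
    res <- wilcoxon_signed_rank(a, b, exact = TRUE)
    orc <- wilcoxon_exact_oracle(a, b)
    expect_equal(res$W, orc$W)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
  }
})

test_that("ICC agrees with a variance-components oracle", {
  r1 <- c(1, 2, 3, 4, 5, 6)
  r2 <- c(2, 2, 4, 4, 5, 7)
  expect_equal(icc_reliability(r1, r2), icc_a1_oracle(r1, r2),
               tolerance = 1e-12)
  expect_equal(icc_reliability(r1, r1), 1.0, tolerance = 1e-12)
  expect_error(icc_reliability(1:4, 1:5), "length")
  set.seed(7)
  for (i in 1:5) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(icc_reliability(a, b), icc_a1_oracle(a, b),
                 tolerance = 1e-10)
  }
})

test_that("independent random ratings have near-zero expected ICC", {
  set.seed(11)
  vals <- replicate(300, icc_reliability(rnorm(10), rnorm(10)))
  expect_lt(abs(mean(vals)), 0.05)
})
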