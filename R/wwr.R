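#' Assign whole-word-repetition trials with the established model
#'
#' Feeds a subject's WWR trials through their final LT/MT classification
#' model as unclassified cases and reports the fraction assigned to each
#' type.  Fractions depend only on the sign of the decision values, so any
#' strictly monotone rescaling of decisions leaves them unchanged.
#'
#' @param model The subject's final `linear_svm` (labels LT/MT); any
#'   stored training standardization is reused.
#' @param wwr_features Matrix of region-mean PSC features for the WWR
#'   trials (>= 1 row).
#' @return List with `predictions` (data.frame: trial, predicted,
#'   decision), `fraction_LT`, `fraction_MT` (summing to 1) and `n_wwr`.
#'   The caller should flag subjects with fewer than 3 WWR trials, whose
#'   fractions are necessarily coarse.
#' @export
predict_wwr <- function(model, wwr_features) {
  if (is.null(dim(wwr_features)))
    wwr_features <- matrix(wwr_features, nrow = 1)
  if (nrow(wwr_features) == 0L) stop("no WWR trials")
  dec <- decision_value(model, wwr_features)
  pred <- ifelse(dec > 0, model$labels[2], model$labels[1])
  list(predictions = data.frame(trial = seq_along(dec), predicted = pred,
                                decision = dec),
       fraction_LT = mean(pred == "LT"),
       fraction_MT = mean(pred == "MT"),
       n_wwr = length(dec))
}

#' Group test of WWR assignment fractions against chance
#'
#' One-sample two-tailed t-test of per-subject WWR-assigned-to-LT (or MT)
#' fractions against 0.5.  Because fraction_MT = 1 - fraction_LT, the MT
#' test statistic is the negative of the LT one.
#'
#' @param fractions Per-subject assignment fractions (subjects without WWR
#'   trials excluded beforehand).
#' @param chance Chance level (default 0.5).
#' @return As [group_metric_ttest()].
#' @export
fraction_group_test <- function(fractions, chance = 0.5) {
  group_metric_ttest(fractions, chance = chance)
}

#' Region-wise BOLD comparisons across symptom conditions
#'
#' For each subject, averages region PSC per condition (LT, MT, WWR,
#' FLUENT); then, for each requested condition pair, runs a paired
#' two-tailed t-test across subjects per region.  Subjects missing either
#' condition of a pair are dropped pairwise and counted.
#'
#' @param subject_condition_means List (one element per subject) of
#'   matrices `conditions x regions` of mean PSC, as produced by
#'   [condition_roi_means()]; missing conditions are NA rows.
#' @param pairs List of length-2 character vectors of conditions to
#'   compare; defaults to all six pairs among MT, LT, WWR, FLUENT.
#' @return List with `means` (per-condition per-region grand means) and
#'   `tests` (data.frame: pair, roi, mean_diff, t, p, n_subjects).
#' @export
bold_condition_comparison <- function(subject_condition_means,
                                      pairs = NULL) {
  stopifnot(length(subject_condition_means) >= 2L)
  conds <- rownames(subject_condition_means[[1]])
  rois <- colnames(subject_condition_means[[1]])
  if (is.null(pairs))
    pairs <- utils::combn(c("MT", "LT", "WWR", "FLUENT"), 2,
                          simplify = FALSE)
  arr <- simplify2array(subject_condition_means)  # cond x roi x subject
  means <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  tests <- list()
  for (pr in pairs) {
    if (!all(pr %in% conds)) next
    for (r in rois) {
      a <- arr[pr[1], r, ]; b <- arr[pr[2], r, ]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 2L) next
      d <- a[ok] - b[ok]
      if (stats::sd(d) == 0) {
        tval <- if (all(d == 0)) 0 else NA_real_
        pval <- if (all(d == 0)) 1 else NA_real_
      } else {
        tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
        tval <- unname(tt$statistic); pval <- tt$p.value
      }
      tests[[length(tests) + 1L]] <- data.frame(
        pair = paste(pr, collapse = "-"), roi = r,
        mean_diff = mean(d), t = tval, p = pval, n_subjects = sum(ok),
        n_dropped = sum(!ok))
    }
  }
  list(means = means,
       tests = if (length(tests)) do.call(rbind, tests) else
         data.frame(pair = character(), roi = character(),
                    mean_diff = numeric(), t = numeric(), p = numeric(),
                    n_subjects = integer(), n_dropped = integer()))
}

#' Per-subject region means by condition
#'
#' Averages region-mean PSC features over a subject's trials of each
#' condition; conditions with no trials give NA.
#'
#' @param features n_trials x n_rois matrix from [extract_features()].
#' @param labels Trial types aligned with the rows.
#' @param conditions Conditions to summarize.
#' @return `conditions x rois` matrix.
#' @export
condition_roi_means <- function(features, labels,
                                conditions = c("MT", "LT", "WWR",
                                               "FLUENT")) {
  out <- matrix(NA_real_, length(conditions), ncol(features),
                dimnames = list(conditions, colnames(features)))
  for (cond in conditions) {
    rows <- which(labels == cond)
    if (length(rows))
      out[cond, ] <- colMeans(features[rows, , drop = FALSE])
  }
  out
}
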