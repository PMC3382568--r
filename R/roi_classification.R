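#' Region-mean PSC features
#'
#' Feature (i, r) is the mean PSC over region r's voxels for trial i,
#' computed on the run used for classification.
#'
#' @param psc List of PSC volumes (or 4-D array), one per trial.
#' @param roiset A `roi_set`; only surviving regions are used unless
#'   `survivors_only = FALSE`.
#' @param geometry An `acq_geometry` (defaults to the roi_set's).
#' @param survivors_only Use only cluster-corrected survivors.
#' @return n_trials x n_rois numeric matrix with region names as columns.
#' @export
extract_features <- function(psc, roiset, geometry = roiset$geometry,
                             survivors_only = TRUE) {
  rois <- if (survivors_only) surviving_rois(roiset)
          else list(names = roiset$table$name, signs = roiset$table$sign,
                    voxels = roiset$voxels)
  if (length(rois$voxels) == 0L) stop("roi set is empty")
  if (any(vapply(rois$voxels, length, integer(1)) == 0L))
    stop("region with zero in-mask voxels")
  psc <- as_volume_list(psc, geometry)
  X <- t(vapply(psc, function(v)
    vapply(rois$voxels, function(ix) mean(v[ix]), numeric(1)),
    numeric(length(rois$voxels))))
  colnames(X) <- rois$names
  X
}

performance_report <- function(tp, fn, fp, tn, predictions = NULL) {
  n <- tp + fn + fp + tn
  structure(list(
    TP = tp, FN = fn, FP = fp, TN = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    generalization = if (n > 0) (tp + tn) / n else NA_real_,
    n = n, predictions = predictions
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(
    "performance: TP=%d FN=%d FP=%d TN=%d | sens=%.3f spec=%.3f gen=%.3f\n",
    x$TP, x$FN, x$FP, x$TN, x$sensitivity, x$specificity,
    x$generalization))
  invisible(x)
}

#' Leave-one-trial-out cross-validation of the LT/MT classifier
#'
#' For each trial, the SVM is trained on the remaining n - 1 trials and
#' predicts the held-out one.  Counts follow the convention that LT is the
#' positive class of the confusion matrix: TP = LT predicted LT,
#' TN = MT predicted MT, sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), generalization = (TP+TN)/n.  (Internally the
#' SVM keeps MT as +1; the report layer translates.)  A fold whose training
#' set loses one class entirely is skipped with a warning.
#'
#' @param features n x d matrix of region-mean PSC features.
#' @param labels Character vector of `"LT"`/`"MT"` per trial.
#' @param C,tol Passed to [train_linear_svm()].
#' @param standardize Z-score features within each training fold
#'   (default TRUE).
#' @return A `performance_report` with a per-trial `predictions`
#'   data.frame (trial, true, predicted, decision value).
#' @export
loocv <- function(features, labels, C = 100, tol = 1e-6,
                  standardize = TRUE) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels),
            all(labels %in% c("LT", "MT")))
  if (sum(labels == "LT") < 2L || sum(labels == "MT") < 2L)
    stop("need at least 2 trials per class")
  n <- nrow(features)
  pred <- character(n); dec <- numeric(n); used <- logical(n)
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (length(unique(tr_lab)) < 2L) {
      warning("fold ", i, " skipped: training set lost a class")
      next
    }
    m <- train_linear_svm(features[-i, , drop = FALSE], tr_lab, C = C,
                          tol = tol, standardize = standardize,
                          labels = c("LT", "MT"))
    dec[i] <- decision_value(m, features[i, ])
    pred[i] <- predict_label(m, features[i, ])
    used[i] <- TRUE
  }
  tp <- sum(used & labels == "LT" & pred == "LT")
  fn <- sum(used & labels == "LT" & pred == "MT")
  tn <- sum(used & labels == "MT" & pred == "MT")
  fp <- sum(used & labels == "MT" & pred == "LT")
  performance_report(tp, fn, fp, tn, predictions = data.frame(
    trial = which(used), true = labels[used], predicted = pred[used],
    decision = dec[used]))
}

#' Final per-subject classification model
#'
#' Trains the linear SVM on all of a subject's LT/MT trials from the
#' classification run; this is the model later applied to unclassified WWR
#' trials.
#'
#' @inheritParams loocv
#' @return A `linear_svm` with labels `c("LT", "MT")` (MT positive).
#' @export
final_model <- function(features, labels, C = 100, tol = 1e-6,
                        standardize = TRUE) {
  train_linear_svm(as.matrix(features), as.character(labels), C = C,
                   tol = tol, standardize = standardize,
                   labels = c("LT", "MT"))
}

#' Group t-tests on region weights of the final models
#'
#' One-sample two-tailed t-test across subjects on each region's weight in
#' the final classification model.  With MT as the SVM's positive class, a
#' significantly positive mean weight marks a region whose activity is
#' higher in MT ("higher-in MT"), and conversely.
#'
#' @param models List of per-subject `linear_svm` models with identical
#'   feature (region) order.
#' @param roi_names Region names (defaults to names stored on the first
#'   model's weights).
#' @return Data.frame with per-region mean weight, t, p, and `higher_in`.
#' @export
roi_weight_ttests <- function(models, roi_names = NULL) {
  models <- Filter(Negate(is.null), models)
  if (length(models) < 2L) stop("need at least 2 subject models")
  W <- do.call(rbind, lapply(models, function(m) m$w))  # subjects x rois
  if (is.null(roi_names))
    roi_names <- names(models[[1]]$w) %||%
      paste0("roi_", seq_len(ncol(W)))
  out <- lapply(seq_len(ncol(W)), function(r) {
    w <- W[, r]
    if (stats::sd(w) == 0) {
      data.frame(roi = roi_names[r], mean_weight = mean(w), t = NA_real_,
                 p = NA_real_,
                 higher_in = if (mean(w) == 0) NA_character_
                             else if (mean(w) > 0) "MT" else "LT")
    } else {
      tt <- stats::t.test(w, mu = 0)
      data.frame(roi = roi_names[r], mean_weight = mean(w),
                 t = unname(tt$statistic), p = tt$p.value,
                 higher_in = if (mean(w) > 0) "MT" else "LT")
    }
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-sample t-test of a per-subject metric against chance
#'
#' Two-tailed one-sample t-test of per-subject values (e.g. sensitivity or
#' generalization rate) against a chance constant.  When all subjects share
#' one value (zero variance — e.g. specificity 1 everywhere) no t exists
#' and a degenerate flag is returned instead.
#'
#' @param values Per-subject metric values (>= 2 subjects).
#' @param chance Chance level (default 0.5).
#' @return List with `t`, `p`, `mean`, `sd`, `n`, `degenerate` (logical)
#'   and `note`.
#' @export
group_metric_ttest <- function(values, chance = 0.5) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 subjects")
  if (stats::sd(values) == 0) {
    if (values[1] == chance)
      # constant exactly at chance: no deviation in any direction
      return(list(t = 0, p = 1, mean = chance, sd = 0,
                  n = length(values), degenerate = FALSE,
                  note = "constant at chance"))
    return(list(t = NA_real_, p = NA_real_, mean = mean(values),
                sd = 0, n = length(values), degenerate = TRUE,
                note = paste0("degenerate: constant at ", values[1])))
  }
  tt <- stats::t.test(values, mu = chance)
  list(t = unname(tt$statistic), p = tt$p.value, mean = mean(values),
       sd = stats::sd(values), n = length(values), degenerate = FALSE,
       note = NULL)
}
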