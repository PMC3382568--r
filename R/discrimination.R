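#' Whole-brain SVM discrimination map for one subject
#'
#' Trains the linear SVM on the localizer run's trial volumes, with every
#' in-mask voxel's PSC as one feature, and maps each weight back to its
#' voxel.  The absolute weight indexes a voxel's importance for separating
#' the two symptom types.  Label convention: MT is the positive class
#' (+1), LT negative, recorded in the output.  Whole-brain features are
#' used raw (no per-voxel standardization).
#'
#' @param psc List of PSC volumes (or 4-D array) for the run's trials.
#' @param labels Character vector of trial types; only `"LT"`/`"MT"` trials
#'   are used.
#' @param geometry An `acq_geometry`.
#' @param subject_id Identifier carried into the map.
#' @param C,tol Passed to [train_linear_svm()].
#' @return A `discrimination_map`: `weights` (3-D array, zero outside the
#'   mask), `subject_id`, `convention`, and the training `model` without
#'   the weight vector.  Returns `NULL` with a warning when a class has
#'   fewer than 2 trials in the run.
#' @export
subject_discrimination_map <- function(psc, labels, geometry,
                                       subject_id = NA, C = 100,
                                       tol = 1e-6) {
  psc <- as_volume_list(psc, geometry)
  stopifnot(length(labels) == length(psc))
  use <- labels %in% c("LT", "MT")
  labs <- labels[use]
  if (sum(labs == "LT") < 2L || sum(labs == "MT") < 2L) {
    warning("subject ", subject_id,
            " skipped: fewer than 2 trials in a class")
    return(NULL)
  }
  msk <- geometry$mask
  X <- t(vapply(psc[use], function(v) v[msk], numeric(sum(msk))))
  model <- train_linear_svm(X, labs, C = C, tol = tol,
                            labels = c("LT", "MT"))
  weights <- array(0, geometry$grid_shape)
  weights[msk] <- model$w
  model$w <- NULL
  structure(list(subject_id = subject_id, weights = weights,
                 convention = c(negative = "LT", positive = "MT"),
                 model = model, geometry = geometry),
            class = "discrimination_map")
}

#' Group one-sample t-map over subject discrimination maps
#'
#' Voxelwise random-effects one-sample t statistic against zero:
#' `t = mean / (sd / sqrt(n))`, df = n - 1.  Voxels with zero
#' across-subject variance get an undefined-t flag (NA in the map).
#'
#' @param maps List of `discrimination_map` objects on identical geometry.
#' @return A `group_tmap`: `t` (3-D array, NA where undefined or outside
#'   the mask), `df`, `n_subjects`, `undefined` (logical array), and the
#'   shared `geometry` and `convention`.
#' @export
group_tmap <- function(maps) {
  maps <- Filter(Negate(is.null), maps)
  if (length(maps) < 2L) stop("need at least 2 subject maps")
  geom <- maps[[1]]$geometry
  for (m in maps[-1])
    if (!same_geometry(m$geometry, geom)) stop("geometry mismatch")
  msk <- geom$mask
  W <- vapply(maps, function(m) m$weights[msk], numeric(sum(msk)))
  n <- ncol(W)
  mu <- rowMeans(W)
  s <- sqrt(rowSums((W - mu)^2) / (n - 1))
  tval <- rep(NA_real_, length(mu))
  ok <- s > 0
  tval[ok] <- mu[ok] / (s[ok] / sqrt(n))
  tarr <- array(NA_real_, geom$grid_shape)
  tarr[msk] <- tval
  undef <- array(FALSE, geom$grid_shape)
  undef[msk] <- !ok
  structure(list(t = tarr, df = n - 1L, n_subjects = n,
                 undefined = undef, geometry = geom,
                 convention = maps[[1]]$convention),
            class = "group_tmap")
}
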