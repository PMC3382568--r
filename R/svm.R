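#' Train a linear soft-margin support vector machine
#'
#' Minimizes `0.5 ||w||^2 + C sum_i hinge(y_i (w.x_i + b))` by solving the
#' dual with SMO pairwise coordinate updates on the linear-kernel Gram
#' matrix (first-order choice of the ascent index, second-order choice of
#' its partner).  Training stops when the KKT violation
#' (`m(alpha) - M(alpha)`) drops to `tol`; every pairwise update is an exact
#' analytic minimization, so the dual objective never increases.  The
#' working-set choice is deterministic, so identical inputs give identical
#' models and row permutations change nothing beyond `tol`.
#'
#' @param x Numeric feature matrix, one row per trial.
#' @param y Labels: numeric -1/+1, or values of `labels` (negative class
#'   first, positive second).
#' @param C Soft-margin penalty (> 0); default 100.
#' @param tol KKT stopping tolerance (default 1e-6).
#' @param max_iter Iteration cap; hitting it issues a convergence warning
#'   and flags the model, it is never silently accepted.
#' @param standardize Z-score each feature over the training set and store
#'   the transform in the model (default FALSE).
#' @param labels Length-2 character vector `(negative, positive)` naming
#'   the classes.
#' @param trace Record the dual objective at every iteration.
#' @return A `linear_svm`: `w`, `b`, `C`, `labels`, `alpha`, `center`/
#'   `scale` (when standardized), `objective` (primal), `dual_objective`,
#'   `kkt_gap`, `iterations`, `converged`, and `obj_trace` when traced.
#' @export
train_linear_svm <- function(x, y, C = 100, tol = 1e-6, max_iter = 200000L,
                             standardize = FALSE,
                             labels = c("-1", "+1"), trace = FALSE) {
  x <- as.matrix(x)
  if (C <= 0) stop("C must be positive")
  if (any(!is.finite(x))) stop("non-finite feature values")
  if (!is.numeric(y)) {
    y <- as.character(y)
    if (!all(y %in% labels))
      stop("labels in y must be one of: ", paste(labels, collapse = ", "))
    y <- ifelse(y == labels[2], 1, -1)
  }
  if (!all(y %in% c(-1, 1))) stop("numeric y must be -1/+1")
  if (length(unique(y)) < 2L) stop("degenerate labels: one class only")
  n <- nrow(x)
  stopifnot(length(y) == n, n >= 2L)

  center <- NULL; scl <- NULL
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scl, "/")
  }

  K <- x %*% t(x)
  Kdiag <- diag(K)
  alpha <- numeric(n)
  G <- rep(-1, n)                       # G_i = (Q alpha)_i - 1
  obj_trace <- if (trace) numeric(0) else NULL
  iter <- 0L
  converged <- FALSE
  gap <- Inf
  repeat {
    ng <- -y * G                        # -y_i G_i = y_i - w.x_i
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    m_val <- if (any(up)) max(ng[up]) else -Inf
    M_val <- if (any(lo)) min(ng[lo]) else Inf
    gap <- m_val - M_val
    if (gap <= tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    i <- which(up)[which.max(ng[up])]
    # second-order working-set choice for j: maximal objective decrease
    cand <- which(lo & ng < m_val)
    bvec <- m_val - ng[cand]
    hvec <- K[i, i] + Kdiag[cand] - 2 * K[i, cand]
    hvec[hvec <= 1e-12] <- 1e-12
    j <- cand[which.min(-bvec^2 / hvec)]
    g <- y[i] * G[i] - y[j] * G[j]      # = -(m - M) < 0
    h <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_max_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_max <- min(t_max_i, t_max_j)
    step <- if (h > 1e-12) min(-g / h, t_max) else t_max
    alpha[i] <- alpha[i] + y[i] * step
    alpha[j] <- alpha[j] - y[j] * step
    G <- G + y * (K[, i] - K[, j]) * step
    iter <- iter + 1L
    if (trace)
      obj_trace <- c(obj_trace,
                     0.5 * sum((y * alpha) * (K %*% (y * alpha))) -
                       sum(alpha))
  }
  if (!converged)
    warning("SMO did not reach tol = ", tol, " within ", max_iter,
            " iterations (KKT gap ", signif(gap, 3), ")")
  ng <- -y * G
  up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
  lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
  b <- if (any(up) && any(lo)) (max(ng[up]) + min(ng[lo])) / 2
       else mean(ng)
  w <- drop(t(x) %*% (alpha * y))
  margins <- y * (drop(x %*% w) + b)
  primal <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - margins))
  dual <- sum(alpha) - 0.5 * sum((y * alpha) * (K %*% (y * alpha)))
  structure(
    list(w = w, b = b, C = C, labels = labels, alpha = alpha,
         center = center, scale = scl, objective = primal,
         dual_objective = dual, kkt_gap = gap, iterations = iter,
         converged = converged, obj_trace = obj_trace),
    class = "linear_svm"
  )
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("linear_svm:", length(x$w), "features, C =", x$C,
      "| labels:", paste(x$labels, collapse = " vs "),
      "| iterations:", x$iterations, "\n")
  invisible(x)
}

#' Decision values and class predictions
#'
#' `decision_value` returns `w . x + b` (after applying any stored
#' standardization).  `predict_label` maps positive decisions to the
#' positive class; a decision of exactly 0 goes to the negative class (the
#' documented tie rule).
#'
#' @param model A `linear_svm`.
#' @param x Feature vector or matrix (rows = trials).
#' @return Numeric decision values, or class labels.
#' @export
decision_value <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$w))
    stop("feature dimension mismatch: ", ncol(x), " vs ", length(model$w))
  if (!is.null(model$center))
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  drop(x %*% model$w + model$b)
}

#' @rdname decision_value
#' @export
predict_label <- function(model, x) {
  d <- decision_value(model, x)
  ifelse(d > 0, model$labels[2], model$labels[1])
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  predict_label(object, newdata)
}

#' Serialize a linear SVM to JSON
#'
#' Stores weights, bias, penalty, label order and any standardization
#' parameters; [read_svm_json()] restores a functionally identical model.
#'
#' @param model A `linear_svm`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_svm_json <- function(model, path) {
  jsonlite::write_json(
    list(w = model$w, b = model$b, C = model$C, labels = model$labels,
         center = model$center, scale = model$scale),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_svm_json
#' @export
read_svm_json <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(w = as.numeric(m$w), b = m$b, C = m$C,
                 labels = m$labels,
                 center = if (length(m$center)) as.numeric(m$center),
                 scale = if (length(m$scale)) as.numeric(m$scale)),
            class = "linear_svm")
}
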