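# Independent oracles, deliberately implemented by different routes than
# the package code they check.

# Brute-force primal SVM oracle: joint grid search over (w, b) with
# iterative refinement.  Feasible for d <= 2 and a handful of points.
svm_primal_oracle <- function(x, y, C, width = 20, rounds = 18,
                              per_axis = 21) {
  x <- as.matrix(x)
  d <- ncol(x)
  centre <- rep(0, d + 1)
  widths <- rep(width, d + 1)
  objective <- function(P) {
    # P: m x (d+1) rows of candidate (w, b)
    marg <- x %*% t(P[, 1:d, drop = FALSE])          # n x m
    marg <- sweep(marg, 2, P[, d + 1], "+")
    marg <- marg * y
    hinge <- 1 - marg
    hinge[hinge < 0] <- 0
    dim(hinge) <- dim(marg)
    0.5 * rowSums(P[, 1:d, drop = FALSE]^2) + C * colSums(hinge)
  }
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(d + 1), function(k)
      seq(centre[k] - widths[k], centre[k] + widths[k],
          length.out = per_axis))
    P <- as.matrix(expand.grid(grids))
    vals <- objective(P)
    centre <- as.numeric(P[which.min(vals), ])
    widths <- widths * 2 / (per_axis - 1) * 2   # keep 2 cells of slack
  }
  list(w = centre[1:d], b = centre[d + 1],
       objective = min(objective(matrix(centre, 1))))
}

# Exact two-sided sign-flip permutation p for the signed-rank statistic.
wilcoxon_exact_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  stats <- vapply(0:(2^n - 1), function(m)
    sum(r[bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0]), numeric(1))
  list(W = W, p = mean(abs(stats - mu) >= abs(W - mu) - 1e-12))
}

# ICC(A,1) from aov() variance components (two-way layout, long format).
icc_a1_oracle <- function(r1, r2) {
  ratings <- cbind(r1, r2)
  n <- nrow(ratings); k <- 2
  long <- data.frame(score = as.vector(ratings),
                     item = factor(rep(seq_len(n), k)),
                     rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(score ~ item + rater, data = long))[[1]]
  msr <- av["item", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

# Connected components via igraph on an explicit adjacency edge list.
igraph_cluster_oracle <- function(idx, grid_shape,
                                  connectivity = "face") {
  if (length(idx) == 0L) return(integer(0))
  coords <- arrayInd(idx, grid_shape)
  offs <- switch(connectivity,
    "face" = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    stop("oracle supports face connectivity only"))
  key <- function(cc) paste(cc[, 1], cc[, 2], cc[, 3])
  have <- key(coords)
  edges <- NULL
  for (o in seq_len(nrow(offs))) {
    nb <- coords + matrix(offs[o, ], nrow(coords), 3, byrow = TRUE)
    hit <- match(key(nb), have)
    ok <- !is.na(hit)
    if (any(ok))
      edges <- rbind(edges, cbind(which(ok), hit[ok]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges))
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

# Max cluster size of an independent-Bernoulli(p) field (no smoothing),
# using the igraph oracle for clustering.
bernoulli_max_cluster_oracle <- function(grid_shape, p, n_draws, seed) {
  set.seed(seed)
  vapply(seq_len(n_draws), function(i) {
    idx <- which(stats::runif(prod(grid_shape)) < p)
    if (length(idx) == 0L) return(0L)
    as.integer(max(tabulate(igraph_cluster_oracle(idx, grid_shape))))
  }, integer(1))
}
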