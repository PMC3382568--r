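#' Symptom-code vocabulary and trial types
#'
#' The closed vocabulary of per-trial disfluency codes.  `PAUSE` and `MR`
#' are less-typical (LT) symptoms; `PWR`, `PRO` and `BREAK` are more-typical
#' (MT) symptoms; `WWR` (monosyllabic whole-word repetition) is kept apart
#' so its type membership can be decided from brain activity.
#' `PLANNING_PAUSE` and `PREPAUSAL_PROLONGATION` are fluent-equivalent
#' markers: they occur in fluent speech and never make a trial disfluent.
#'
#' @return Character vector of valid codes.
#' @export
symptom_vocabulary <- function() {
  c("PAUSE", "MR", "WWR", "PWR", "PRO", "BREAK",
    "PLANNING_PAUSE", "PREPAUSAL_PROLONGATION")
}

lt_codes <- function() c("PAUSE", "MR")
mt_codes <- function() c("PWR", "PRO", "BREAK")
fluent_codes <- function() c("PLANNING_PAUSE", "PREPAUSAL_PROLONGATION")

#' The five trial types
#' @return Character vector of labels.
#' @export
trial_types <- function() c("FLUENT", "LT", "MT", "WWR", "EXCLUDED")

#' Assign a trial to a type from its symptom codes
#'
#' Fluent-equivalent codes are ignored whenever any stutter code is present.
#' A trial is `LT` if it carries at least one LT code and no MT code and no
#' WWR; `MT` symmetrically; `WWR` if it carries WWR and no LT/MT code;
#' `FLUENT` if (after dropping fluent-equivalent markers) no code remains.
#' Any mixture of types — LT with MT, or WWR with either — is `EXCLUDED`,
#' mirroring the exclusion of mixed-symptom trials from analysis.
#'
#' @param codes Character vector (possibly empty) of symptom codes for one
#'   trial; duplicates are ignored.
#' @return One of [trial_types()].
#' @export
classify_trial <- function(codes) {
  codes <- unique(as.character(codes))
  unknown <- setdiff(codes, symptom_vocabulary())
  if (length(unknown))
    stop("unknown symptom code(s): ", paste(unknown, collapse = ", "))
  codes <- setdiff(codes, fluent_codes())
  if (length(codes) == 0L) return("FLUENT")
  has_lt <- any(codes %in% lt_codes())
  has_mt <- any(codes %in% mt_codes())
  has_wwr <- "WWR" %in% codes
  n_kinds <- has_lt + has_mt + has_wwr
  if (n_kinds > 1L) return("EXCLUDED")
  if (has_wwr) return("WWR")
  if (has_lt) "LT" else "MT"
}

#' Classify a table of trial transcripts
#'
#' @param trials A data.frame with a `symptom_codes` column holding
#'   comma-separated code strings (empty string = no codes).
#' @return The data.frame with a `type` column appended.
#' @export
classify_trials <- function(trials) {
  stopifnot("symptom_codes" %in% names(trials))
  trials$type <- vapply(trials$symptom_codes, function(s) {
    codes <- strsplit(s, ",", fixed = TRUE)[[1]]
    classify_trial(trimws(codes[nzchar(trimws(codes))]))
  }, character(1), USE.NAMES = FALSE)
  trials
}

#' Per-subject and cohort summaries of trial counts
#'
#' Computes per-subject LT (PAUSE + MR), MT (PWR + PRO + BREAK) and WWR
#' trial totals and cohort mean/SD per type and per subtype.  SDs use the
#' n - 1 denominator.  Full precision is returned; any rounding is left to
#' the caller's report layer.
#'
#' @param counts A data.frame of per-subject subtype counts with columns
#'   PAUSE, MR, WWR, PWR, PRO, BREAK (one row per subject), e.g.
#'   [reference_cohort()] or [sample_counts()] output.
#' @return A list with `per_subject` (data.frame with lt, mt, wwr totals),
#'   `type_stats` and `subtype_stats` (data.frames of means and SDs).
#' @export
summarize_counts <- function(counts) {
  cols <- c("PAUSE", "MR", "WWR", "PWR", "PRO", "BREAK")
  stopifnot(all(cols %in% names(counts)), nrow(counts) >= 1L)
  per <- data.frame(
    subject = seq_len(nrow(counts)),
    lt = counts$PAUSE + counts$MR,
    mt = counts$PWR + counts$PRO + counts$BREAK,
    wwr = counts$WWR
  )
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  type_stats <- data.frame(
    type = c("LT", "MT", "WWR"),
    mean = c(mean(per$lt), mean(per$mt), mean(per$wwr)),
    sd = c(sd0(per$lt), sd0(per$mt), sd0(per$wwr))
  )
  subtype_stats <- data.frame(
    subtype = cols,
    mean = vapply(cols, function(cc) mean(counts[[cc]]), numeric(1)),
    sd = vapply(cols, function(cc) sd0(counts[[cc]]), numeric(1))
  )
  rownames(subtype_stats) <- NULL
  list(per_subject = per, type_stats = type_stats,
       subtype_stats = subtype_stats)
}

#' Wilcoxon signed-rank test for paired counts
#'
#' Matched-pairs signed-rank test.  Zero differences are dropped; tied
#' absolute differences receive mean ranks.  The default normal
#' approximation uses the tie-corrected variance
#' n(n+1)(2n+1)/24 - sum(t^3 - t)/48 with no continuity correction and
#' returns |Z| with the two-sided p = 2(1 - pnorm(|Z|)).  With
#' `exact = TRUE` (n <= 14 after dropping zeros) the two-sided p is computed
#' by enumerating all 2^n sign assignments of the ranked differences.
#'
#' @param x,y Paired numeric vectors.
#' @param exact Use the exact sign-flip permutation distribution.
#' @return List with `W` (positive-rank sum), `Z` (|Z|, NA when exact),
#'   `p` (two-sided), and `n` (non-zero pairs).
#' @export
wilcoxon_signed_rank <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 2L) stop("degenerate pairing: fewer than 2 non-zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (exact) {
    if (n > 14L) stop("exact enumeration limited to n <= 14")
    # all 2^n assignments of ranks to the positive side
    stats <- vapply(0:(2^n - 1), function(m) {
      sum(r[bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) != 0])
    }, numeric(1))
    mu <- n * (n + 1) / 4
    p <- mean(abs(stats - mu) >= abs(W - mu) - 1e-12)
    return(list(W = W, Z = NA_real_, p = p, n = n))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) stop("degenerate pairing: zero variance")
  z <- abs(W - mu) / sqrt(sigma2)
  list(W = W, Z = z, p = 2 * (1 - stats::pnorm(z)), n = n)
}

#' Intra-class correlation between two raters
#'
#' Single-measure intra-class correlation for inter-rater reliability of
#' numerically coded trial labels.  The default `"A1"` is the two-way
#' mixed-effects, absolute-agreement, single-measure coefficient
#' (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE)); `"C1"` is the
#' consistency variant (MSR - MSE) / (MSR + (k-1) MSE).
#'
#' @param rater1,rater2 Equal-length numeric vectors (coded labels).
#' @param type `"A1"` (absolute agreement, default) or `"C1"` (consistency).
#' @return The ICC, a scalar in \[-1, 1\].
#' @export
icc_reliability <- function(rater1, rater2, type = c("A1", "C1")) {
  type <- match.arg(type)
  if (length(rater1) != length(rater2))
    stop("rater vectors must have equal length")
  ratings <- cbind(as.numeric(rater1), as.numeric(rater2))
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L) stop("need at least 2 rated items")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- switch(type,
    A1 = msr + (k - 1) * mse + k / n * (msc - mse),
    C1 = msr + (k - 1) * mse)
  if (denom == 0) return(NaN)
  (msr - mse) / denom
}
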