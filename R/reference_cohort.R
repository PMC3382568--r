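#' Reference cohort: per-patient symptom counts and severity scores
#'
#' Per-patient demographic, severity and disfluency-count data for the
#' twenty-patient sentence-completion cohort the package's synthetic
#' generator is calibrated to.  Each symptom column gives the number of task
#' trials on which that subtype occurred (trials are pure, i.e. carry exactly
#' one subtype).  Subtypes: PAUSE = between-character pauses and rhyme
#' prolongations; MR = multi-character repetitions; WWR = monosyllabic
#' whole-word repetitions; PWR = onset-consonant (part-word) repetitions;
#' PRO = onset prolongations; BREAK = within-character breaks.  PAUSE and MR
#' constitute the less-typical (LT) type, PWR/PRO/BREAK the more-typical
#' (MT) type.
#'
#' @return A data.frame with one row per patient and columns `patient`,
#'   `age`, `handedness`, `pct_ss` (percent stuttered syllables), `ssi3`
#'   (Stuttering Severity Instrument III), `oases`, and the six subtype
#'   count columns.
#' @export
reference_cohort <- function() {
  data.frame(
    patient = 1:20,
    age        = c(21, 34, 18, 36, 23, 29, 23, 31, 37, 17,
                   24, 38, 22, 25, 24, 26, 36, 29, 21, 22),
    handedness = c(54, 40, 82, 60, 80, 100, 100, 100, 100, 80,
                   100, 100, 60, 100, 100, 68, 100, 64, 62, 50),
    pct_ss     = c(11, 11, 13, 9, 11, 10, 11, 13, 24, 11,
                   7, 13, 10, 13, 11, 13, 7, 11, 16, 16),
    ssi3       = c(25, 32, 28, 24, 25, 22, 28, 38, 24, 22,
                   32, 27, 28, 32, 25, 29, 18, 29, 32, 43),
    oases      = c(53, 39, 66, 48, 49, 57, 74, 56, 71, 57,
                   51, 63, 50, 52, 48, 46, 39, 37, 67, 67),
    PAUSE      = c(18, 9, 17, 12, 16, 18, 19, 12, 9, 8,
                   12, 10, 18, 10, 15, 12, 32, 23, 15, 7),
    MR         = c(4, 1, 7, 1, 0, 4, 1, 5, 2, 5,
                   2, 3, 1, 0, 3, 7, 5, 0, 10, 1),
    WWR        = c(2, 0, 3, 2, 0, 3, 1, 2, 1, 2,
                   1, 4, 3, 0, 0, 2, 1, 0, 4, 0),
    PWR        = c(9, 13, 6, 8, 5, 4, 13, 7, 8, 8,
                   5, 22, 9, 38, 3, 4, 6, 14, 16, 66),
    PRO        = c(1, 4, 2, 3, 0, 2, 13, 4, 6, 3,
                   6, 10, 3, 1, 2, 1, 5, 4, 0, 10),
    BREAK      = c(1, 0, 0, 0, 0, 0, 1, 4, 1, 0,
                   1, 0, 0, 0, 0, 1, 0, 0, 0, 0)
  )
}

#' Draw per-subject subtype trial counts
#'
#' Either returns the reference cohort's printed count rows verbatim
#' (`mode = "fixed"`) or bootstraps rows with replacement
#' (`mode = "resample"`), for parameterizing synthetic subjects.
#'
#' @param counts_table A data.frame containing the six subtype count columns;
#'   defaults to [reference_cohort()].
#' @param mode `"fixed"` or `"resample"`.
#' @param n Number of subjects to draw when resampling (defaults to
#'   `nrow(counts_table)`; must equal it when `mode = "fixed"`).
#' @param seed RNG seed used when resampling.
#' @return A data.frame with columns PAUSE, MR, WWR, PWR, PRO, BREAK, one
#'   row per subject.
#' @export
sample_counts <- function(counts_table = reference_cohort(),
                          mode = c("fixed", "resample"),
                          n = NULL, seed = 1L) {
  mode <- match.arg(mode)
  cols <- c("PAUSE", "MR", "WWR", "PWR", "PRO", "BREAK")
  if (!all(cols %in% names(counts_table)))
    stop("counts_table must have columns ", paste(cols, collapse = ", "))
  tab <- counts_table[, cols, drop = FALSE]
  if (nrow(tab) == 0L) stop("empty counts table")
  if (mode == "fixed") {
    if (!is.null(n) && n != nrow(tab))
      stop("mode = 'fixed' returns the table verbatim; n must match")
    rows <- seq_len(nrow(tab))
  } else {
    if (is.null(n)) n <- nrow(tab)
    set.seed(seed)
    rows <- sample.int(nrow(tab), n, replace = TRUE)
  }
  out <- tab[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}
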