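#' Planted ground truth for the synthetic cohort
#'
#' Defines the spherical regions carrying condition-dependent signal
#' increments, the noise model and the baseline.  By default the MT-type
#' regions are the left inferior frontal cortex and the precuneus and the
#' LT-type regions are the bilateral putamen, right lateral globus pallidus
#' and bilateral cerebellum, at their standard-space centres; WWR trials are
#' planted with the LT pattern (the hypothesis the analysis is meant to
#' recover), switchable to the MT or null pattern for control simulations.
#'
#' Amplitudes are fractions of baseline, so a planted amplitude `a` has an
#' expected percent-signal-change of `100 a`.  Noise is zero-mean Gaussian,
#' smoothed to `noise_fwhm` mm and scaled so its voxelwise standard
#' deviation is `noise_sd` (fraction of baseline).
#'
#' @param amplitude Fractional signal increment in active regions
#'   (default 0.01, i.e. 1\% PSC).
#' @param noise_sd Voxelwise noise SD as a fraction of baseline
#'   (default 0.01).
#' @param noise_fwhm Spatial smoothness of the noise in mm (default 6).
#' @param baseline Baseline signal level in arbitrary units (default 100).
#' @param radius Region sphere radius in mm (default 6).
#' @param wwr_pattern Which planted pattern WWR trials carry:
#'   `"LT"` (default), `"MT"`, or `"FLUENT"` (no effect).
#' @return A `ground_truth` list with `roi_specs`, `noise_sd`, `noise_fwhm`,
#'   `baseline`.
#' @export
default_ground_truth <- function(amplitude = 0.01, noise_sd = 0.01,
                                 noise_fwhm = 6, baseline = 100,
                                 radius = 6,
                                 wwr_pattern = c("LT", "MT", "FLUENT")) {
  wwr_pattern <- match.arg(wwr_pattern)
  mt_eff <- c(MT = amplitude)
  lt_eff <- c(LT = amplitude)
  if (wwr_pattern == "MT") mt_eff <- c(mt_eff, WWR = amplitude)
  if (wwr_pattern == "LT") lt_eff <- c(lt_eff, WWR = amplitude)
  roi <- function(name, x, y, z, eff, assoc)
    list(name = name, center = c(x, y, z), radius = radius,
         effects = eff, assoc = assoc)
  gt <- list(
    roi_specs = list(
      roi("left_IFC",         -59,  14,  14, mt_eff, "MT"),
      roi("precuneus",         -4, -54,  54, mt_eff, "MT"),
      roi("left_putamen",     -24,  -5,  10, lt_eff, "LT"),
      roi("right_putamen",     30, -16,  15, lt_eff, "LT"),
      roi("right_LGP",         24,  -4,   4, lt_eff, "LT"),
      roi("left_cerebellum",  -40, -48, -36, lt_eff, "LT"),
      roi("right_cerebellum",  30, -58, -46, lt_eff, "LT")
    ),
    noise_sd = noise_sd, noise_fwhm = noise_fwhm, baseline = baseline,
    wwr_pattern = wwr_pattern
  )
  validate_ground_truth(gt)
  gt
}

validate_ground_truth <- function(gt) {
  if (gt$baseline <= 0) stop("baseline must be positive")
  for (r in gt$roi_specs) {
    if (r$radius <= 0) stop("radius must be positive in ROI ", r$name)
    if (any(!is.finite(r$effects)))
      stop("non-finite amplitude in ROI ", r$name)
  }
  # regions of opposite association must not overlap
  specs <- gt$roi_specs
  n <- length(specs)
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (specs[[i]]$assoc != specs[[j]]$assoc) {
      d <- sqrt(sum((specs[[i]]$center - specs[[j]]$center)^2))
      if (d <= specs[[i]]$radius + specs[[j]]$radius)
        stop("ROIs of opposite association overlap: ",
             specs[[i]]$name, " and ", specs[[j]]$name)
    }
  }
  invisible(gt)
}

#' Synthetic-cohort configuration
#'
#' Bundles geometry, ground truth and per-subject trial counts.  Each run
#' holds `n_task / 2` task trials plus `n_null / 2` null trials (a third of
#' acquisitions are null), one volume acquired per trial.  Per-subtype
#' counts are split across the two runs by an even random partition; the
#' remaining task trials are fluent.
#'
#' @param geometry An `acq_geometry` (default [default_geometry()]).
#' @param ground_truth A ground-truth list (default
#'   [default_ground_truth()]).
#' @param counts Data.frame of per-subject subtype counts (default
#'   [reference_cohort()] rows, used verbatim).
#' @param n_task,n_null Total task and null trials per subject across the
#'   two runs (defaults 90 and 30).
#' @param smooth_fwhm Analysis smoothing FWHM in mm used downstream
#'   (default 6).
#' @return A `synth_config` list.
#' @export
synth_config <- function(geometry = default_geometry(),
                         ground_truth = default_ground_truth(),
                         counts = sample_counts(mode = "fixed"),
                         n_task = 90L, n_null = 30L, smooth_fwhm = 6) {
  validate_ground_truth(ground_truth)
  cfg <- list(geometry = geometry, ground_truth = ground_truth,
              counts = counts, n_task = as.integer(n_task),
              n_null = as.integer(n_null), smooth_fwhm = smooth_fwhm)
  class(cfg) <- "synth_config"
  cfg
}

# In-mask voxel indices of each planted region sphere; errors when a region
# has no in-mask voxel.
planted_roi_voxels <- function(config) {
  geom <- config$geometry
  coords <- voxel_to_world(geom, arrayInd(seq_len(prod(geom$grid_shape)),
                                          geom$grid_shape))
  lapply(config$ground_truth$roi_specs, function(r) {
    d2 <- (coords[, 1] - r$center[1])^2 + (coords[, 2] - r$center[2])^2 +
      (coords[, 3] - r$center[3])^2
    idx <- which(d2 <= r$radius^2 & as.vector(geom$mask))
    if (length(idx) == 0L)
      stop("ROI falls outside the mask: ", r$name)
    list(name = r$name, assoc = r$assoc, effects = r$effects, voxels = idx)
  })
}

# Per-condition fractional-amplitude volumes (vectors over the full grid).
condition_amplitude_maps <- function(config) {
  rois <- planted_roi_voxels(config)
  conds <- c("MT", "LT", "WWR", "FLUENT")
  maps <- lapply(conds, function(cond) {
    amp <- numeric(prod(config$geometry$grid_shape))
    for (r in rois)
      if (cond %in% names(r$effects))
        amp[r$voxels] <- amp[r$voxels] + unname(r$effects[[cond]])
    amp
  })
  names(maps) <- conds
  maps
}

# Exact per-voxel variance factor of separable kernel smoothing, so smoothed
# white noise can be rescaled to unit marginal SD everywhere.
noise_sd_map <- function(kernels, grid_shape) {
  rs <- lapply(kernels, function(K) rowSums(K^2))
  sqrt(outer(outer(rs[[1]], rs[[2]]), rs[[3]]))
}

# One smoothed unit-SD noise volume.
draw_noise <- function(kernels, grid_shape, sdmap) {
  raw <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  if (is.null(kernels)) return(raw)
  apply_kernels(raw, kernels) / sdmap
}

split_evenly <- function(count) {
  # even random partition of `count` across two runs
  half <- count %/% 2L
  extra <- if (count %% 2L == 1L) stats::rbinom(1L, 1L, 0.5) else 0L
  c(half + extra, count - half - extra)
}

#' Generate one synthetic subject
#'
#' Simulates two sparse-sampling runs for one subject: per-run trial
#' sequences (task trials randomly interleaved with null trials), one
#' acquired volume per trial.  A task trial's noise-free expectation equals
#' `baseline * (1 + amplitude)` inside every region active for its
#' condition and `baseline` elsewhere; null and fluent trials have baseline
#' expectation everywhere.  Noise is zero-mean Gaussian smoothed to
#' `noise_fwhm` and rescaled to exact voxelwise SD `noise_sd * baseline`.
#'
#' @param config A [synth_config()].
#' @param seed Integer RNG seed (required; same config + seed gives a
#'   bit-identical dataset).
#' @param subject_id Subject identifier (also selects the row of
#'   `config$counts` when it has several rows).
#' @return A `subject_dataset`: list with `subject_id`, `geometry`, `runs`
#'   (two lists of `trials` data.frame + `volumes` list) and `seed`.
#' @export
generate_subject <- function(config, seed, subject_id = 1L) {
  stopifnot(inherits(config, "synth_config"), !missing(seed))
  gt <- config$ground_truth
  if (gt$baseline <= 0) stop("baseline must be positive")
  counts_row <- config$counts[
    if (nrow(config$counts) >= subject_id) subject_id else 1L, ]
  subtypes <- c("PAUSE", "MR", "WWR", "PWR", "PRO", "BREAK")
  ns <- vapply(subtypes, function(s) as.integer(counts_row[[s]]),
               integer(1))
  if (any(ns < 0)) stop("subtype counts must be >= 0")
  n_stutter <- sum(ns)
  n_fluent <- config$n_task - n_stutter
  if (n_fluent < 0)
    stop("subtype counts exceed the number of task trials")

  set.seed(as.integer(seed))
  amps <- condition_amplitude_maps(config)
  kernels <- if (gt$noise_fwhm > 0)
    smoothing_kernels(config$geometry, gt$noise_fwhm) else NULL
  sdmap <- if (!is.null(kernels))
    noise_sd_map(kernels, config$geometry$grid_shape) else NULL

  # even random split of every subtype, the fluent pool and nulls over runs
  run_of <- list()
  for (s in subtypes) run_of[[s]] <- split_evenly(ns[[s]])
  run_of[["FLUENT_TASK"]] <- split_evenly(n_fluent)
  run_of[["NULL"]] <- split_evenly(config$n_null)

  grid <- config$geometry$grid_shape
  trial_id <- 0L
  runs <- lapply(1:2, function(run) {
    kinds <- c(rep(subtypes, times = vapply(subtypes,
                 function(s) run_of[[s]][run], integer(1))),
               rep("FLUENT_TASK", run_of[["FLUENT_TASK"]][run]),
               rep("NULL", run_of[["NULL"]][run]))
    kinds <- sample(kinds)
    type <- vapply(kinds, function(k) {
      switch(k, "NULL" = "NULL", FLUENT_TASK = "FLUENT",
             classify_trial(k))
    }, character(1), USE.NAMES = FALSE)
    trials <- data.frame(
      trial_id = trial_id + seq_along(kinds),
      run = run,
      onset_index = seq_along(kinds),
      symptom_codes = ifelse(kinds %in% subtypes, kinds, ""),
      type = type,
      is_null = kinds == "NULL"
    )
    trial_id <<- trial_id + nrow(trials)
    volumes <- lapply(seq_len(nrow(trials)), function(i) {
      cond <- if (trials$type[i] %in% c("LT", "MT", "WWR"))
        trials$type[i] else "FLUENT"
      amp <- if (trials$is_null[i]) 0 else amps[[cond]]
      noise <- if (is.null(kernels))
        array(stats::rnorm(prod(grid)), grid)
      else draw_noise(kernels, grid, sdmap)
      array(gt$baseline * (1 + amp), grid) +
        gt$noise_sd * gt$baseline * noise
    })
    list(trials = trials, volumes = volumes)
  })
  structure(list(subject_id = subject_id, geometry = config$geometry,
                 runs = runs, seed = as.integer(seed)),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  n <- vapply(x$runs, function(r) nrow(r$trials), integer(1))
  cat("subject_dataset", x$subject_id, "- trials per run:",
      paste(n, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Per-subject seeds are derived deterministically as
#' `master_seed + subject index`.  The returned manifest records every
#' planted parameter.
#'
#' @param n_subjects Number of subjects (>= 2; default 20).
#' @param config A [synth_config()]; its `counts` rows are recycled by
#'   subject index.
#' @param master_seed Integer master seed.
#' @return List with `subjects` (list of `subject_dataset`) and `manifest`.
#' @export
generate_cohort <- function(n_subjects = 20L, config = synth_config(),
                            master_seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  seeds <- as.integer(master_seed) + seq_len(n_subjects)
  subjects <- lapply(seq_len(n_subjects), function(i)
    generate_subject(config, seed = seeds[i], subject_id = i))
  manifest <- list(
    n_subjects = n_subjects, master_seed = as.integer(master_seed),
    subject_seeds = seeds,
    grid_shape = config$geometry$grid_shape,
    voxel_size = config$geometry$voxel_size,
    affine = config$geometry$affine,
    ground_truth = config$ground_truth,
    counts = config$counts, n_task = config$n_task, n_null = config$n_null,
    smooth_fwhm = config$smooth_fwhm
  )
  list(subjects = subjects, manifest = manifest)
}
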