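#' Default end-to-end pipeline configuration
#'
#' All tunable parameters of the synthetic cohort and the analysis, as a
#' plain list that can be round-tripped through YAML.  Defaults follow the
#' study conditions: 20 subjects with the reference-cohort trial counts,
#' 1\% planted amplitude, 1\% noise smoothed to 6 mm, SVM C = 100, voxel
#' p = 0.01 two-tailed with Monte-Carlo cluster correction at familywise
#' alpha 0.05.  The analysis smoothing default is 0 mm because the
#' generator already delivers volumes at the 6-mm smoothness that scanner
#' preprocessing would produce (planted amplitudes then reach the
#' classifier with their nominal PSC); set `preprocess$fwhm` to 6 when
#' consuming raw, spatially unsmoothed volumes.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    n_subjects = 20L,
    geometry = list(grid_shape = c(38L, 40L, 42L),
                    voxel_size = c(3, 3, 3), origin = c(-69, -75, -57)),
    synth = list(amplitude = 0.01, noise_sd = 0.01, noise_fwhm = 6,
                 baseline = 100, radius = 6, wwr_pattern = "LT",
                 counts_mode = "fixed", n_task = 90L, n_null = 30L,
                 rois = NULL),
    preprocess = list(fwhm = 0, baseline = "null_mean",
                      smooth_first = TRUE),
    svm = list(C = 100, tol = 1e-6, standardize_roi = TRUE),
    cluster = list(voxel_p = 0.01, corrected_alpha = 0.05,
                   n_iter = 1000L, connectivity = "face"),
    wwr = list(runs = "run2")
  )
}

#' Read and validate a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_config()]; unknown top-level
#' sections are rejected.  Validation happens before any computation.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return Validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config section(s): ", paste(bad, collapse = ", "))
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        badf <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
        if (length(badf))
          stop("unknown config field(s) in ", nm, ": ",
               paste(badf, collapse = ", "))
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param cfg Configuration list.
#' @return `cfg`, invisibly; errors on invalid settings.
#' @export
validate_config <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g$grid_shape) || length(g$grid_shape) != 3L ||
      any(g$grid_shape < 8))
    stop("geometry$grid_shape must be 3 values >= 8")
  if (any(g$voxel_size <= 0)) stop("voxel sizes must be positive")
  if (cfg$synth$baseline <= 0) stop("baseline must be positive")
  if (cfg$synth$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$svm$C <= 0) stop("svm C must be positive")
  with(cfg$cluster, {
    if (voxel_p <= 0 || voxel_p >= 1) stop("voxel_p must be in (0,1)")
    if (corrected_alpha <= 0 || corrected_alpha >= 1)
      stop("corrected_alpha must be in (0,1)")
    if (n_iter < 100) stop("cluster n_iter must be >= 100")
  })
  if (!cfg$synth$wwr_pattern %in% c("LT", "MT", "FLUENT"))
    stop("wwr_pattern must be LT, MT or FLUENT")
  if (cfg$n_subjects < 2) stop("n_subjects must be >= 2")
  invisible(cfg)
}

#' Build the synthetic-data configuration from a pipeline config
#' @param cfg Pipeline configuration list.
#' @param seed Seed used only when `counts_mode = "resample"`.
#' @return A [synth_config()].
#' @export
build_synth_config <- function(cfg, seed = 1L) {
  geom <- acq_geometry(cfg$geometry$grid_shape, cfg$geometry$voxel_size,
                       origin = cfg$geometry$origin)
  gt <- default_ground_truth(
    amplitude = cfg$synth$amplitude, noise_sd = cfg$synth$noise_sd,
    noise_fwhm = cfg$synth$noise_fwhm, baseline = cfg$synth$baseline,
    radius = cfg$synth$radius, wwr_pattern = cfg$synth$wwr_pattern)
  if (!is.null(cfg$synth$rois)) {
    # custom planted regions: (name, center, assoc), e.g. for small grids
    amp <- cfg$synth$amplitude
    mt_eff <- c(MT = amp); lt_eff <- c(LT = amp)
    if (cfg$synth$wwr_pattern == "MT") mt_eff <- c(mt_eff, WWR = amp)
    if (cfg$synth$wwr_pattern == "LT") lt_eff <- c(lt_eff, WWR = amp)
    gt$roi_specs <- lapply(cfg$synth$rois, function(r)
      list(name = r$name, center = as.numeric(r$center),
           radius = cfg$synth$radius,
           effects = if (r$assoc == "MT") mt_eff else lt_eff,
           assoc = r$assoc))
    validate_ground_truth(gt)
  }
  counts <- if (cfg$synth$counts_mode == "fixed")
    sample_counts(mode = "fixed")
  else sample_counts(mode = "resample", n = cfg$n_subjects, seed = seed)
  synth_config(geometry = geom, ground_truth = gt, counts = counts,
               n_task = cfg$synth$n_task, n_null = cfg$synth$n_null,
               smooth_fwhm = cfg$preprocess$fwhm)
}

subject_masked_psc <- function(dataset, run, cfg) {
  geom <- dataset$geometry
  rn <- dataset$runs[[run]]
  pp <- preprocess_run(rn$volumes, rn$trials$is_null, geom,
                       fwhm = cfg$preprocess$fwhm,
                       baseline = cfg$preprocess$baseline,
                       smooth_first = cfg$preprocess$smooth_first)
  task <- !rn$trials$is_null
  msk <- geom$mask
  list(psc = t(vapply(pp$psc[task], function(v) v[msk],
                      numeric(sum(msk)))),
       labels = rn$trials$type[task],
       trial_id = rn$trials$trial_id[task])
}

map_from_masked <- function(psc_matrix, labels, geometry, subject_id,
                            svm_cfg) {
  use <- labels %in% c("LT", "MT")
  labs <- labels[use]
  if (sum(labs == "LT") < 2L || sum(labs == "MT") < 2L) {
    warning("subject ", subject_id,
            " skipped: fewer than 2 trials in a class")
    return(NULL)
  }
  model <- train_linear_svm(psc_matrix[use, , drop = FALSE], labs,
                            C = svm_cfg$C, tol = svm_cfg$tol,
                            labels = c("LT", "MT"))
  weights <- array(0, geometry$grid_shape)
  weights[geometry$mask] <- model$w
  model$w <- NULL
  structure(list(subject_id = subject_id, weights = weights,
                 convention = c(negative = "LT", positive = "MT"),
                 model = model, geometry = geometry),
            class = "discrimination_map")
}

roi_features_from_masked <- function(psc_matrix, roiset, geometry) {
  rois <- surviving_rois(roiset)
  mask_idx <- which(geometry$mask)
  cols <- lapply(rois$voxels, function(vx) match(vx, mask_idx))
  X <- vapply(cols, function(cc)
    rowMeans(psc_matrix[, cc, drop = FALSE]), numeric(nrow(psc_matrix)))
  X <- matrix(X, nrow = nrow(psc_matrix))
  colnames(X) <- rois$names
  X
}

#' Jaccard overlap between planted regions and recovered clusters
#'
#' For every planted region, finds the surviving cluster with the largest
#' voxel-set Jaccard overlap and reports that overlap, the cluster's sign
#' and whether the sign matches the planted association.
#'
#' @param roiset A `roi_set`.
#' @param synth_cfg The [synth_config()] that generated the cohort.
#' @return Data.frame: planted name, association, n_voxels, best Jaccard,
#'   matched cluster and sign, sign_correct.
#' @export
planted_recovery <- function(roiset, synth_cfg) {
  planted <- planted_roi_voxels(synth_cfg)
  surv <- surviving_rois(roiset)
  out <- lapply(planted, function(p) {
    jac <- vapply(surv$voxels, function(vx)
      length(intersect(p$voxels, vx)) / length(union(p$voxels, vx)),
      numeric(1))
    if (length(jac) == 0L || max(jac) == 0) {
      data.frame(planted = p$name, assoc = p$assoc,
                 n_voxels = length(p$voxels), jaccard = 0,
                 matched_cluster = NA_character_,
                 cluster_sign = NA_character_, sign_correct = FALSE)
    } else {
      k <- which.max(jac)
      data.frame(planted = p$name, assoc = p$assoc,
                 n_voxels = length(p$voxels), jaccard = jac[k],
                 matched_cluster = surv$names[k],
                 cluster_sign = surv$signs[k],
                 sign_correct = surv$signs[k] == p$assoc)
    }
  })
  do.call(rbind, out)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, label, preprocess, whole-brain discrimination
#' mapping (run 1), group t-map, Monte-Carlo cluster-corrected region
#' selection, region-feature leave-one-trial-out classification (run 2),
#' WWR assignment, and condition-wise BOLD comparisons.  Deterministic
#' given `config` + `seed`.
#'
#' @param config Configuration list (see [default_config()]).
#' @param seed Master seed for every source of randomness.
#' @param out Optional output directory for artifacts (JSON/TSV reports,
#'   t-map and region volumes, manifest); NULL keeps everything in memory.
#' @param verbose Print stage progress to stderr.
#' @return A `pipeline_report` list: `roiset` table, planted-region
#'   `recovery`, `per_subject` metrics, `group_tests`, `roi_weights`,
#'   `bold_comparison`, `mc_threshold`, and the cohort `manifest`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out = NULL, verbose = FALSE) {
  validate_config(config)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  synth_cfg <- build_synth_config(config, seed = seed)
  geom <- synth_cfg$geometry
  n <- config$n_subjects

  say("simulate + preprocess + map (", n, " subjects)")
  seeds <- as.integer(seed) + seq_len(n)
  maps <- vector("list", n)
  run2 <- vector("list", n)
  counts_used <- vector("list", n)
  for (i in seq_len(n)) {
    ds <- generate_subject(synth_cfg, seed = seeds[i], subject_id = i)
    counts_used[[i]] <- table(factor(
      unlist(lapply(ds$runs, function(r) r$trials$type)),
      levels = c("FLUENT", "LT", "MT", "WWR", "NULL")))
    r1 <- subject_masked_psc(ds, 1L, config)
    maps[[i]] <- map_from_masked(r1$psc, r1$labels, geom, i, config$svm)
    run2[[i]] <- subject_masked_psc(ds, 2L, config)
    rm(ds, r1)
  }

  say("group t-map")
  tmap <- group_tmap(maps)

  say("Monte-Carlo cluster threshold")
  null_fwhm <- sqrt(synth_cfg$ground_truth$noise_fwhm^2 +
                      config$preprocess$fwhm^2)
  mc <- monte_carlo_cluster_threshold(
    geom, voxel_p = config$cluster$voxel_p,
    corrected_alpha = config$cluster$corrected_alpha,
    n_iter = config$cluster$n_iter, noise_fwhm = null_fwhm,
    connectivity = config$cluster$connectivity,
    seed = as.integer(seed) + 7919L)

  say("threshold and cluster")
  roiset <- threshold_and_cluster(tmap, voxel_p = config$cluster$voxel_p,
                                  min_cluster_voxels = mc$min_voxels,
                                  connectivity =
                                    config$cluster$connectivity)
  recovery <- planted_recovery(roiset, synth_cfg)
  if (sum(roiset$table$survived) == 0L) {
    warning("no surviving clusters; downstream stages skipped")
    report <- structure(list(roiset = roiset, recovery = recovery,
                             mc_threshold = mc$min_voxels,
                             per_subject = NULL, group_tests = NULL,
                             manifest = list(seed = as.integer(seed),
                                             config = config)),
                        class = "pipeline_report")
    if (!is.null(out)) write_pipeline_report(report, tmap, out)
    return(report)
  }

  say("roi classification (run 2) + wwr assignment")
  per <- vector("list", n)
  models <- vector("list", n)
  cond_means <- vector("list", n)
  for (i in seq_len(n)) {
    feats <- roi_features_from_masked(run2[[i]]$psc, roiset, geom)
    labs <- run2[[i]]$labels
    lt_mt <- labs %in% c("LT", "MT")
    cond_means[[i]] <- condition_roi_means(feats, labs)
    ok <- sum(labs == "LT") >= 2L && sum(labs == "MT") >= 2L
    rep_i <- if (ok)
      loocv(feats[lt_mt, , drop = FALSE], labs[lt_mt],
            C = config$svm$C, tol = config$svm$tol,
            standardize = config$svm$standardize_roi)
    else NULL
    models[[i]] <- if (ok)
      final_model(feats[lt_mt, , drop = FALSE], labs[lt_mt],
                  C = config$svm$C, tol = config$svm$tol,
                  standardize = config$svm$standardize_roi)
    else NULL
    wwr_rows <- which(labs == "WWR")
    wwr_res <- if (ok && length(wwr_rows) > 0L)
      predict_wwr(models[[i]], feats[wwr_rows, , drop = FALSE])
    else NULL
    per[[i]] <- data.frame(
      subject = i,
      n_lt = sum(labs == "LT"), n_mt = sum(labs == "MT"),
      n_wwr = length(wwr_rows),
      sensitivity = if (!is.null(rep_i)) rep_i$sensitivity else NA,
      specificity = if (!is.null(rep_i)) rep_i$specificity else NA,
      generalization = if (!is.null(rep_i)) rep_i$generalization else NA,
      fraction_LT = if (!is.null(wwr_res)) wwr_res$fraction_LT else NA,
      few_wwr = length(wwr_rows) < 3L
    )
  }
  per <- do.call(rbind, per)

  say("group statistics")
  group_tests <- list(
    sensitivity = group_metric_ttest(per$sensitivity, 0.5),
    specificity = group_metric_ttest(per$specificity, 0.5),
    generalization = group_metric_ttest(per$generalization, 0.5),
    wwr_fraction_lt = if (any(!is.na(per$fraction_LT)))
      fraction_group_test(per$fraction_LT[!is.na(per$fraction_LT)])
    else NULL
  )
  roi_weights <- roi_weight_ttests(models)
  bold <- bold_condition_comparison(cond_means)

  report <- structure(list(
    roiset = roiset, recovery = recovery, mc_threshold = mc$min_voxels,
    per_subject = per, group_tests = group_tests,
    roi_weights = roi_weights, bold_comparison = bold,
    trial_type_counts = counts_used,
    manifest = list(seed = as.integer(seed), subject_seeds = seeds,
                    config = config,
                    package_version =
                      as.character(utils::packageVersion("stutterMVPA")))
  ), class = "pipeline_report")

  if (!is.null(out)) write_pipeline_report(report, tmap, out)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", sum(x$roiset$table$survived),
      "surviving clusters; minimum cluster size", x$mc_threshold,
      "voxels\n")
  if (!is.null(x$per_subject)) {
    cat(sprintf("mean sensitivity %.3f, specificity %.3f, ",
                mean(x$per_subject$sensitivity, na.rm = TRUE),
                mean(x$per_subject$specificity, na.rm = TRUE)))
    cat(sprintf("generalization %.3f; mean WWR->LT fraction %.3f\n",
                mean(x$per_subject$generalization, na.rm = TRUE),
                mean(x$per_subject$fraction_LT, na.rm = TRUE)))
  }
  invisible(x)
}

write_pipeline_report <- function(report, tmap, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_volume(tmap$t, tmap$geometry, file.path(out, "group_tmap.nii.gz"))
  write_roi_set(report$roiset, out)
  if (!is.null(report$per_subject))
    utils::write.table(report$per_subject,
                       file.path(out, "per_subject.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(recovery = report$recovery, group_tests = report$group_tests,
         roi_weights = report$roi_weights,
         bold_tests = report$bold_comparison$tests,
         mc_threshold_voxels = report$mc_threshold,
         manifest = report$manifest),
    file.path(out, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null", force = TRUE)
  invisible(out)
}
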