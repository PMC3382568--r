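---
title: "Classifying stuttering symptom types from trial-wise brain activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying stuttering symptom types from trial-wise brain activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Disfluencies in stuttered speech are conventionally grouped into
*more-typical* (MT) symptoms — part-word repetitions (PWR), prolongations
of onset sounds (PRO) and within-word breaks (BREAK), all of which disrupt
the inside of a syllable — and *less-typical* (LT) symptoms — pauses and
rhyme prolongations (PAUSE) and multi-word repetitions (MR), which also
occur in fluent speakers.  Monosyllabic whole-word repetitions (WWR) have
a disputed membership.  stutterMVPA implements a trial-wise multivoxel
pattern analysis that (i) tests whether MT and LT trials can be separated
from single-trial fMRI volumes and (ii) assigns WWR trials to one of the
two types with the model so established.

Because no imaging data from the motivating study are deposited, the
package ships a seeded synthetic-cohort generator with planted,
ground-truth effects.  Every pipeline stage can therefore be verified
end to end: the planted regions are known voxel sets, the planted
condition amplitudes are known PSC values, and the WWR pattern is planted
deliberately (LT by default) so the final assignment step has a right
answer.

## Pipeline

1. **Simulate** (`generate_cohort`): two sparse-sampling runs per subject,
   one volume acquired per trial, a third of acquisitions null.
2. **Label** (`classify_trial`): symptom codes to
   FLUENT / LT / MT / WWR / EXCLUDED.
3. **Preprocess** (`preprocess_run`): optional Gaussian smoothing, then
   voxelwise percent signal change (PSC) against the run's null-trial
   mean.
4. **Map** (`subject_discrimination_map`): per subject, a linear
   soft-margin SVM on run-1 LT/MT trials with every in-mask voxel as a
   feature; the weight vector, mapped back to voxels, is the subject's
   discrimination map.
5. **Select regions** (`group_tmap`, `monte_carlo_cluster_threshold`,
   `threshold_and_cluster`): voxelwise one-sample t over subjects' maps,
   thresholded at a two-tailed per-voxel p with a Monte-Carlo
   cluster-size correction.
6. **Classify** (`extract_features`, `loocv`, `final_model`): region-mean
   PSC features from run 2, leave-one-trial-out validation, and the final
   per-subject model.
7. **Assign WWR** (`predict_wwr`): run-2 WWR trials fed to the final
   model as unclassified cases.
8. **Condition comparisons** (`bold_condition_comparison`): per-region
   mean PSC by condition with paired t-tests across subjects.

`run_pipeline()` orchestrates all stages deterministically from one
config and one seed; `inst/cli/stutter_mvpa.R` is a thin shell entry for
`simulate` and `run-all`, and each intermediate stage is equally runnable
from its exported function on the previous stage's on-disk artifacts
(`write_subject_dataset`/`read_subject_dataset`, `write_volume`,
`write_roi_set`).

## Labelling rules

A trial is LT if it carries an LT code and neither an MT code nor WWR;
MT symmetrically; WWR only in isolation.  Planning pauses and pre-pausal
prolongations are fluent-equivalent markers: they are ignored whenever
any stutter code is present, and a trial carrying only them (or nothing)
is FLUENT.  Mixtures across types — LT with MT, or WWR with either — are
EXCLUDED from analysis.  The mixed-WWR case is not specified by the
grouping scheme we implement; exclusion is the conservative choice and is
the only assignment consistent with requiring pure trials for both
training classes.

Rater reliability is summarized by a single-measure intra-class
correlation.  The variant is configurable; the default is the two-way
mixed-effects absolute-agreement coefficient ICC(A,1), the common choice
when the same two fixed raters score every trial.

The paired LT-vs-MT count comparison uses the Wilcoxon signed-rank test
with the tie-corrected normal approximation and no continuity
correction; with the bundled reference counts this yields |Z| = 1.047,
p = 0.295.  (With a continuity correction or without tie correction the
third decimal changes, so the variant matters and is fixed and tested.)
An exact sign-flip enumeration is available for small samples.

## The synthetic cohort

**What it emulates.** Twenty subjects whose per-subtype trial counts are
the bundled reference cohort's printed rows (`sample_counts(mode =
"fixed")`; a bootstrap mode exists for power exploration).  90 task
trials plus 30 nulls per subject are split over two runs by an even
random partition per subtype — the motivating design counterbalanced two
runs but did not publish per-run splits, so an even random split is the
neutral choice.  Each trial contributes exactly one volume (the sparse
design acquires after the spoken response, so per-trial volumes are the
natural sample unit).  Condition effects are fractional signal increments
`baseline * (1 + amplitude)` inside 6-mm spheres at the standard-space
coordinates of the regions the analysis is expected to find: left
inferior frontal cortex and precuneus for MT; bilateral putamen, right
lateral globus pallidus and bilateral cerebellum for LT.  WWR trials
carry the LT amplitude pattern by default — this is the planted
hypothesis the assignment stage must recover — switchable to MT or to no
effect for symmetry controls.  Noise is zero-mean Gaussian, smoothed to
`noise_fwhm` (default 6 mm) and rescaled to an exact voxelwise SD of
`noise_sd * baseline` (default 1% of baseline, matching the 1% planted
amplitude so the per-voxel single-trial SNR is 1).

**What it does not emulate.** Hemodynamic convolution and delay, motion
and physiological artifacts, scanner drift, anatomical variability,
inter-subject misregistration, and non-Gaussian noise.  Passing the
recovery tests therefore shows the *analysis chain* is correct and
well-calibrated under its own assumptions — not that real scans of this
size would yield the same accuracy.

**Geometry.** The default grid is 38 x 40 x 42 voxels at 3-mm isotropic
resolution with the voxel-(1,1,1) centre at (-69, -75, -57) mm: the
smallest comfortable box whose field of view contains every default
region sphere (the needed world extent is about x in [-65, 36], z in
[-52, 60] mm).  The default mask is the grid minus a one-voxel border;
an ellipsoidal "brain" centred in this FOV would clip the cerebellar
spheres, and mask shape is immaterial to the method, so the box is kept
and both grid and mask are configurable.  This grid is deliberately
smaller than a scanner matrix; the method is geometry-agnostic and all
thresholds are recomputed per geometry.

**Smoothing and why the analysis default is 0 mm.** The generator's
`noise_fwhm = 6` mm reproduces the spatial smoothness that scanner-side
preprocessing (which includes 6-mm Gaussian smoothing) would leave in
real data, and the planted amplitudes are defined so that a fraction
`a` arrives at the classifier as a PSC of `100 a`.  Re-smoothing these
volumes in the analysis would double-smooth: it attenuates the planted
1.0 PSC to about 0.4, blurs sphere borders into each other (the right
putamen and pallidus merge), and inflates the apparent null smoothness.
`default_config()` therefore sets `preprocess$fwhm = 0` for synthetic
cohorts; `gaussian_smooth` (separable kernel, sigma = FWHM/2.3548 per
axis in mm, truncated at 4 sigma, renormalized, mask-aware) remains part
of the preprocessing stage with a 6-mm default for data that have not
been smoothed.  Smoothing order (before vs after PSC) is configurable;
the default smooths raw volumes first, matching the usual preprocessing
order.

**Percent signal change.** `psc = 100 (v - b) / b` per voxel.  The
baseline `b` defaults to the voxelwise mean of the run's null trials —
the sparse design has no within-trial baseline — with a run-mean
fallback.  PSC is invariant to global rescaling of a run; a non-positive
baseline voxel inside the mask is an error, not a warning.

## The classifier

The SVM is a linear soft-margin machine minimizing
`0.5 ||w||^2 + C * sum_i max(0, 1 - y_i (w.x_i + b))`, trained in the
dual by SMO pairwise updates on the Gram matrix: the first index is the
maximal KKT violator, its partner is chosen by the second-order
(maximal objective decrease) rule, each pairwise step is solved
analytically and clipped to the box, so the dual objective is
monotonically non-increasing.  Training stops at a KKT gap of `tol`
(default 1e-6); exceeding `max_iter` flags the model and warns rather
than silently accepting.  Selection is deterministic, so identical
inputs give identical models and row order is irrelevant.

`C` defaults to 100, the default of the AFNI `3dsvm` tool commonly used
for this analysis; no solver parameter is dictated by the motivating
method, so this is a package choice, exposed in the config.  No class
weighting is applied: the reference counts have LT and MT near parity.
Whole-brain mapping uses raw PSC features; the region-feature stage
z-scores each feature over its training set (standard MVPA practice for
few-feature models), stores the transform in the model, and reuses it
for held-out and WWR trials.  Decision values of exactly zero go to the
negative (LT-internal) class by a documented tie rule.

Sign conventions are kept separate by concern: the SVM's positive class
is MT everywhere (so positive group-t voxels and positive region weights
are MT-associated), while the confusion matrix counts LT as positive
(TP = LT predicted LT), matching the convention in which sensitivity is
the LT detection rate.  Region-level direction is always reported as
"higher-in MT/LT" rather than by raw sign.

## Cluster-size correction

`monte_carlo_cluster_threshold` simulates null volumes of unit Gaussian
noise at the configured smoothness inside the mask, thresholds |z| at
the two-tailed `voxel_p` quantile (default 0.01), and records each
iteration's maximum cluster size at the configured connectivity
(face-only by default — the conservative choice).  The minimum surviving
size is the `ceiling((1 - alpha) * n_iter)`-th order statistic plus one,
so an observed cluster at least that large has familywise null
probability of about `alpha` (default 0.05, 1000 iterations).  The null
smoothness is taken from the synthetic config when known (the quadrature
sum of generator and analysis FWHM); for real data it would be estimated
from residual neighbour correlations.  Volume thresholds in cubic mm are
specific to a grid and smoothness, so the package always recomputes the
threshold per geometry rather than reusing any published value; the
familywise error calibration is itself tested against a pure-null cohort
simulation.  Clusters below the minimum are retained in the output table
flagged `survived = FALSE` (an uncorrected report, mirroring the
practice of noting near-threshold regions), but only survivors feed the
classification stage.

## Numerical and degenerate-case conventions

* Noise volumes are variance-normalized exactly (the separable kernel's
  per-axis sum of squared weights), so the empirical voxel SD equals
  `noise_sd` everywhere including edges.
* Zero across-subject variance at a voxel flags the group t as
  undefined (NA) rather than +/-Inf.
* A per-subject metric that is constant across subjects has no t
  statistic; it is reported as degenerate (the expected situation for
  specificity at ceiling).  A metric constant *exactly at* chance is
  reported as t = 0, p = 1.
* A LOOCV fold whose training set loses a class is skipped with a
  warning (possible only when a class has two trials).
* Subjects without WWR trials are excluded from assignment fractions and
  listed; with fewer than 3 WWR trials the per-subject fraction is
  flagged as coarse.
* WWR features are taken from run 2, the run the final model was built
  on (configurable); the stored training standardization is reused.
* Per-subject seeds are `master_seed + subject_index`; the Monte-Carlo
  null uses `master_seed + 7919`.

## Problem sizes used by the tests

The test suite exercises the full default cohort (20 subjects,
38 x 40 x 42 grid, about 2400 volumes, roughly half a minute) plus a
WWR-planted-as-MT control cohort; the familywise-rate calibration uses a
16^3 grid with 2000 null iterations and 200 replicate null cohorts; the
solver is checked against a brute-force primal grid-refinement oracle on
point sets of at most eight points, and the cluster null against an
independent-Bernoulli-field oracle on a 4^3 mask with 10^4 draws.  These
sizes are the package's chosen trade-off between statistical resolution
and a test suite that stays pleasant to run.

## Known limitations

* The generator's realism limits are listed above; in particular,
  planted effects are spatially binary (sphere in/out), so recovery
  Jaccard has no partial-volume ambiguity.
* The whole-brain SVM stores a dense weight per voxel; grids much larger
  than scanner resolution would need a sparse or chunked Gram-matrix
  path.
* Cluster correction controls the familywise error of cluster *extent*
  only; no random-field or permutation alternatives are provided.
* The CLI covers simulation and the end-to-end run; intermediate stages
  are driven from R.
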