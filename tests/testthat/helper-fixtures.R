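# Small geometries and synthetic configs used across tests.

tiny_geometry <- function(n = 12L, vox = 3, origin = -(n - 1) / 2 * vox) {
  acq_geometry(rep(n, 3), rep(vox, 3), origin = rep(origin, 3))
}

# Two well-separated planted regions inside a small grid: one MT, one LT
# (the LT region also carries the WWR pattern, as in the default truth).
tiny_ground_truth <- function(amplitude = 0.01, noise_sd = 0.01,
                              noise_fwhm = 6, baseline = 100,
                              wwr_pattern = "LT") {
  gt <- default_ground_truth(amplitude = amplitude, noise_sd = noise_sd,
                             noise_fwhm = noise_fwhm, baseline = baseline,
                             wwr_pattern = wwr_pattern)
  mt_eff <- c(MT = amplitude)
  lt_eff <- c(LT = amplitude)
  if (wwr_pattern == "MT") mt_eff <- c(mt_eff, WWR = amplitude)
  if (wwr_pattern == "LT") lt_eff <- c(lt_eff, WWR = amplitude)
  gt$roi_specs <- list(
    list(name = "mt_roi", center = c(-8, -8, -8), radius = 5,
         effects = mt_eff, assoc = "MT"),
    list(name = "lt_roi", center = c(8, 8, 8), radius = 5,
         effects = lt_eff, assoc = "LT"))
  gt
}

tiny_synth_config <- function(geometry = tiny_geometry(16),
                              ground_truth = tiny_ground_truth(),
                              counts = sample_counts(mode = "fixed")[1, ],
                              n_task = 60L, n_null = 20L) {
  synth_config(geometry = geometry, ground_truth = ground_truth,
               counts = counts, n_task = n_task, n_null = n_null)
}

# Wrap a weight volume as a discrimination_map (for group-level tests).
as_disc_map <- function(weights, geometry, subject_id = NA) {
  w <- array(0, geometry$grid_shape)
  w[geometry$mask] <- weights[geometry$mask]
  structure(list(subject_id = subject_id, weights = w,
                 convention = c(negative = "LT", positive = "MT"),
                 model = NULL, geometry = geometry),
            class = "discrimination_map")
}

# A group_tmap built directly from a t array (for threshold tests).
as_group_tmap <- function(tarr, geometry, df) {
  structure(list(t = tarr, df = as.integer(df),
                 n_subjects = as.integer(df) + 1L,
                 undefined = array(FALSE, geometry$grid_shape),
                 geometry = geometry,
                 convention = c(negative = "LT", positive = "MT")),
            class = "group_tmap")
}
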