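as_nifti_volume <- function(arr, geometry) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geometry$voxel_size
  RNifti::qform(img) <- structure(geometry$affine, code = 2L)
  img
}

#' Write a 3-D or 4-D volume as NIfTI
#'
#' @param arr 3-D array, list of 3-D arrays, or 4-D array.
#' @param geometry An `acq_geometry` providing voxel size and affine.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, geometry, path) {
  if (is.list(arr))
    arr <- array(unlist(arr), c(geometry$grid_shape, length(arr)))
  RNifti::writeNifti(as_nifti_volume(arr, geometry), path)
  invisible(path)
}

#' Write a subject dataset to a directory
#'
#' Produces one 4-D NIfTI per run (`run1.nii.gz`, `run2.nii.gz`), the
#' brain mask (`mask.nii.gz`), the per-trial events table (`events.tsv`
#' with trial_id, run, onset_index, symptom_codes, type) and a geometry
#' sidecar (`geometry.json`).
#'
#' @param dataset A `subject_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geom <- dataset$geometry
  for (r in 1:2)
    write_volume(dataset$runs[[r]]$volumes, geom,
                 file.path(dir, sprintf("run%d.nii.gz", r)))
  write_volume(geom$mask + 0, geom, file.path(dir, "mask.nii.gz"))
  ev <- do.call(rbind, lapply(dataset$runs, function(r)
    r$trials[, c("trial_id", "run", "onset_index", "symptom_codes",
                 "type")]))
  utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subject_id = dataset$subject_id, seed = dataset$seed,
         grid_shape = geom$grid_shape, voxel_size = geom$voxel_size,
         affine = geom$affine),
    file.path(dir, "geometry.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a subject dataset written by [write_subject_dataset()]
#'
#' @param dir Directory containing the subject artifacts.
#' @return A `subject_dataset`.
#' @export
read_subject_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "geometry.json"),
                              simplifyVector = TRUE)
  mask_img <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  geom <- acq_geometry(meta$grid_shape, meta$voxel_size,
                       affine = matrix(unlist(meta$affine), 4, 4,
                                       byrow = FALSE),
                       mask = array(as.logical(mask_img > 0.5),
                                    dim = meta$grid_shape))
  ev <- utils::read.table(file.path(dir, "events.tsv"), sep = "\t",
                          header = TRUE,
                          colClasses = c("integer", "integer", "integer",
                                         "character", "character"))
  ev$symptom_codes[is.na(ev$symptom_codes)] <- ""
  runs <- lapply(1:2, function(r) {
    vols4d <- RNifti::readNifti(file.path(dir,
                                          sprintf("run%d.nii.gz", r)))
    trials <- ev[ev$run == r, , drop = FALSE]
    rownames(trials) <- NULL
    trials$is_null <- trials$type == "NULL"
    volumes <- lapply(seq_len(dim(vols4d)[4]), function(i)
      array(vols4d[, , , i], dim = meta$grid_shape))
    list(trials = trials, volumes = volumes)
  })
  structure(list(subject_id = meta$subject_id, geometry = geom,
                 runs = runs, seed = meta$seed),
            class = "subject_dataset")
}

#' Write a roi_set as a labelled volume plus JSON table
#'
#' @param roiset A `roi_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_roi_set <- function(roiset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(roiset$labels, roiset$geometry,
               file.path(dir, "roi_labels.nii.gz"))
  jsonlite::write_json(
    list(table = roiset$table, voxel_p = roiset$voxel_p,
         min_cluster_voxels = roiset$min_cluster_voxels,
         convention = as.list(roiset$convention)),
    file.path(dir, "roi_table.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
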