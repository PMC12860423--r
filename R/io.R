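#' Read and write GM volumes as NIfTI-1
#'
#' Volumes are written with an isotropic diagonal affine (`voxel_mm`
#' millimetres per voxel), matching the 2 mm resampled space the analysis
#' assumes by default.
#'
#' @param volume 3-D numeric array.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param voxel_mm Isotropic voxel size in mm.
#' @return `path`, invisibly (write); a 3-D array (read).
#' @export
write_gm_nifti <- function(volume, path, voxel_mm = 2) {
  stopifnot(length(dim(volume)) == 3L)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_gm_nifti
#' @export
read_gm_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attr(arr, "voxel_mm") <- unname(RNifti::pixdim(img)[1])
  arr
}

#' Write an atlas as NIfTI plus a region lookup CSV
#'
#' @param atlas A `gm_atlas`.
#' @param nifti_path Path for the integer label volume.
#' @param regions_path Path for the region table CSV (default: alongside the
#'   NIfTI with extension `.csv`).
#' @export
write_atlas <- function(atlas, nifti_path,
                        regions_path = sub("\\.nii(\\.gz)?$", ".csv", nifti_path)) {
  stopifnot(inherits(atlas, "gm_atlas"))
  write_gm_nifti(atlas$labels, nifti_path, voxel_mm = atlas$voxel_mm)
  readr::write_csv(atlas$regions, regions_path)
  invisible(nifti_path)
}

#' Read/write the cohort table as CSV
#'
#' The on-disk header is `subject_id,site,group,sex,age` plus any extra
#' columns present (e.g. `corrupted`, `qc_excluded`).
#'
#' @param cohort A cohort tibble (or a `gm_cohort`, whose table is used).
#' @param path CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (inherits(cohort, "gm_cohort")) cohort <- cohort$cohort
  stopifnot(all(c("subject_id", "site", "group", "sex", "age") %in% names(cohort)))
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Save or load a resampling configuration as YAML
#'
#' All seeds and parameters are explicit in the file, so a saved config plus
#' the package version suffices to re-run an experiment bit-identically.
#'
#' @param config A [resampling_config()].
#' @param path YAML path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  do.call(resampling_config, yaml::read_yaml(path))
}
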