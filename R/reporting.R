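#' Combined per-region PD/FP table across arms and scopes
#'
#' Builds the wide region table mirroring the standard presentation: one row
#' per region, and for each named analysis a probability-of-detection column
#' and a false-positive column, rounded to three decimals (full precision is
#' preserved by [write_region_table()]'s JSON sidecar).
#'
#' @param summaries Named list; each element is a list with components `pd`
#'   and/or `fp`, both `resampling_summary` objects on the same atlas.
#'   Example: `list(SAM_pooled = list(pd = s1, fp = s2))` yields columns
#'   `SAM_pooled_Pd` and `SAM_pooled_FP`.
#' @param digits Rounding applied to the displayed values (default 3).
#' @return Tibble with `region_id`, `name`, `n_voxels` and one or two value
#'   columns per analysis.
#' @export
region_table <- function(summaries, digits = 3) {
  stopifnot(is.list(summaries), length(summaries) >= 1, !is.null(names(summaries)))
  ref <- NULL
  for (nm in names(summaries)) for (s in summaries[[nm]]) {
    ids <- s$region_id
    if (is.null(ref)) ref <- s[, c("region_id", "name", "n_voxels")]
    else if (!identical(sort(ids), sort(ref$region_id)))
      stop("mismatched region sets across summaries")
  }
  out <- tibble::as_tibble(as.data.frame(ref))
  for (nm in names(summaries)) {
    pair <- summaries[[nm]]
    if (!is.null(pair$pd))
      out[[paste0(nm, "_Pd")]] <- unname(round(
        pair$pd$frequency[match(out$region_id, pair$pd$region_id)], digits))
    if (!is.null(pair$fp))
      out[[paste0(nm, "_FP")]] <- unname(round(
        pair$fp$frequency[match(out$region_id, pair$fp$region_id)], digits))
  }
  out
}

#' Write a region table as CSV with a full-precision JSON sidecar
#'
#' @param tbl Output of [region_table()] (or any tibble).
#' @param path CSV path; the sidecar is `path` with extension `.json`.
#' @export
write_region_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  jsonlite::write_json(tbl, sub("\\.csv$", ".json", path),
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Permutation p-values for regions flagged above the chance band
#'
#' Filters a resampling summary to the regions whose flagged-iteration count
#' strictly exceeds the chance expectation `alpha * n_iterations` (with 1000
#' iterations at level 0.05 the band is 50 flags), and lists their
#' permutation p-values — the regions worth reading, since everything below
#' the band is indistinguishable from chance.
#'
#' @param summary A `resampling_summary`.
#' @param alpha Per-iteration level used for the band (default: the
#'   experiment's own alpha).
#' @return Tibble `(region_id, name, flag_count, frequency, p_value)` for
#'   the included regions (possibly empty, header preserved).
#' @export
pvalue_table <- function(summary, alpha = NULL) {
  stopifnot(inherits(summary, "resampling_summary"))
  if (is.null(alpha)) alpha <- attr(summary, "config")$alpha
  band <- alpha * attr(summary, "n_iterations")
  keep <- summary$flag_count > band
  out <- tibble::as_tibble(as.data.frame(
    summary[keep, c("region_id", "name", "flag_count", "frequency", "p_value")]))
  attr(out, "band") <- band
  out
}

#' Significant-voxel counts per design and contrast
#'
#' @param results Named list of `spm_map` objects (names identify the scope,
#'   e.g. `"Database"`, `"NYU"`).
#' @return Tibble `(scope, contrast, n_voxels)`, one row per scope/contrast.
#' @export
voxel_count_table <- function(results) {
  stopifnot(is.list(results), !is.null(names(results)))
  rows <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    stopifnot(inherits(x, "spm_map"))
    for (ct in names(x$results))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scope = nm, contrast = ct,
        n_voxels = x$results[[ct]]$n_significant_voxels)
  }
  dplyr::bind_rows(rows)
}

#' Write per-region detection frequencies as a NIfTI overlay
#'
#' Paints each region's PD/FP frequency (or any per-region column) into the
#' atlas volume and writes it as NIfTI, for overlay on anatomy.
#'
#' @param summary A `resampling_summary`.
#' @param atlas The matching `gm_atlas`.
#' @param path Output NIfTI path.
#' @param column Column painted (default `"frequency"`).
#' @export
write_frequency_map <- function(summary, atlas, path, column = "frequency") {
  vol <- region_map_volume(atlas,
    stats::setNames(summary[[column]], summary$region_id))
  write_gm_nifti(vol, path, voxel_mm = atlas$voxel_mm)
}

#' Snapshot of a full run: configs, QC, summaries and artifact paths
#'
#' Bundles everything needed to regenerate an analysis bit-identically:
#' the resampling configs (with seeds), the QC report, and the produced
#' summaries/tables. Serialize the config part with [write_config_yaml()].
#'
#' @param summaries Named list of `resampling_summary` objects.
#' @param qc Optional `qc_report`.
#' @param tables Optional named list of produced tables.
#' @return A `run_report` list.
#' @export
run_report <- function(summaries, qc = NULL, tables = list()) {
  stopifnot(is.list(summaries), !is.null(names(summaries)))
  configs <- lapply(summaries, attr, "config")
  structure(list(summaries = summaries, configs = configs, qc = qc,
                 tables = tables),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d summaries: %s\n", length(x$summaries),
              paste(names(x$summaries), collapse = ", ")))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %d excluded of %d subjects\n",
                sum(x$qc$excluded), nrow(x$qc)))
  invisible(x)
}

#' Size-versus-frequency scatter for one or two designs
#'
#' @param profile Output of [size_power_profile()].
#' @param label_top Label the `label_top` highest-frequency regions.
#' @return A ggplot object.
#' @export
plot_size_power <- function(profile, label_top = 5) {
  long <- tidyr::pivot_longer(profile, cols = dplyr::any_of(c("pd", "fp")),
                              names_to = "design", values_to = "frequency")
  long <- long[!is.na(long$frequency), ]
  lab <- dplyr::slice_max(dplyr::group_by(long, .data$design),
                          .data$frequency, n = label_top, with_ties = FALSE)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_voxels, y = .data$frequency)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$name),
                       vjust = -0.6, size = 2.7) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~design,
      labeller = ggplot2::as_labeller(c(pd = "probability of detection",
                                        fp = "false-positive rate"))) +
    ggplot2::labs(x = "region size (voxels)", y = "detection frequency") +
    ggplot2::theme_minimal()
}
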