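#' Per-subject flagged-voxel fractions from voxelwise z-scores
#'
#' For every in-mask voxel, each subject's value is standardized against the
#' cohort (mean and n-1 standard deviation across subjects, both groups
#' pooled; a zero-variance voxel yields z = 0 for everyone). A voxel is
#' flagged for a subject when |z| exceeds `z_thresh`; the subject's
#' `flagged_fraction` is the fraction of in-mask voxels flagged. Large
#' fractions indicate failed preprocessing rather than biology.
#'
#' @param x A `gm_cohort`, or a numeric matrix (subjects x voxels, rownames
#'   taken as subject ids).
#' @param z_thresh Absolute z-score above which a voxel is flagged
#'   (default 5).
#' @param by_site Standardize within site instead of over the full cohort
#'   (requires a `gm_cohort`); default `FALSE`.
#' @return Tibble with `subject_id` and `flagged_fraction`, carrying
#'   `z_thresh` as an attribute.
#' @export
voxel_zscores <- function(x, z_thresh = 5, by_site = FALSE) {
  if (inherits(x, "gm_cohort")) {
    if (by_site) {
      parts <- split(seq_len(nrow(x$cohort)), x$cohort$site)
      out <- lapply(parts, function(i)
        voxel_zscores(x$gm[i, , drop = FALSE], z_thresh = z_thresh))
      res <- dplyr::bind_rows(out)
      res <- res[match(x$cohort$subject_id, res$subject_id), ]
      attr(res, "z_thresh") <- z_thresh
      return(res)
    }
    x <- x$gm
  }
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (n < 3L) stop("insufficient cohort for z-scores (need >= 3 subjects)")
  mu <- colMeans(x)
  ss <- colSums(x^2) - n * mu^2
  sdv <- sqrt(pmax(ss, 0) / (n - 1))
  ok <- sdv > 0
  flagged <- integer(n)
  if (any(ok)) {
    z <- sweep(x[, ok, drop = FALSE], 2, mu[ok], "-")
    z <- sweep(z, 2, sdv[ok], "/")
    flagged <- rowSums(abs(z) > z_thresh)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n))
  out <- tibble::tibble(subject_id = ids,
                        flagged_fraction = unname(flagged) / ncol(x))
  attr(out, "z_thresh") <- z_thresh
  out
}

#' Mark suspicious and excluded subjects from flagged fractions
#'
#' A subject is *suspicious* when strictly more than `frac_thresh` of its
#' in-mask voxels were flagged. Exclusion additionally requires confirmation:
#' in the original workflow this was visual inspection; here `confirm` is an
#' explicit subject-id list standing in for it, defaulting to confirming all
#' suspicious subjects so the pipeline stays automatable.
#'
#' @param fractions Output of [voxel_zscores()] (tibble with `subject_id`,
#'   `flagged_fraction`).
#' @param frac_thresh Flagged-fraction threshold (default 0.03; the rule is
#'   strict: exactly 3% is not suspicious).
#' @param confirm Optional character vector of subject ids confirmed for
#'   exclusion; `NULL` confirms every suspicious subject.
#' @return A `qc_report` tibble: `subject_id`, `flagged_fraction`,
#'   `suspicious`, `excluded`.
#' @export
flag_outliers <- function(fractions, frac_thresh = 0.03, confirm = NULL) {
  stopifnot(all(c("subject_id", "flagged_fraction") %in% names(fractions)),
            frac_thresh >= 0)
  out <- tibble::tibble(
    subject_id = fractions$subject_id,
    flagged_fraction = unname(fractions$flagged_fraction),
    suspicious = unname(fractions$flagged_fraction > frac_thresh)
  )
  out$excluded <- out$suspicious &
    (if (is.null(confirm)) TRUE else out$subject_id %in% confirm)
  attr(out, "frac_thresh") <- frac_thresh
  attr(out, "z_thresh") <- attr(fractions, "z_thresh")
  class(out) <- c("qc_report", class(out))
  out
}

#' Run the two-criterion QC rule and mark exclusions on a cohort
#'
#' Convenience chain: [voxel_zscores()] then [flag_outliers()], writing the
#' result into the cohort's `qc_excluded` column.
#'
#' @inheritParams voxel_zscores
#' @inheritParams flag_outliers
#' @return The `gm_cohort` with `qc_excluded` updated and the `qc_report`
#'   attached as attribute `qc_report`.
#' @export
apply_qc <- function(x, z_thresh = 5, frac_thresh = 0.03, confirm = NULL,
                     by_site = FALSE) {
  stopifnot(inherits(x, "gm_cohort"))
  rep <- flag_outliers(voxel_zscores(x, z_thresh = z_thresh, by_site = by_site),
                       frac_thresh = frac_thresh, confirm = confirm)
  x$cohort$qc_excluded <- unname(rep$excluded[match(x$cohort$subject_id, rep$subject_id)])
  attr(x, "qc_report") <- rep
  x
}

#' Write a QC report as CSV
#'
#' @param report A `qc_report` from [flag_outliers()].
#' @param path CSV path.
#' @export
write_qc_csv <- function(report, path) {
  readr::write_csv(report, path)
  invisible(path)
}
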