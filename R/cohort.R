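#' Specify planted effects, site offsets and corruption for a synthetic cohort
#'
#' The generative model for one subject's grey-matter (GM) probability map is
#' `gm(v) = baseline(v) + site_offset + group_effect(v) + noise`, clipped to
#' the valid probability range \[0, 1\]. The baseline is a smooth radially
#' decaying field spanning \[0.2, 0.8\] inside the brain mask; the group
#' effect adds `effect_size_d * noise_sd` at every voxel of the chosen effect
#' regions for case (ASC) subjects, so `effect_size_d` is the per-voxel
#' standardized difference (Cohen's d); site offsets are additive scalar
#' intensity shifts, the simplest structure capturing multi-site scanner and
#' protocol heterogeneity.
#'
#' A fraction of subjects can be marked as "failed preprocessing": a random
#' subset of their in-mask voxels is shifted by a large multiple of the noise
#' standard deviation (see [inject_corruption()]), emulating segmentation or
#' registration failures that the quality-control rule is meant to catch.
#'
#' @param effect_regions Integer region ids carrying the planted group effect.
#' @param effect_size_d Per-voxel standardized mean difference (unitless).
#' @param site_offsets Named numeric vector of additive per-site intensity
#'   shifts; sites not listed get 0.
#' @param noise_sd Standard deviation of i.i.d. per-voxel subject noise
#'   (GM probability units).
#' @param noise_smooth_fwhm Optional FWHM (mm) with which to smooth the noise
#'   field, giving spatially correlated noise; 0 (default) keeps noise i.i.d.
#' @param corruption_rate Fraction of subjects receiving injected corruption.
#' @param corruption_frac Fraction of in-mask voxels corrupted within a
#'   corrupted scan.
#' @param corruption_magnitude Size of the corruption shift, in multiples of
#'   `noise_sd`.
#' @return An `effect_spec` list, validated.
#' @export
effect_spec <- function(effect_regions = integer(), effect_size_d = 0,
                        site_offsets = NULL, noise_sd = 0.05,
                        noise_smooth_fwhm = 0,
                        corruption_rate = 0, corruption_frac = 0.05,
                        corruption_magnitude = 10) {
  stopifnot(noise_sd > 0,
            corruption_rate >= 0, corruption_rate <= 1,
            corruption_frac >= 0, corruption_frac <= 1,
            noise_smooth_fwhm >= 0)
  structure(list(effect_regions = as.integer(effect_regions),
                 effect_size_d = effect_size_d,
                 site_offsets = site_offsets,
                 noise_sd = noise_sd,
                 noise_smooth_fwhm = noise_smooth_fwhm,
                 corruption_rate = corruption_rate,
                 corruption_frac = corruption_frac,
                 corruption_magnitude = corruption_magnitude),
            class = "effect_spec")
}

#' Generate a multi-site two-group cohort of synthetic GM maps
#'
#' Simulates one GM probability map per subject on the atlas grid, following
#' the generative model documented in [effect_spec()]. Subjects are split
#' into healthy controls (HC) and cases (ASC) per site, with sex and age
#' drawn to echo the male-skewed, adolescent-centred demographics typical of
#' multi-site autism cohorts.
#'
#' @param atlas A `gm_atlas` from [generate_atlas()].
#' @param site_sizes Either a named list mapping site name to `c(n_HC, n_ASC)`
#'   or a tibble/data.frame with columns `site`, `n_hc`, `n_asc`.
#' @param spec An [effect_spec()].
#' @param seed Integer seed; cohorts are bit-identical given the same inputs.
#'
#' @return A `gm_cohort` object: list with `cohort` (tibble: `subject_id`,
#'   `site`, `group`, `sex`, `age`, `corrupted`, `qc_excluded`), `gm` (matrix,
#'   subjects x in-mask voxels in `atlas$mask_index` order), `dim`,
#'   `mask_index`, `voxel_mm`.
#' @export
#' @examples
#' atl <- generate_atlas(c(20, 20, 20), n_regions = 4, seed = 1)
#' coh <- generate_cohort(atl, list(SITE_A = c(10, 8)), seed = 2)
#' dplyr::count(coh$cohort, site, group)
generate_cohort <- function(atlas, site_sizes, spec = effect_spec(), seed = 1L) {
  stopifnot(inherits(atlas, "gm_atlas"), inherits(spec, "effect_spec"))
  sz <- normalize_site_sizes(site_sizes)
  if (nrow(sz) == 0L) stop("site_sizes must be nonempty")
  bad <- setdiff(spec$effect_regions, atlas$regions$region_id)
  if (length(bad)) stop("unknown region id(s) in effect_regions: ",
                        paste(bad, collapse = ", "))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  cohort <- tidyr::pivot_longer(sz, cols = c("n_hc", "n_asc"),
                                names_to = "group", values_to = "n")
  cohort$group <- ifelse(cohort$group == "n_hc", "HC", "ASC")
  cohort <- tidyr::uncount(cohort[cohort$n > 0, ], weights = .data$n)
  n <- nrow(cohort)
  if (n == 0L) stop("site_sizes must contain at least one subject")
  cohort <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    site = cohort$site,
    group = cohort$group,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.82, 0.18)),
    age = round(pmin(pmax(rnorm(n, 15, 6), 6), 60), 1)
  )

  n_mask <- length(atlas$mask_index)
  baseline <- 0.8 - 0.6 * atlas$rho2  # radial decay, 0.8 centre -> 0.2 rim

  offsets <- rep(0, n)
  if (!is.null(spec$site_offsets)) {
    o <- spec$site_offsets[cohort$site]
    o[is.na(o)] <- 0
    offsets <- unname(o)
  }

  effect_cols <- integer(0)
  if (length(spec$effect_regions)) {
    lab <- atlas$labels[atlas$mask_index]
    effect_cols <- which(lab %in% spec$effect_regions)
  }

  gm <- matrix(rnorm(n * n_mask, sd = spec$noise_sd), nrow = n)
  if (spec$noise_smooth_fwhm > 0) {
    for (i in seq_len(n)) {
      vol <- array(0, dim = dim(atlas$labels))
      vol[atlas$mask_index] <- gm[i, ]
      vol <- gaussian_smooth(vol, fwhm_mm = spec$noise_smooth_fwhm,
                             voxel_mm = atlas$voxel_mm,
                             mask = atlas$labels > 0)
      sm <- vol[atlas$mask_index]
      # rescale so the marginal voxel noise keeps sd = noise_sd
      gm[i, ] <- sm * spec$noise_sd / stats::sd(sm)
    }
  }
  gm <- sweep(gm, 2, baseline, "+") + offsets
  if (length(effect_cols)) {
    asc <- cohort$group == "ASC"
    gm[asc, effect_cols] <- gm[asc, effect_cols] +
      spec$effect_size_d * spec$noise_sd
  }
  gm[gm < 0] <- 0
  gm[gm > 1] <- 1

  corrupted <- rep(FALSE, n)
  n_corrupt <- round(spec$corruption_rate * n)
  if (n_corrupt > 0 && spec$corruption_frac > 0) {
    who <- sample.int(n, n_corrupt)
    corrupted[who] <- TRUE
    for (i in who) {
      gm[i, ] <- inject_corruption(gm[i, ], frac = spec$corruption_frac,
                                   magnitude = spec$corruption_magnitude,
                                   noise_sd = spec$noise_sd,
                                   seed = derive_seed(seed, paste0("corrupt", i)))
    }
  }
  cohort$corrupted <- corrupted
  cohort$qc_excluded <- FALSE
  rownames(gm) <- cohort$subject_id

  structure(list(cohort = cohort, gm = gm, dim = dim(atlas$labels),
                 mask_index = atlas$mask_index, voxel_mm = atlas$voxel_mm,
                 spec = spec, seed = seed),
            class = "gm_cohort")
}

normalize_site_sizes <- function(site_sizes) {
  if (is.data.frame(site_sizes)) {
    stopifnot(all(c("site", "n_hc", "n_asc") %in% names(site_sizes)))
    return(tibble::as_tibble(site_sizes[, c("site", "n_hc", "n_asc")]))
  }
  stopifnot(is.list(site_sizes), !is.null(names(site_sizes)))
  tibble::tibble(
    site = names(site_sizes),
    n_hc = vapply(site_sizes, function(x) as.integer(x[1]), integer(1)),
    n_asc = vapply(site_sizes, function(x) as.integer(x[2]), integer(1))
  )
}

#' @export
print.gm_cohort <- function(x, ...) {
  tab <- table(x$cohort$group)
  cat(sprintf("<gm_cohort> %d subjects (%s), %d sites, %d in-mask voxels\n",
              nrow(x$cohort),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              length(unique(x$cohort$site)), ncol(x$gm)))
  if (any(x$cohort$corrupted))
    cat(sprintf("  %d corrupted scan(s) injected\n", sum(x$cohort$corrupted)))
  if (any(x$cohort$qc_excluded))
    cat(sprintf("  %d subject(s) QC-excluded\n", sum(x$cohort$qc_excluded)))
  invisible(x)
}

#' Inject localized corruption into a GM volume
#'
#' Shifts exactly `round(frac * n_voxels)` randomly chosen in-mask voxels by
#' `magnitude * noise_sd` with random sign, emulating a failed-preprocessing
#' scan. Values are clipped to \[0, 1\]; if clipping would leave a chosen
#' voxel unchanged the opposite sign is used, so every chosen voxel differs
#' from the input.
#'
#' @param volume Numeric vector of in-mask GM values, or a 3-D array (then
#'   `mask` selects the in-mask voxels; default: all nonzero voxels).
#' @param frac Fraction of in-mask voxels to corrupt (`frac = 0` returns the
#'   input untouched).
#' @param magnitude Shift size in multiples of `noise_sd`.
#' @param noise_sd Noise scale of the parent cohort.
#' @param seed Integer seed; corrupted positions are deterministic given it.
#' @param mask Optional logical array for 3-D input.
#' @return Same shape as `volume`.
#' @export
inject_corruption <- function(volume, frac, magnitude = 10, noise_sd = 0.05,
                              seed = 1L, mask = NULL) {
  stopifnot(frac >= 0, frac <= 1)
  if (frac == 0) return(volume)
  if (is.array(volume) && length(dim(volume)) == 3L) {
    if (is.null(mask)) mask <- volume != 0
    vals <- volume[mask]
    volume[mask] <- inject_corruption(vals, frac, magnitude, noise_sd, seed)
    return(volume)
  }
  v <- as.numeric(volume)
  n_flip <- round(frac * length(v))
  if (n_flip == 0L) return(volume)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- sample.int(length(v), n_flip)
  sgn <- sample(c(-1, 1), n_flip, replace = TRUE)
  shift <- sgn * magnitude * noise_sd
  out <- pmin(pmax(v[pos] + shift, 0), 1)
  same <- out == v[pos]
  if (any(same)) out[same] <- pmin(pmax(v[pos][same] - shift[same], 0), 1)
  v[pos] <- out
  if (is.matrix(volume)) dim(v) <- dim(volume)
  v
}

#' Reconstruct one subject's 3-D volume from a cohort
#'
#' @param x A `gm_cohort`.
#' @param subject Subject id (character) or row index.
#' @return A 3-D numeric array (0 outside the brain mask).
#' @export
cohort_volume <- function(x, subject) {
  stopifnot(inherits(x, "gm_cohort"))
  i <- if (is.character(subject)) match(subject, x$cohort$subject_id) else subject
  if (is.na(i) || i < 1 || i > nrow(x$gm)) stop("unknown subject: ", subject)
  vol <- array(0, dim = x$dim)
  vol[x$mask_index] <- x$gm[i, ]
  vol
}

# Subset a gm_cohort to given subject ids (order preserved as given).
cohort_subset <- function(x, ids) {
  i <- match(ids, x$cohort$subject_id)
  stopifnot(!anyNA(i))
  out <- x
  out$cohort <- x$cohort[i, ]
  out$gm <- x$gm[i, , drop = FALSE]
  out
}
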