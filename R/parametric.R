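#' Convert a Gaussian FWHM in mm to a kernel sigma in voxels
#'
#' @param fwhm_mm Full width at half maximum, millimetres.
#' @param voxel_mm Voxel size, millimetres.
#' @return Sigma in voxel units: `fwhm_mm / (voxel_mm * 2 * sqrt(2 * log(2)))`.
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_mm = 2) {
  fwhm_mm / (voxel_mm * 2 * sqrt(2 * log(2)))
}

# Dense 1-D Gaussian convolution matrix (n x n), rows renormalized so a
# constant signal is preserved exactly (kernel truncated at 4 sigma).
gauss_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-d^2 / (2 * sigma^2))
  K[abs(d) > r] <- 0
  K / rowSums(K)
}

#' Separable Gaussian smoothing of a 3-D volume
#'
#' Applies an axis-separable Gaussian of the given FWHM. When a brain mask is
#' supplied the kernel is renormalized inside the mask
#' (`smooth(v * m) / smooth(m)`), which avoids the edge attenuation that
#' plain zero-padded smoothing produces at the brain boundary — exactly where
#' registration artifacts concentrate. `fwhm_mm = 0` is the identity.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm Smoothing kernel FWHM in mm (default 8).
#' @param voxel_mm Voxel size in mm (default 2).
#' @param mask Optional logical 3-D array; output is 0 outside it.
#' @return Smoothed 3-D array.
#' @export
gaussian_smooth <- function(volume, fwhm_mm = 8, voxel_mm = 2, mask = NULL) {
  stopifnot(length(dim(volume)) == 3L, fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  sigma <- fwhm_to_sigma(fwhm_mm, voxel_mm)
  if (is.null(mask)) return(smooth3d(volume, sigma))
  m <- array(as.numeric(mask), dim = dim(volume))
  num <- smooth3d(volume * m, sigma)
  den <- smooth3d(m, sigma)
  out <- array(0, dim = dim(volume))
  inside <- m > 0 & den > 0
  out[inside] <- num[inside] / den[inside]
  out
}

smooth3d <- function(arr, sigma) {
  d <- dim(arr)
  K1 <- gauss_conv_matrix(d[1], sigma)
  K2 <- gauss_conv_matrix(d[2], sigma)
  K3 <- gauss_conv_matrix(d[3], sigma)
  x <- K1 %*% matrix(arr, d[1], d[2] * d[3])
  dim(x) <- d
  x <- aperm(x, c(2, 1, 3))
  x <- K2 %*% matrix(x, d[2], d[1] * d[3])
  dim(x) <- c(d[2], d[1], d[3])
  x <- aperm(x, c(3, 2, 1))
  x <- K3 %*% matrix(x, d[3], d[2] * d[1])
  dim(x) <- c(d[3], d[2], d[1])
  aperm(x, c(3, 2, 1))
}

#' Smooth every subject's map once (mask-renormalized)
#'
#' Smoothing does not depend on group labels, so it is applied once per
#' subject before any permutation work.
#'
#' @param cohort A `gm_cohort`.
#' @param fwhm_mm Kernel FWHM in mm (0 = no-op).
#' @return The `gm_cohort` with its `gm` matrix replaced by smoothed values.
#' @export
smooth_cohort <- function(cohort, fwhm_mm = 8) {
  stopifnot(inherits(cohort, "gm_cohort"))
  if (fwhm_mm == 0) return(cohort)
  mask <- array(FALSE, dim = cohort$dim)
  mask[cohort$mask_index] <- TRUE
  out <- cohort
  for (i in seq_len(nrow(cohort$gm))) {
    vol <- array(0, dim = cohort$dim)
    vol[cohort$mask_index] <- cohort$gm[i, ]
    sm <- gaussian_smooth(vol, fwhm_mm = fwhm_mm, voxel_mm = cohort$voxel_mm,
                          mask = mask)
    out$gm[i, ] <- sm[cohort$mask_index]
  }
  attr(out, "fwhm_mm") <- fwhm_mm
  out
}

#' Voxelwise two-sample t-map (two-group GLM special case)
#'
#' Pooled-variance two-sample t at every in-mask voxel, with
#' `df = n1 + n2 - 2`. The contrast picks the tested direction: `"HC<ASC"`
#' tests for larger GM in the case (ASC) group (+t where mean(ASC) >
#' mean(HC)); `"ASC<HC"` negates the map. Zero-pooled-variance voxels get
#' t = 0 so degenerate background voxels cannot seed clusters.
#'
#' @param cohort A `gm_cohort` (typically after [smooth_cohort()] via
#'   [spm_map()]), or a subjects x voxels matrix.
#' @param groups Optional label vector overriding `cohort$cohort$group`
#'   (two levels; for matrix input it is required).
#' @param contrast `"HC<ASC"` or `"ASC<HC"`.
#' @return A `t_map` object: list with `t_values` (3-D array for cohort
#'   input, vector for matrix input), `df`, `contrast`.
#' @export
glm_ttest <- function(cohort, groups = NULL, contrast = c("HC<ASC", "ASC<HC")) {
  contrast <- match.arg(contrast)
  if (inherits(cohort, "gm_cohort")) {
    keep <- !cohort$cohort$qc_excluded
    gm <- cohort$gm[keep, , drop = FALSE]
    if (is.null(groups)) groups <- cohort$cohort$group[keep]
    y <- ifelse(groups == "ASC", 1, -1)
    tv <- col_tstat(gm, y, var_equal = TRUE)
    if (contrast == "ASC<HC") tv <- -tv
    vol <- array(0, dim = cohort$dim)
    vol[cohort$mask_index] <- tv
    structure(list(t_values = vol, df = nrow(gm) - 2L, contrast = contrast,
                   mask_index = cohort$mask_index, dim = cohort$dim),
              class = "t_map")
  } else {
    stopifnot(is.matrix(cohort), !is.null(groups))
    g <- if (all(groups %in% c("HC", "ASC")))
      ifelse(groups == "ASC", 1, -1) else groups
    tv <- col_tstat(cohort, g, var_equal = TRUE)
    if (contrast == "ASC<HC") tv <- -tv
    structure(list(t_values = tv, df = nrow(cohort) - 2L, contrast = contrast),
              class = "t_map")
  }
}

# Connected components of supra-threshold voxels (linear indices into a grid
# of dimensions `dims`), with 6/18/26-connectivity. Returns a list of integer
# vectors (one per cluster).
label_clusters <- function(supra, dims, connectivity = 26) {
  n <- length(supra)
  if (n == 0L) return(list())
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  ord <- rowSums(abs(off))
  off <- off[ord > 0 & ord <= switch(as.character(connectivity),
                                     "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  pos <- arrayInd(supra, dims)
  edges <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    nb <- sweep(pos, 2, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
          nb[, 2] >= 1 & nb[, 2] <= dims[2] &
          nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1) * dims[1] * dims[2] + (nb[ok, 2] - 1) * dims[1] + nb[ok, 1]
    j <- match(lin, supra)
    hit <- !is.na(j)
    if (any(hit)) edges[[k]] <- cbind(which(ok)[hit], j[hit])
  }
  e <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(e) && nrow(e)) g <- igraph::add_edges(g, t(e))
  memb <- igraph::components(g)$membership
  unname(split(supra, memb))
}

#' Cluster-level FWE correction by a permutation max-cluster-size null
#'
#' Thresholds the one-sided t-map at the Student quantile for the
#' cluster-forming p, groups supra-threshold voxels into connected clusters,
#' and corrects cluster sizes against the null distribution of the maximum
#' cluster size over group-label permutations of the identical pipeline:
#' `corrected_p = (1 + #\{null max >= size\}) / (n_null + 1)`. The
#' permutation null is exact under exchangeability and needs no smoothness
#' estimation.
#'
#' Uses the current RNG state for the permutation stream; seed with
#' `set.seed()` (or let [spm_map()] / [run_experiment()] manage seeds).
#'
#' @param cohort `gm_cohort` (already smoothed) or subjects x voxels matrix.
#' @param groups Label vector (required for matrix input).
#' @param contrast Tested direction, see [glm_ttest()].
#' @param cluster_forming_p Uncorrected voxel-level threshold (default 0.001;
#'   0.05 is available as an exploratory preset).
#' @param alpha Cluster-level significance level.
#' @param n_null Number of label permutations (>= 99).
#' @param connectivity 6, 18 or 26 (default) neighbourhood.
#' @param dims Grid dimensions (matrix input only).
#' @param mask_index Linear in-mask indices (matrix input only).
#' @return A `cluster_result`: tibble `clusters` (`cluster_id`, `size`,
#'   `peak_t`, `corrected_p`, `significant`), list `voxels` of per-cluster
#'   linear indices, `n_significant_voxels`, `null_max` sizes, `t_threshold`.
#' @export
cluster_fwe <- function(cohort, groups = NULL, contrast = c("HC<ASC", "ASC<HC"),
                        cluster_forming_p = 0.001, alpha = 0.05, n_null = 199L,
                        connectivity = 26, dims = NULL, mask_index = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(n_null >= 99)
  if (inherits(cohort, "gm_cohort")) {
    keep <- !cohort$cohort$qc_excluded
    gm <- cohort$gm[keep, , drop = FALSE]
    if (is.null(groups)) groups <- cohort$cohort$group[keep]
    dims <- cohort$dim
    mask_index <- cohort$mask_index
  } else {
    gm <- cohort
    stopifnot(!is.null(groups), !is.null(dims), !is.null(mask_index))
  }
  y <- if (is.numeric(groups)) groups else ifelse(groups == "ASC", 1, -1)
  sgn <- if (contrast == "ASC<HC") -1 else 1
  df <- nrow(gm) - 2L
  t_crit <- qt(1 - cluster_forming_p, df)

  obs_t <- sgn * col_tstat(gm, y, var_equal = TRUE)
  obs_clusters <- label_clusters(mask_index[obs_t > t_crit], dims, connectivity)

  # batched permutation t-maps: group sums via one matrix product per chunk
  n <- length(y)
  n_pos <- sum(y > 0); n_neg <- n - n_pos
  tot <- colSums(gm)
  qtot <- colSums(gm^2)
  gm2 <- gm^2
  null_max <- integer(n_null)
  b <- 0L
  while (b < n_null) {
    k <- min(64L, n_null - b)
    Pa <- vapply(seq_len(k), function(i) as.numeric(sample(y) > 0),
                 numeric(n))
    s_pos <- crossprod(Pa, gm)    # k x V group sums
    q_pos <- crossprod(Pa, gm2)
    for (i in seq_len(k)) {
      m_pos <- s_pos[i, ] / n_pos
      m_neg <- (tot - s_pos[i, ]) / n_neg
      ss <- pmax(q_pos[i, ] - n_pos * m_pos^2, 0) +
            pmax((qtot - q_pos[i, ]) - n_neg * m_neg^2, 0)
      se <- sqrt(ss / df * (1 / n_pos + 1 / n_neg))
      tp <- (m_pos - m_neg) / se
      tp[se == 0] <- 0
      cl <- label_clusters(mask_index[sgn * tp > t_crit], dims, connectivity)
      null_max[b + i] <- if (length(cl)) max(lengths(cl)) else 0L
    }
    b <- b + k
  }

  sizes <- lengths(obs_clusters)
  if (length(sizes)) {
    pk <- vapply(obs_clusters, function(v)
      max(obs_t[match(v, mask_index)]), numeric(1))
    cp <- vapply(sizes, function(s) (1 + sum(null_max >= s)) / (n_null + 1),
                 numeric(1))
    clusters <- tibble::tibble(
      cluster_id = seq_along(sizes),
      size = as.integer(sizes),
      peak_t = pk,
      corrected_p = cp,
      significant = cp <= alpha
    )
  } else {
    clusters <- tibble::tibble(cluster_id = integer(), size = integer(),
                               peak_t = numeric(), corrected_p = numeric(),
                               significant = logical())
  }
  structure(list(clusters = clusters,
                 voxels = unname(obs_clusters),
                 n_significant_voxels = sum(clusters$size[clusters$significant]),
                 null_max = null_max, t_threshold = t_crit, df = df,
                 contrast = contrast, alpha = alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> contrast %s, t>%.3f (df=%d): %d cluster(s), %d significant voxel(s)\n",
              x$contrast, x$t_threshold, x$df, nrow(x$clusters),
              x$n_significant_voxels))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Voxelwise parametric mapping over both contrasts with region attribution
#'
#' Runs the full parametric arm: Gaussian smoothing of every map (8 mm FWHM
#' by default), a voxelwise two-sample t-map per contrast, cluster formation
#' and permutation FWE correction, then attributes each significant voxel to
#' its atlas region.
#'
#' @param cohort A `gm_cohort`.
#' @param atlas The matching `gm_atlas`.
#' @param fwhm_mm Smoothing FWHM in mm.
#' @param seed Seed for the permutation streams.
#' @inheritParams cluster_fwe
#' @return An `spm_map` object: `region_counts` tibble (`region_id`, `name`,
#'   `n_voxels`, `n_sig_HC<ASC`, `n_sig_ASC<HC`), `results` (named list of
#'   `cluster_result` per contrast), and the smoothing/threshold settings.
#' @export
spm_map <- function(cohort, atlas, fwhm_mm = 8, cluster_forming_p = 0.001,
                    alpha = 0.05, n_null = 199L, connectivity = 26, seed = 1L) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(atlas, "gm_atlas"))
  sm <- smooth_cohort(cohort, fwhm_mm = fwhm_mm)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  results <- list()
  counts <- list()
  for (ct in c("HC<ASC", "ASC<HC")) {
    set.seed(derive_seed(seed, ct))
    res <- cluster_fwe(sm, contrast = ct, cluster_forming_p = cluster_forming_p,
                       alpha = alpha, n_null = n_null,
                       connectivity = connectivity)
    results[[ct]] <- res
    sigvox <- unlist(res$voxels[res$clusters$significant], use.names = FALSE)
    lab <- if (length(sigvox)) atlas$labels[sigvox] else integer(0)
    counts[[ct]] <- tabulate(lab[lab > 0], nbins = nrow(atlas$regions))
  }
  region_counts <- atlas$regions
  region_counts[["n_sig_HC<ASC"]] <- as.integer(counts[["HC<ASC"]])
  region_counts[["n_sig_ASC<HC"]] <- as.integer(counts[["ASC<HC"]])
  structure(list(region_counts = region_counts, results = results,
                 fwhm_mm = fwhm_mm, cluster_forming_p = cluster_forming_p,
                 alpha = alpha, n_null = n_null, seed = seed),
            class = "spm_map")
}

#' @export
print.spm_map <- function(x, ...) {
  cat(sprintf("<spm_map> fwhm %g mm, cluster-forming p=%g, alpha=%g, %d permutations\n",
              x$fwhm_mm, x$cluster_forming_p, x$alpha, x$n_null))
  for (ct in names(x$results))
    cat(sprintf("  %s: %d significant voxel(s)\n", ct,
                x$results[[ct]]$n_significant_voxels))
  invisible(x)
}

#' @export
tidy.spm_map <- function(x, ...) {
  tibble::as_tibble(x$region_counts)
}

#' @export
glance.spm_map <- function(x, ...) {
  tibble::tibble(
    `n_sig_voxels_HC<ASC` = x$results[["HC<ASC"]]$n_significant_voxels,
    `n_sig_voxels_ASC<HC` = x$results[["ASC<HC"]]$n_significant_voxels,
    fwhm_mm = x$fwhm_mm, cluster_forming_p = x$cluster_forming_p,
    alpha = x$alpha, n_null = x$n_null
  )
}
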