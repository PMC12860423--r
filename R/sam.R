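#' Feature extraction/selection configuration for the region classifier
#'
#' @param k_voxels Number of voxels kept per region, ranked by absolute
#'   two-sample t statistic (default 50, the standard choice for 2 mm voxels
#'   and a ~116-region parcellation).
#' @param pls_components Number of partial-least-squares dimensions extracted
#'   from the selected voxels (default 1).
#' @return An `fes_config` list.
#' @export
fes_config <- function(k_voxels = 50L, pls_components = 1L) {
  stopifnot(k_voxels >= 1, pls_components >= 1)
  structure(list(k_voxels = as.integer(k_voxels),
                 pls_components = as.integer(pls_components)),
            class = "fes_config")
}

#' Rank and select voxels by two-sample t statistic
#'
#' Computes a per-voxel two-sample t (Welch by default: unequal group
#' variances are the norm in multi-site GM data) and returns the indices of
#' the `k` voxels with the largest |t|, ties broken by ascending voxel index
#' for determinism. Regions smaller than `k` return all their voxels.
#'
#' @param region_values Numeric matrix, subjects x voxels.
#' @param labels Group labels: two levels (any coding; +1/-1, "HC"/"ASC", ...).
#' @param k Number of voxels to keep.
#' @param var_equal Use pooled-variance t instead of Welch.
#' @return Integer vector of selected voxel column indices, ordered by
#'   decreasing |t|.
#' @export
select_voxels <- function(region_values, labels, k = 50L, var_equal = FALSE) {
  stopifnot(is.matrix(region_values), ncol(region_values) >= 1)
  t_abs <- abs(col_tstat(region_values, labels, var_equal = var_equal))
  ord <- order(-t_abs, seq_along(t_abs))
  ord[seq_len(min(k, length(t_abs)))]
}

# Vectorized per-column two-sample t. Zero-variance columns give t = 0.
col_tstat <- function(X, labels, var_equal = FALSE) {
  g <- as.factor(labels)
  if (nlevels(g) != 2L) stop("labels must have exactly two groups")
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("degenerate t-test: each group needs >= 2 subjects")
  X1 <- X[i1, , drop = FALSE]; X2 <- X[i2, , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- pmax(colSums(X1^2) - n1 * m1^2, 0) / (n1 - 1)
  v2 <- pmax(colSums(X2^2) - n2 * m2^2, 0) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
  }
  t <- (m2 - m1) / se
  t[se == 0] <- 0
  t
}

#' Partial-least-squares score extraction (PLS1 / NIPALS)
#'
#' Columns of `X` are centered internally; for a single component the weight
#' vector is the normalized cross-covariance `t(Xc) %*% y` and the scores are
#' `Xc %*% w`. Further components follow NIPALS deflation.
#'
#' @param X Numeric matrix, subjects x features.
#' @param y Numeric +1/-1 group labels.
#' @param n_components Number of score dimensions (<= ncol(X)).
#' @return Matrix of scores, subjects x `n_components`, with the weight
#'   matrix attached as attribute `weights`.
#' @export
pls_extract <- function(X, y, n_components = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(y), n_components >= 1,
            n_components <= ncol(X))
  Xc <- sweep(X, 2, colMeans(X), "-")
  if (all(abs(Xc) < .Machine$double.eps * 1e2)) stop("degenerate features: zero variance")
  yc <- y - mean(y)
  n <- nrow(X)
  scores <- matrix(0, n, n_components)
  W <- matrix(0, ncol(X), n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("degenerate features: no covariance with labels")
    w <- w / nw
    t_a <- drop(Xc %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xc, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xc <- Xc - tcrossprod(t_a, p_a)
    yc <- yc - q_a * t_a
    scores[, a] <- t_a
    W[, a] <- w
  }
  attr(scores, "weights") <- W
  scores
}

#' Resubstitution accuracy of a linear soft-margin SVM
#'
#' Trains a linear SVM (empirical risk minimization; cost C = 1, features
#' standardized) on the score matrix and evaluates it on the same sample,
#' returning the fraction correctly classified — the complement of the
#' replacement (resubstitution) error.
#'
#' @param scores Numeric matrix or vector of classifier inputs.
#' @param y Group labels with two levels.
#' @param cost Soft-margin cost parameter.
#' @return Empirical (training-sample) accuracy in \[0, 1\].
#' @export
fit_svm_resub <- function(scores, y, cost = 1) {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1)
  yf <- as.factor(y)
  if (nlevels(yf) != 2L) stop("need both classes present")
  sds <- apply(scores, 2, stats::sd)
  fit <- e1071::svm(x = scores, y = yf, kernel = "linear", cost = cost,
                    scale = sds > 0, type = "C-classification")
  mean(stats::predict(fit, scores) == yf)
}

#' Worst-case (concentration-bound) accuracy correction
#'
#' Lower-bounds the true accuracy from the empirical accuracy with
#' probability 1 - alpha using a distribution-free concentration inequality:
#' `worst = emp - Delta(n, alpha)`, floored at 0. The default is a
#' Vapnik-style bound with the VC complexity of a linear rule in the
#' extracted score space (h = 2),
#' `Delta = sqrt((h (log(2n/h) + 1) + log(4/alpha)) / n)`, which accounts
#' for the capacity of the trained classifier and is what keeps
#' resubstitution-based inference honest after feature selection. The plain
#' two-sided Hoeffding test-set bound `Delta = sqrt(log(2/alpha) / (2 n))`
#' is available but makes no allowance for fitting and selection, so it is
#' anticonservative when the accuracy comes from the training sample.
#'
#' @param emp_accuracy Empirical accuracy.
#' @param n Sample size the accuracy was measured on (total subjects in the
#'   comparison).
#' @param alpha Significance level (default 0.05, i.e. 0.95 confidence).
#' @param bound `"vapnik"` (default) or `"hoeffding"`.
#' @return Worst-case accuracy, with the bound family as attribute `bound`.
#' @export
worst_case_accuracy <- function(emp_accuracy, n, alpha = 0.05,
                                bound = c("vapnik", "hoeffding")) {
  bound <- match.arg(bound)
  stopifnot(alpha > 0, alpha < 1, n >= 2)
  delta <- switch(bound,
    hoeffding = sqrt(log(2 / alpha) / (2 * n)),
    vapnik = {
      h <- 2
      sqrt((h * (log(2 * n / h) + 1) + log(4 / alpha)) / n)
    })
  out <- pmax(emp_accuracy - delta, 0)
  attr(out, "bound") <- bound
  out
}

#' z-test of a worst-case accuracy against chance
#'
#' Standardizes the worst-case accuracy against the chance level 0.5 with
#' binomial variance 0.25/n and tests one-sided (only better-than-chance
#' counts as evidence of a group difference).
#'
#' @param worst_accuracy Worst-case accuracy from [worst_case_accuracy()].
#' @param n Sample size.
#' @param alpha One-sided significance level.
#' @return List with `z_stat` and `significant`.
#' @export
region_significance <- function(worst_accuracy, n, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1, n >= 2)
  z <- (as.numeric(worst_accuracy) - 0.5) / sqrt(0.25 / n)
  list(z_stat = z, significant = z > qnorm(1 - alpha))
}

# Core per-region loop on a subjects-x-maskvoxels matrix.
# region_cols: list of column-index vectors per region (atlas_region_columns).
# y: +1/-1 labels. Returns tibble of per-region results.
sam_regions_matrix <- function(gm, region_cols, y, fes = fes_config(),
                               alpha = 0.05, bound = "vapnik", cost = 1) {
  n <- nrow(gm)
  res <- lapply(region_cols, function(cols) {
    X <- gm[, cols, drop = FALSE]
    sel <- select_voxels(X, y, k = fes$k_voxels)
    sc <- pls_extract(X[, sel, drop = FALSE], y,
                      n_components = min(fes$pls_components, length(sel)))
    emp <- fit_svm_resub(sc, y, cost = cost)
    worst <- worst_case_accuracy(emp, n, alpha = alpha, bound = bound)
    sig <- region_significance(worst, n, alpha = alpha)
    c(emp_accuracy = emp, worst_accuracy = as.numeric(worst),
      z_stat = sig$z_stat, significant = as.numeric(sig$significant))
  })
  m <- do.call(rbind, res)
  tibble::tibble(
    region_id = as.integer(names(region_cols)),
    emp_accuracy = unname(m[, "emp_accuracy"]),
    worst_accuracy = unname(m[, "worst_accuracy"]),
    z_stat = unname(m[, "z_stat"]),
    significant = unname(m[, "significant"] > 0)
  )
}

#' Region-level agnostic mapping over an atlas
#'
#' For every atlas region: select the top-k voxels by |t|, extract PLS
#' scores, train a linear SVM and take its resubstitution accuracy, correct
#' it to the worst case with a concentration bound, and z-test the corrected
#' accuracy against chance. QC-excluded subjects are dropped first.
#'
#' @param cohort A `gm_cohort` (optionally after [apply_qc()]).
#' @param atlas The `gm_atlas` the cohort was generated on.
#' @param fes An [fes_config()].
#' @param alpha Significance level for both the bound and the z-test.
#' @param bound Concentration bound family, see [worst_case_accuracy()].
#' @param subjects Optional subject ids restricting the comparison.
#' @return A `sam_map` tibble: one row per region with `region_id`, `name`,
#'   `n_voxels`, `emp_accuracy`, `worst_accuracy`, `z_stat`, `significant`;
#'   attributes record `n`, `alpha`, `bound` and the FES configuration.
#' @export
sam_map <- function(cohort, atlas, fes = fes_config(), alpha = 0.05,
                    bound = c("vapnik", "hoeffding"), subjects = NULL) {
  stopifnot(inherits(cohort, "gm_cohort"), inherits(atlas, "gm_atlas"))
  bound <- match.arg(bound)
  keep <- !cohort$cohort$qc_excluded
  if (!is.null(subjects)) keep <- keep & cohort$cohort$subject_id %in% subjects
  tab <- cohort$cohort[keep, ]
  y <- ifelse(tab$group == "ASC", 1, -1)
  if (length(unique(tab$group)) != 2L) stop("need both groups after QC/subset")
  gm <- cohort$gm[keep, , drop = FALSE]
  out <- sam_regions_matrix(gm, atlas_region_columns(atlas), y,
                            fes = fes, alpha = alpha, bound = bound)
  out <- dplyr::left_join(atlas$regions, out, by = "region_id")
  attr(out, "n") <- nrow(tab)
  attr(out, "alpha") <- alpha
  attr(out, "bound") <- bound
  attr(out, "fes") <- fes
  class(out) <- c("sam_map", class(out))
  out
}

#' @export
tidy.sam_map <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.sam_map <- function(x, ...) {
  tibble::tibble(
    n_regions = nrow(x),
    n_significant = sum(x$significant),
    n = attr(x, "n"),
    alpha = attr(x, "alpha"),
    bound = attr(x, "bound"),
    max_worst_accuracy = max(x$worst_accuracy)
  )
}

#' @export
autoplot.sam_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$n_voxels, y = .data$worst_accuracy,
                               colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "region size (voxels)", y = "worst-case accuracy",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Paint per-region values into a volume (e.g. a z-statistic map)
#'
#' @param atlas A `gm_atlas`.
#' @param values Numeric vector named by region id, or a data frame with
#'   `region_id` and a value column (its first non-id numeric column).
#' @return 3-D numeric array with each region's voxels set to its value.
#' @export
region_map_volume <- function(atlas, values) {
  stopifnot(inherits(atlas, "gm_atlas"))
  if (is.data.frame(values)) {
    vcol <- setdiff(names(values)[vapply(values, is.numeric, logical(1))], "region_id")[1]
    v <- stats::setNames(values[[vcol]], values$region_id)
  } else v <- values
  vol <- array(0, dim = dim(atlas$labels))
  lab <- atlas$labels[atlas$mask_index]
  vol[atlas$mask_index] <- unname(v[as.character(lab)])
  vol[is.na(vol)] <- 0
  vol
}
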