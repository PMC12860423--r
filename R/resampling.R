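#' Configuration for a resampling experiment
#'
#' Defaults follow the reference experimental design: 1000 outer resampling
#' iterations, 1000 inner label permutations for the permutation p-value,
#' significance level 0.05, case-control comparison over all sites pooled.
#' Subsample sizes default to the 1/5 rule over all centers (about 100 per
#' group for a ~500-per-group cohort) and the 1/3-per-group rule within a
#' single center. Tests and examples scale `n_iterations` / `n_permutations`
#' down; the defaults are the study design, not a runtime recommendation.
#'
#' @param n_iterations Outer subsampling iterations (R).
#' @param n_permutations Inner label permutations for the p-value (M);
#'   0 skips the p-value stage.
#' @param alpha Per-iteration significance level.
#' @param comparison `"HC_vs_ASC"` (case-control) or `"HC_vs_HC"` (null).
#' @param scope `"all_centers"` (pooled) or `"per_center"`.
#' @param n_per_group Subjects drawn per group each iteration; `NULL` applies
#'   the 1/5 (all centers) or 1/3 (per center) rule.
#' @param seed Master seed; every random stream in the experiment derives
#'   from it.
#' @param apply_qc Drop QC-excluded subjects before sampling.
#' @param fes Region-classifier settings ([fes_config()]), SAM arm.
#' @param bound Concentration bound family, SAM arm.
#' @param fwhm_mm,cluster_forming_p,n_null,connectivity Parametric-arm
#'   settings (see [cluster_fwe()]).
#' @param p_per_iteration Also compute an Eq.-style permutation p-value in
#'   every outer iteration and report its mean (slow; default `FALSE`).
#' @return A `resampling_config` list.
#' @export
resampling_config <- function(n_iterations = 1000L, n_permutations = 1000L,
                              alpha = 0.05,
                              comparison = c("HC_vs_ASC", "HC_vs_HC"),
                              scope = c("all_centers", "per_center"),
                              n_per_group = NULL, seed = 1L, apply_qc = TRUE,
                              fes = fes_config(), bound = "vapnik",
                              fwhm_mm = 8, cluster_forming_p = 0.001,
                              n_null = 199L, connectivity = 26,
                              p_per_iteration = FALSE) {
  comparison <- match.arg(comparison)
  scope <- match.arg(scope)
  stopifnot(n_iterations >= 1, n_permutations >= 0, alpha > 0, alpha < 1)
  if (inherits(fes, "fes_config")) fes <- unclass(fes)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_permutations = as.integer(n_permutations),
                 alpha = alpha, comparison = comparison, scope = scope,
                 n_per_group = n_per_group, seed = as.integer(seed),
                 apply_qc = apply_qc, fes = fes, bound = bound,
                 fwhm_mm = fwhm_mm, cluster_forming_p = cluster_forming_p,
                 n_null = as.integer(n_null), connectivity = connectivity,
                 p_per_iteration = p_per_iteration),
            class = "resampling_config")
}

#' Draw one subsample for a comparison
#'
#' Case-control (`HC_vs_ASC`) draws a subsample from each group; the null
#' design (`HC_vs_HC`) draws two *disjoint* control subsets. Sampling is
#' without replacement. When `n_per_group` is `NULL` the fraction rules
#' apply group-wise: pooled over all centers, 1/5 of each group (about 100
#' per group for a ~500-per-group cohort); restricted to one `site`, 1/3 of
#' each of the site's groups — so a 100 HC / 75 ASC site yields 33 HC and
#' 25 ASC per draw. QC-excluded subjects never enter the pool.
#'
#' @param cohort Cohort tibble or `gm_cohort`.
#' @param comparison `"HC_vs_ASC"` or `"HC_vs_HC"`.
#' @param n_per_group Subsample size: scalar (both groups) or length 2
#'   (group A = HC, group B = ASC); `NULL` applies the 1/5 (pooled) or 1/3
#'   (per-center) group-wise rule.
#' @param site Optional site name restricting the pool.
#' @return List with `a` and `b`, character vectors of subject ids (group A
#'   is HC; group B is ASC or the second HC subset).
#' @export
draw_subsample <- function(cohort, comparison = c("HC_vs_ASC", "HC_vs_HC"),
                           n_per_group = NULL, site = NULL) {
  comparison <- match.arg(comparison)
  if (inherits(cohort, "gm_cohort")) cohort <- cohort$cohort
  pool <- cohort[!cohort$qc_excluded, ]
  where <- if (is.null(site)) "pooled cohort" else paste0("site ", site)
  if (!is.null(site)) pool <- pool[pool$site == site, ]
  hc <- pool$subject_id[pool$group == "HC"]
  asc <- pool$subject_id[pool$group == "ASC"]
  if (is.null(n_per_group)) {
    frac <- if (is.null(site)) 5 else 3
    n_per_group <- if (comparison == "HC_vs_ASC")
      c(floor(length(hc) / frac), floor(length(asc) / frac))
    else floor(length(hc) / frac)
  }
  n_per_group <- as.integer(n_per_group)
  n_a <- n_per_group[1L]
  n_b <- if (length(n_per_group) > 1L) n_per_group[2L] else n_per_group[1L]
  if (n_a < 2L || n_b < 2L)
    stop("insufficient subjects at ", where, ": subsample sizes ", n_a, "/", n_b)
  if (comparison == "HC_vs_ASC") {
    if (length(hc) < n_a || length(asc) < n_b)
      stop("insufficient subjects at ", where, " for HC_vs_ASC (need ",
           n_a, " HC / ", n_b, " ASC, have ", length(hc), " HC / ",
           length(asc), " ASC)")
    list(a = sample(hc, n_a), b = sample(asc, n_b))
  } else {
    if (length(hc) < n_a + n_b)
      stop("insufficient subjects at ", where, " for HC_vs_HC (need ",
           n_a + n_b, " HC, have ", length(hc), ")")
    pick <- sample(hc, n_a + n_b)
    list(a = pick[seq_len(n_a)], b = pick[n_a + seq_len(n_b)])
  }
}

#' Permutation p-value from an observed statistic and its null draws
#'
#' `p = (#\{T_null >= T_obs\} + 1) / (M + 1)`; ties count toward the
#' numerator and the +1 includes the observed statistic itself, so the
#' smallest attainable p is `1/(M+1)` and the test is valid at any M.
#'
#' @param t_obs Observed statistic.
#' @param t_null Numeric vector of M permuted statistics.
#' @return p-value in `[1/(M+1), 1]`.
#' @export
permutation_pvalue <- function(t_obs, t_null) {
  if (length(t_null) == 0L) stop("empty null statistic list")
  (sum(t_null >= t_obs) + 1) / (length(t_null) + 1)
}

# One arm evaluation on a drawn subsample.
# Returns list(flag = logical per region, stat = numeric per region).
eval_arm <- function(arm, cohort, atlas, ids_a, ids_b, labels = NULL, config) {
  ids <- c(ids_a, ids_b)
  y <- if (is.null(labels)) rep(c(-1, 1), c(length(ids_a), length(ids_b))) else labels
  region_cols <- attr(cohort, "region_cols")
  if (arm == "ttest") {
    rm <- attr(cohort, "region_means")[ids, , drop = FALSE]
    tv <- col_tstat(rm, y, var_equal = TRUE)
    p <- 2 * stats::pt(-abs(tv), df = length(y) - 2L)
    return(list(flag = p <= config$alpha, stat = abs(tv)))
  }
  sub <- cohort_subset(cohort, ids)
  if (arm == "sam") {
    res <- sam_regions_matrix(sub$gm, region_cols, y,
                              fes = do.call(fes_config, config$fes),
                              alpha = config$alpha, bound = config$bound)
    list(flag = res$significant, stat = res$worst_accuracy)
  } else {
    res <- cluster_fwe(sub$gm, groups = y, contrast = "HC<ASC",
                       cluster_forming_p = config$cluster_forming_p,
                       alpha = config$alpha, n_null = config$n_null,
                       connectivity = config$connectivity,
                       dims = sub$dim, mask_index = sub$mask_index)
    n_regions <- length(region_cols)
    flag <- logical(n_regions)
    stat <- numeric(n_regions)
    if (nrow(res$clusters)) {
      labs <- attr(cohort, "atlas_labels")
      for (ci in seq_along(res$voxels)) {
        regs <- unique(labs[res$voxels[[ci]]])
        regs <- regs[regs > 0]
        stat[regs] <- pmax(stat[regs], res$clusters$size[ci])
        if (res$clusters$significant[ci]) flag[regs] <- TRUE
      }
    }
    list(flag = flag, stat = stat)
  }
}

#' Run a full resampling experiment for one arm and design
#'
#' The outer loop repeats `n_iterations` times: draw a subsample
#' ([draw_subsample()]), run the mapping arm on it, and record which regions
#' it declares significant (SAM: worst-case-bound z-test; parametric arm: at
#' least one significant-cluster voxel inside the region). The per-region
#' detection frequency over iterations is the probability of detection (PD)
#' under the case-control design, or the false-positive (FP) rate under the
#' control-control design, where every detection is false by construction.
#'
#' Separately, an inner loop computes a permutation p-value per region: one
#' label-faithful draw gives the observed statistic (SAM: worst-case
#' accuracy; parametric arm: largest cluster touching the region) and
#' `n_permutations` label shuffles of the same draw give its null.
#' Iterations that fail (e.g. a site too small to subsample) are counted and
#' reported, not fatal.
#'
#' For the parametric arm, smoothing is applied once per subject up front
#' (it does not depend on labels).
#'
#' @param cohort A `gm_cohort`.
#' @param atlas The matching `gm_atlas`.
#' @param arm `"sam"`, `"spm"`, or `"ttest"` — the last a calibrated
#'   two-sample t-test on region-mean GM (exact level `alpha` per region
#'   under the null), the yardstick the two mapping arms are compared
#'   against: with 1000 null iterations at level 0.05 it flags each region
#'   about 50 times.
#' @param config A [resampling_config()].
#' @param site Site name when `config$scope == "per_center"`.
#' @return A `resampling_summary` tibble: per region `region_id`, `name`,
#'   `n_voxels`, `flag_count`, `frequency`, `t_obs`, `p_value` (and
#'   `p_value_mean` when `config$p_per_iteration`); attributes carry the
#'   config, arm, comparison, iteration/failure counts.
#' @export
run_experiment <- function(cohort, atlas, arm = c("sam", "spm", "ttest"),
                           config = resampling_config(), site = NULL) {
  arm <- match.arg(arm)
  stopifnot(inherits(cohort, "gm_cohort"), inherits(atlas, "gm_atlas"))
  if (config$scope == "per_center" && is.null(site))
    stop("per_center scope needs a site")
  if (!config$apply_qc) cohort$cohort$qc_excluded <- FALSE

  if (arm == "spm") cohort <- smooth_cohort(cohort, fwhm_mm = config$fwhm_mm)
  attr(cohort, "region_cols") <- atlas_region_columns(atlas)
  attr(cohort, "atlas_labels") <- atlas$labels
  if (arm == "ttest") {
    rc <- attr(cohort, "region_cols")
    rmeans <- vapply(rc, function(cols)
      rowMeans(cohort$gm[, cols, drop = FALSE]), numeric(nrow(cohort$gm)))
    rownames(rmeans) <- cohort$cohort$subject_id
    attr(cohort, "region_means") <- rmeans
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(config$seed, paste0(arm, config$comparison, "outer")))

  n_regions <- nrow(atlas$regions)
  flags <- integer(n_regions)
  p_iter <- if (isTRUE(config$p_per_iteration)) numeric(n_regions) else NULL
  n_fail <- 0L
  for (r in seq_len(config$n_iterations)) {
    res <- tryCatch({
      dr <- draw_subsample(cohort, config$comparison, config$n_per_group, site)
      eval_arm(arm, cohort, atlas, dr$a, dr$b, config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) { n_fail <- n_fail + 1L; next }
    flags <- flags + res$flag
    if (!is.null(p_iter)) {
      stat_null <- replicate(config$n_permutations, {
        dr2 <- draw_subsample(cohort, config$comparison, config$n_per_group, site)
        ids <- c(dr2$a, dr2$b)
        yp <- sample(rep(c(-1, 1), c(length(dr2$a), length(dr2$b))))
        eval_arm(arm, cohort, atlas, dr2$a, dr2$b, labels = yp, config = config)$stat
      })
      p_iter <- p_iter + vapply(seq_len(n_regions), function(i)
        permutation_pvalue(res$stat[i], stat_null[i, ]), numeric(1))
    }
  }
  n_ok <- config$n_iterations - n_fail

  t_obs <- rep(NA_real_, n_regions)
  p_value <- rep(NA_real_, n_regions)
  if (config$n_permutations > 0L) {
    set.seed(derive_seed(config$seed, paste0(arm, config$comparison, "inner")))
    obs <- tryCatch({
      dr <- draw_subsample(cohort, config$comparison, config$n_per_group, site)
      list(dr = dr, res = eval_arm(arm, cohort, atlas, dr$a, dr$b, config = config))
    }, error = function(e) NULL)
    if (!is.null(obs)) {
      t_obs <- obs$res$stat
      y0 <- rep(c(-1, 1), c(length(obs$dr$a), length(obs$dr$b)))
      null_mat <- matrix(NA_real_, n_regions, config$n_permutations)
      for (m in seq_len(config$n_permutations)) {
        yp <- sample(y0)
        null_mat[, m] <- eval_arm(arm, cohort, atlas, obs$dr$a, obs$dr$b,
                                  labels = yp, config = config)$stat
      }
      p_value <- vapply(seq_len(n_regions), function(i)
        permutation_pvalue(t_obs[i], null_mat[i, ]), numeric(1))
    }
  }

  out <- atlas$regions
  out$flag_count <- unname(flags)
  out$frequency <- unname(flags) / config$n_iterations
  out$t_obs <- t_obs
  out$p_value <- p_value
  if (!is.null(p_iter)) out$p_value_mean <- p_iter / max(n_ok, 1L)
  attr(out, "arm") <- arm
  attr(out, "comparison") <- config$comparison
  attr(out, "config") <- config
  attr(out, "site") <- site
  attr(out, "n_iterations") <- config$n_iterations
  attr(out, "n_failures") <- n_fail
  class(out) <- c("resampling_summary", class(out))
  out
}

#' @export
tidy.resampling_summary <- function(x, ...) tibble::as_tibble(unclass(x))

#' @export
glance.resampling_summary <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    arm = attr(x, "arm"), comparison = attr(x, "comparison"),
    n_iterations = attr(x, "n_iterations"),
    n_failures = attr(x, "n_failures"),
    mean_flag_count = mean(x$flag_count),
    max_frequency = max(x$frequency),
    alpha = cfg$alpha
  )
}

#' Region-size versus detection-frequency profile
#'
#' Joins per-region voxel counts with PD (case-control summary) and FP rate
#' (control-control summary), sorted by region size — the data behind the
#' size-versus-power and size-versus-false-positive scatter analyses.
#'
#' @param pd_summary `resampling_summary` under the `HC_vs_ASC` design (or
#'   `NULL`).
#' @param fp_summary `resampling_summary` under the `HC_vs_HC` design (or
#'   `NULL`).
#' @param atlas The `gm_atlas` (used when only one summary is given).
#' @return Tibble `(region_id, name, n_voxels, pd, fp)` sorted by
#'   `n_voxels`.
#' @export
size_power_profile <- function(pd_summary = NULL, fp_summary = NULL,
                               atlas = NULL) {
  base <- if (!is.null(pd_summary)) pd_summary[, c("region_id", "name", "n_voxels")]
    else if (!is.null(fp_summary)) fp_summary[, c("region_id", "name", "n_voxels")]
    else if (!is.null(atlas)) atlas$regions
    else stop("need at least one summary or an atlas")
  out <- tibble::as_tibble(as.data.frame(base))
  out$pd <- if (!is.null(pd_summary))
    pd_summary$frequency[match(out$region_id, pd_summary$region_id)] else NA_real_
  out$fp <- if (!is.null(fp_summary))
    fp_summary$frequency[match(out$region_id, fp_summary$region_id)] else NA_real_
  dplyr::arrange(out, .data$n_voxels)
}

#' @export
autoplot.resampling_summary <- function(object, ...) {
  lab <- if (attr(object, "comparison") == "HC_vs_ASC")
    "probability of detection" else "false-positive rate"
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_voxels, y = .data$frequency)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = cfg$alpha, linetype = 2, colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "region size (voxels)", y = lab,
                  title = sprintf("%s arm, %s design", toupper(attr(object, "arm")),
                                  attr(object, "comparison"))) +
    ggplot2::theme_minimal()
}
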