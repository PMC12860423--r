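# A Table-1-like cohort table (no volumes needed for draw tests).
abide_like_table <- function() {
  sizes <- list(NYU = c(100, 75), UM_1 = c(54, 53), USM = c(26, 44),
                UCLA_1 = c(30, 41), PITT = c(26, 30), YALE = c(28, 28),
                TRINITY = c(25, 22), KKI = c(28, 20), MAX_MUN = c(28, 24),
                LEUVEN_2 = c(19, 15), OLIN = c(14, 20), SDSU = c(22, 14),
                STANFORD = c(17, 18), CALTECH = c(18, 19), CMU = c(13, 14),
                LEUVEN_1 = c(15, 14), OHSU = c(15, 13), SBL = c(15, 15),
                UCLA_2 = c(13, 13), UM_2 = c(21, 13))
  rows <- lapply(names(sizes), function(s)
    tibble::tibble(site = s,
                   group = rep(c("HC", "ASC"), sizes[[s]])))
  tab <- dplyr::bind_rows(rows)
  tab$subject_id <- sprintf("S%04d", seq_len(nrow(tab)))
  tab$qc_excluded <- FALSE
  tab
}

test_that("the null design draws disjoint control subsets", {
  tab <- abide_like_table()
  set.seed(1)
  for (i in 1:20) {
    dr <- draw_subsample(tab, "HC_vs_HC", n_per_group = 50)
    expect_length(intersect(dr$a, dr$b), 0L)
    expect_length(dr$a, 50L)
    expect_true(all(tab$group[match(c(dr$a, dr$b), tab$subject_id)] == "HC"))
  }
})

test_that("the pooled 1/5 rule approximates 100 per group on an ABIDE-like table", {
  tab <- abide_like_table()  # 527 HC / 505 ASC
  set.seed(2)
  dr <- draw_subsample(tab, "HC_vs_ASC")
  expect_equal(length(dr$a), floor(527 / 5))
  expect_equal(length(dr$b), floor(505 / 5))
  expect_lt(abs(length(dr$b) - 100) / 100, 0.05)
})

test_that("the per-center 1/3 rule gives 33 HC and 25 ASC at a 100/75 site", {
  tab <- abide_like_table()
  set.seed(3)
  dr <- draw_subsample(tab, "HC_vs_ASC", site = "NYU")
  expect_length(dr$a, 33L)
  expect_length(dr$b, 25L)
  expect_true(all(tab$site[match(c(dr$a, dr$b), tab$subject_id)] == "NYU"))
})

test_that("insufficient pools raise errors naming the site", {
  tab <- abide_like_table()
  expect_error(draw_subsample(tab, "HC_vs_ASC", n_per_group = 50, site = "CMU"),
               "CMU")
  expect_error(draw_subsample(tab, "HC_vs_ASC", site = "NOWHERE"), "NOWHERE")
  expect_error(draw_subsample(tab, "HC_vs_HC", n_per_group = 300), "insufficient")
})

test_that("permutation p-values follow the add-one counting rule", {
  expect_equal(permutation_pvalue(0.9, seq(0.1, 1, length.out = 10) * 0.8), 1 / 11)
  expect_equal(permutation_pvalue(0.05, seq(0.1, 1, length.out = 10)), 1)
  # ties count toward the numerator
  expect_equal(permutation_pvalue(0.65, c(0.5, 0.6, 0.7, 0.8)), 3 / 5)
  expect_equal(permutation_pvalue(0.7, c(0.5, 0.6, 0.7, 0.8)), 3 / 5)
  expect_error(permutation_pvalue(1, numeric(0)), "empty")
})

test_that("permutation p-values are super-uniform under the null", {
  set.seed(11)
  p <- vapply(1:500, function(i)
    permutation_pvalue(rnorm(1), rnorm(39)), numeric(1))
  for (u in c(0.01, 0.05, 0.1))
    expect_lte(mean(p <= u), u + 2 * sqrt(u * (1 - u) / 500))
})

test_that("a single iteration gives 0/1 frequencies and runs reproducibly", {
  atl <- tiny_atlas(n_regions = 5, seed = 14)
  coh <- generate_cohort(atl, list(A = c(20, 20)), seed = 15)
  cfg <- resampling_config(n_iterations = 1, n_permutations = 5,
                           n_per_group = 10, seed = 30)
  s1 <- run_experiment(coh, atl, "ttest", cfg)
  expect_true(all(s1$frequency %in% c(0, 1)))
  expect_true(all(s1$p_value >= 1 / 6 & s1$p_value <= 1))
  s2 <- run_experiment(coh, atl, "ttest", cfg)
  expect_identical(tidy(s1), tidy(s2))
})

test_that("per-iteration failures are counted, not fatal", {
  atl <- tiny_atlas(n_regions = 3, seed = 16)
  coh <- generate_cohort(atl, list(TINY = c(4, 3), BIG = c(20, 20)), seed = 17)
  cfg <- resampling_config(n_iterations = 10, n_permutations = 0,
                           scope = "per_center", seed = 3)
  s <- run_experiment(coh, atl, "ttest", cfg, site = "TINY")
  expect_equal(attr(s, "n_failures"), 10L)
  expect_true(all(s$flag_count == 0))
})

test_that("null PD (case-control) and FP (control-control) estimands coincide", {
  atl <- tiny_atlas(n_regions = 8, seed = 18)
  coh <- generate_cohort(atl, list(A = c(60, 60)), effect_spec(), seed = 19)
  cfg <- function(cmp, seed) resampling_config(
    n_iterations = 200, n_permutations = 0, comparison = cmp,
    n_per_group = 20, seed = seed)
  s_pd <- run_experiment(coh, atl, "ttest", cfg("HC_vs_ASC", 41))
  s_fp <- run_experiment(coh, atl, "ttest", cfg("HC_vs_HC", 42))
  d <- mean(s_pd$frequency) - mean(s_fp$frequency)
  mc_se <- sqrt(2 * 0.05 * 0.95 / 200)
  expect_lt(abs(d), 3 * mc_se)
  # and neither exceeds the binomial null band, per region
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / 200)
  expect_true(all(s_fp$frequency <= bound))
})

test_that("size-power profiles join regions completely and sort by size", {
  atl <- tiny_atlas(n_regions = 6, seed = 20)
  coh <- generate_cohort(atl, list(A = c(30, 30)), seed = 21)
  cfg <- resampling_config(n_iterations = 20, n_permutations = 0,
                           n_per_group = 15, seed = 1)
  s_pd <- run_experiment(coh, atl, "ttest", cfg)
  prof <- size_power_profile(pd_summary = s_pd)
  expect_equal(nrow(prof), 6L)
  expect_true(!is.unsorted(prof$n_voxels))
  expect_true(all(is.na(prof$fp)))
  prof2 <- size_power_profile(pd_summary = s_pd, fp_summary = s_pd)
  expect_equal(prof2$pd, prof2$fp)
})

test_that("detection probability grows with region size under a uniform effect", {
  atl <- generate_atlas(c(40, 48, 40), n_regions = 116, seed = 7)
  # a small per-voxel d so region-mean power varies across sizes instead of
  # saturating (the region-mean effect scales with sqrt(region size))
  sp <- effect_spec(effect_regions = atl$regions$region_id, effect_size_d = 0.03)
  coh <- generate_cohort(atl, list(A = c(60, 60)), sp, seed = 23)
  cfg <- resampling_config(n_iterations = 200, n_permutations = 0,
                           n_per_group = 30, seed = 9)
  s <- run_experiment(coh, atl, "ttest", cfg)
  prof <- size_power_profile(pd_summary = s)
  rho <- cor(prof$n_voxels, prof$pd, method = "spearman")
  expect_gt(rho, 0)
})

test_that("configs round-trip through YAML", {
  cfg <- resampling_config(n_iterations = 42, comparison = "HC_vs_HC",
                           n_per_group = 12, seed = 99, bound = "hoeffding")
  path <- tempfile(fileext = ".yaml")
  write_config_yaml(cfg, path)
  back <- read_config_yaml(path)
  expect_equal(back$n_iterations, 42L)
  expect_equal(back$comparison, "HC_vs_HC")
  expect_equal(back$seed, 99L)
  expect_equal(back$bound, "hoeffding")
})
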