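test_that("voxel selection returns all indices when the region is small", {
  set.seed(1)
  X <- matrix(rnorm(20 * 30), nrow = 20)
  y <- rep(c(-1, 1), each = 10)
  expect_equal(sort(select_voxels(X, y, k = 50)), 1:30)
  X2 <- matrix(rnorm(20 * 80), nrow = 20)
  expect_length(select_voxels(X2, y, k = 50), 50L)
})

test_that("voxel ranking matches a brute-force per-voxel Welch t", {
  # voxel 3 carries a pure group shift; the rest are pure noise
  X <- matrix(c(
    0.10, 0.21, 0.52, 0.30, 0.41,
    0.12, 0.19, 0.55, 0.28, 0.44,
    0.09, 0.22, 0.50, 0.33, 0.40,
    0.11, 0.20, 0.95, 0.31, 0.43,
    0.13, 0.18, 0.93, 0.29, 0.42,
    0.10, 0.23, 0.97, 0.32, 0.39
  ), nrow = 6, byrow = TRUE)
  y <- c(-1, -1, -1, 1, 1, 1)
  sel <- select_voxels(X, y, k = 5)
  expect_equal(sel[1], 3L)
  brute <- abs(welch_t_by_ttest(X, y))
  expect_equal(sel, order(-brute, seq_along(brute)))
})

test_that("degenerate groups error in voxel selection", {
  X <- matrix(rnorm(12), nrow = 3)
  expect_error(select_voxels(X, c(-1, 1, 1), k = 2), "degenerate")
})

test_that("single-feature PLS scores are the centered feature up to sign", {
  set.seed(3)
  x <- rnorm(10)
  y <- rep(c(-1, 1), 5)
  sc <- pls_extract(matrix(x, ncol = 1), y, 1)
  xc <- x - mean(x)
  expect_true(max(abs(sc - xc)) < 1e-10 || max(abs(sc + xc)) < 1e-10)
})

test_that("first PLS weights equal the normalized cross-covariance", {
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 4, 3), ncol = 2)
  y <- c(-1, -1, 1, 1)
  sc <- pls_extract(X, y, 1)
  Xc <- sweep(X, 2, colMeans(X))
  w_oracle <- drop(crossprod(Xc, y))
  w_oracle <- w_oracle / sqrt(sum(w_oracle^2))
  expect_equal(as.numeric(attr(sc, "weights")), w_oracle, tolerance = 1e-10)
  expect_equal(as.numeric(sc), as.numeric(Xc %*% w_oracle), tolerance = 1e-10)
})

test_that("zero-variance features error in PLS", {
  X <- matrix(1, 6, 3)
  expect_error(pls_extract(X, rep(c(-1, 1), 3), 1), "degenerate")
})

test_that("SVM resubstitution accuracy is bounded by the best 1-D threshold", {
  # separable case is classified perfectly
  expect_equal(fit_svm_resub(c(-2, -1, 1, 2), c(-1, -1, 1, 1)), 1)
  expect_error(fit_svm_resub(c(1, 2, 3), c(1, 1, 1)), "both classes")
  # the exact upper bound: a linear rule in 1-D is a threshold
  set.seed(21)
  for (i in 1:20) {
    n <- sample(c(10, 30, 60), 1)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    x <- rnorm(n) + y * runif(1, 0, 2)
    expect_lte(fit_svm_resub(x, y), best_threshold_accuracy(x, y) + 1e-12)
  }
  # with clear separation at n = 100 the soft margin tracks the optimum
  set.seed(22)
  for (i in 1:10) {
    y <- sample(c(-1, 1), 100, replace = TRUE)
    x <- rnorm(100) + y * 1.5
    expect_gte(fit_svm_resub(x, y), best_threshold_accuracy(x, y) - 0.06)
  }
})

test_that("permuted labels give chance-level resubstitution accuracy", {
  set.seed(5)
  x <- rnorm(400)
  y <- sample(rep(c(-1, 1), 200))
  expect_lt(abs(fit_svm_resub(x, y) - 0.5), 0.08)
})

test_that("worst-case bound evaluates its closed forms and limits", {
  # hand evaluation of the Hoeffding form
  w <- worst_case_accuracy(1.0, 50, alpha = 0.05, bound = "hoeffding")
  expect_equal(as.numeric(w), 1 - sqrt(log(2 / 0.05) / (2 * 50)), tolerance = 1e-12)
  # hand evaluation of the Vapnik form (h = 2)
  wv <- worst_case_accuracy(0.9, 200, alpha = 0.05, bound = "vapnik")
  expect_equal(as.numeric(wv),
               0.9 - sqrt((2 * (log(200) + 1) + log(4 / 0.05)) / 200),
               tolerance = 1e-12)
  # delta < 0.01 once n exceeds ~19000 (alpha = 0.05, Hoeffding)
  w19k <- worst_case_accuracy(0.7, 19000, bound = "hoeffding")
  expect_lt(0.7 - as.numeric(w19k), 0.01)
  # floor at zero
  expect_equal(as.numeric(worst_case_accuracy(0.01, 10, bound = "hoeffding")), 0)
})

test_that("the bound shrinks with n and grows as alpha decreases", {
  for (b in c("hoeffding", "vapnik")) {
    d_n <- vapply(c(20, 50, 100, 500, 2000), function(n)
      0.9 - as.numeric(worst_case_accuracy(0.9, n, 0.05, b)), numeric(1))
    expect_true(all(diff(d_n) < 0))
    d_a <- vapply(c(0.2, 0.1, 0.05, 0.01), function(a)
      0.9 - as.numeric(worst_case_accuracy(0.9, 100, a, b)), numeric(1))
    expect_true(all(diff(d_a) > 0))
    expect_true(all(
      as.numeric(worst_case_accuracy(c(0.3, 0.7, 1), 40, 0.05, b)) <= c(0.3, 0.7, 1)))
  }
})

test_that("region z-test matches hand evaluation and is one-sided", {
  r0 <- region_significance(0.5, 100)
  expect_equal(r0$z_stat, 0)
  expect_false(r0$significant)
  r1 <- region_significance(0.6, 100, alpha = 0.05)
  expect_equal(r1$z_stat, 2.0)
  expect_true(r1$significant)   # 2.0 > 1.645
  for (w in c(0.2, 0.4, 0.5))
    expect_false(region_significance(w, 500)$significant)
})

test_that("sam_map returns one row per region with coherent fields", {
  atl <- generate_atlas(c(40, 48, 40), n_regions = 116, seed = 7)
  coh <- generate_cohort(atl, list(A = c(30, 30)),
                         effect_spec(effect_regions = 1L, effect_size_d = 1.5),
                         seed = 3)
  sm <- sam_map(coh, atl)
  expect_s3_class(sm, "sam_map")
  expect_equal(nrow(sm), 116L)
  expect_true(all(sm$worst_accuracy <= sm$emp_accuracy + 1e-12))
  expect_true(all(sm$emp_accuracy >= 0 & sm$emp_accuracy <= 1))
  expect_identical(sm$significant, sm$z_stat > qnorm(0.95))
  g <- glance(sm)
  expect_equal(g$n, 60L)
  expect_equal(nrow(tidy(sm)), 116L)
})

test_that("label-swap symmetry leaves SAM results unchanged", {
  atl <- tiny_atlas(n_regions = 6, seed = 9)
  coh <- generate_cohort(atl, list(A = c(15, 15)),
                         effect_spec(effect_regions = 2L, effect_size_d = 1.2),
                         seed = 4)
  swapped <- coh
  swapped$cohort$group <- ifelse(coh$cohort$group == "HC", "ASC", "HC")
  s1 <- sam_map(coh, atl)
  s2 <- sam_map(swapped, atl)
  expect_equal(s1$emp_accuracy, s2$emp_accuracy, tolerance = 1e-10)
  expect_identical(s1$significant, s2$significant)
})

test_that("a strongly planted region dominates the SAM ranking", {
  atl <- generate_atlas(c(40, 48, 40), n_regions = 116, seed = 7)
  big <- atl$regions$region_id[which.max(atl$regions$n_voxels)]
  coh <- generate_cohort(atl, list(A = c(100, 100)),
                         effect_spec(effect_regions = big, effect_size_d = 1.5),
                         seed = 15)
  sm <- sam_map(coh, atl)
  expect_true(sm$significant[sm$region_id == big])
  expect_equal(which.max(sm$worst_accuracy), which(sm$region_id == big))
})

test_that("null cohorts produce sparse SAM flags, not saturation", {
  atl <- generate_atlas(c(40, 48, 40), n_regions = 116, seed = 7)
  rates <- vapply(1:5, function(s) {
    coh <- generate_cohort(atl, list(A = c(100, 100)), effect_spec(),
                           seed = 400 + s)
    mean(sam_map(coh, atl)$significant)
  }, numeric(1))
  # far from the saturation an uncorrected resubstitution rule would give
  expect_lt(mean(rates), 0.25)
})

test_that("region value maps paint each region constant", {
  atl <- tiny_atlas(n_regions = 4, seed = 2)
  vals <- c(`1` = 0.1, `2` = 0.5, `3` = -1, `4` = 2)
  vol <- region_map_volume(atl, vals)
  for (id in 1:4)
    expect_true(all(vol[atl$labels == id] == vals[[as.character(id)]]))
  expect_true(all(vol[atl$labels == 0] == 0))
})
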