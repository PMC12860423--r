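# Shared small fixtures, built once per test run.

tiny_atlas <- function(n_regions = 5, seed = 11) {
  generate_atlas(c(20L, 20L, 20L), n_regions = n_regions, seed = seed)
}

# Brute-force best 1-D threshold-with-orientation accuracy.
best_threshold_accuracy <- function(x, y) {
  cs <- sort(unique(x))
  cand <- c(min(x) - 1, (utils::head(cs, -1) + utils::tail(cs, -1)) / 2, max(x) + 1)
  best <- 0
  for (c0 in cand) for (o in c(1, -1))
    best <- max(best, mean((((x - c0) * o > 0) * 2 - 1) == y))
  best
}

# Brute-force Welch t per column using stats::t.test.
welch_t_by_ttest <- function(X, y) {
  vapply(seq_len(ncol(X)), function(j) {
    unname(stats::t.test(X[y > 0, j], X[y < 0, j])$statistic)
  }, numeric(1))
}
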