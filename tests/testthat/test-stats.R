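test_that("aligned ranks match the brute-force sorter, with and without ties", {
  for (seed in 1:6) {
    tb <- random_metric_table(4, 3, ties = seed %% 2 == 0, seed = seed)
    ar <- aligned_ranks(tb)
    expect_equal(unname(ar$ranks), bf_aligned_ranks(tb$values))
    # rank conservation
    kn <- ar$n * ar$k
    expect_equal(sum(ar$ranks), kn * (kn + 1) / 2)
    expect_equal(sum(ar$avg_rank) * ar$n, kn * (kn + 1) / 2)
  }
})

test_that("engineered ties receive the average of the spanned ranks", {
  # block-aligned values tie exactly across blocks
  v <- rbind(c(1, 2, 3), c(2, 3, 4))    # aligned rows identical
  ar <- aligned_ranks(metric_table(v, c("b1", "b2"), c("A", "B", "C")))
  # aligned: (-1,0,1) twice; descending ranks: 1.5,1.5 / 3.5,3.5 / 5.5,5.5
  expect_equal(unname(ar$ranks), rbind(c(5.5, 3.5, 1.5), c(5.5, 3.5, 1.5)))
})

test_that("identical treatment columns give the all-tied average (kn+1)/2", {
  v <- matrix(rep(stats::runif(12), 3), 12, 3)
  ar <- aligned_ranks(metric_table(v))
  expect_equal(unname(ar$avg_rank), rep(18.5, 3))
  om <- far_omnibus(ar)
  expect_equal(om$statistic, 0)
  expect_equal(om$p_value, 1)
})

test_that("the omnibus statistic agrees with the straight-from-formula oracle", {
  tb <- benchmark_table("accuracy")
  ar <- aligned_ranks(tb)
  om <- far_omnibus(ar)
  expect_equal(om$statistic, bf_far_statistic(ar$ranks), tolerance = 1e-9)
  expect_gt(om$statistic, 0)
  expect_lt(om$p_value, 0.05)
  # invariance under treatment relabeling
  perm <- metric_table(tb$values[, c(3, 1, 2)])
  expect_equal(far_omnibus(aligned_ranks(perm))$statistic, om$statistic,
               tolerance = 1e-9)
})

test_that("improving one treatment everywhere never worsens its rank", {
  for (seed in 1:5) {
    tb <- random_metric_table(5, 3, seed = seed)
    before <- aligned_ranks(tb)$avg_rank[2]
    v2 <- tb$values; v2[, 2] <- v2[, 2] + runif(nrow(v2), 0.5, 2)
    after <- aligned_ranks(metric_table(v2))$avg_rank[2]
    expect_lte(after, before + 1e-12)
  }
})

test_that("published accuracy rankings are reproduced from the fixtures", {
  ar <- aligned_ranks(benchmark_table("accuracy"))
  expect_equal(unname(ar$avg_rank["Traditional"]), 24.4167, tolerance = 1e-4)
  expect_equal(unname(ar$avg_rank["MD"]), 21.6667, tolerance = 1e-4)
  expect_equal(unname(ar$avg_rank["CAE"]), 9.4167, tolerance = 1e-4)
})

test_that("published AUC rankings and pairwise p-values are reproduced", {
  ar <- aligned_ranks(benchmark_table("auc"))
  expect_equal(unname(ar$avg_rank[c("CAE", "MD", "Traditional")]),
               c(7.5833, 22.0417, 25.8750), tolerance = 1e-4)
  ph <- finner_posthoc(ar)
  expect_equal(ph$control, "CAE")
  cmp <- ph$comparisons
  expect_equal(cmp$p_raw[cmp$treatment == "MD"], 0.000775, tolerance = 0.01)
  expect_equal(cmp$p_raw[cmp$treatment == "Traditional"], 0.000021,
               tolerance = 0.02)
  # the pairwise standard error at k=3, n=12 is sqrt(18.5)
  expect_equal(ph$se, sqrt(18.5), tolerance = 1e-12)
})

test_that("Finner adjustment follows the step-down closed form", {
  # k = 2: single comparison, adjusted p equals raw p exactly
  v <- rbind(c(1, 2), c(3, 5), c(2, 4), c(0, 2))
  ph <- finner_posthoc(metric_table(v))
  expect_equal(ph$comparisons$p_finner, ph$comparisons$p_raw)
  # direct formula with m = 2: (0.01, 0.04) -> (1-0.99^2, 0.04)
  raw <- c(0.01, 0.04); m <- 2
  adj <- pmin(cummax(1 - (1 - raw)^(m / seq_along(raw))), 1)
  expect_equal(adj, c(1 - 0.99^2, 0.04))
  # monotone and never below raw on random inputs
  for (seed in 1:5) {
    tb <- random_metric_table(6, 4, seed = seed)
    # rank ties for the control can occur in random tables; the warning
    # about lexicographic tie-breaking is not under test here
    cmp <- suppressWarnings(finner_posthoc(tb))$comparisons
    expect_true(all(cmp$p_finner >= cmp$p_raw - 1e-12))
    expect_true(all(diff(cmp$p_finner) >= -1e-12))
  }
})

test_that("degenerate fully-tied tables are reported as undefined", {
  v <- matrix(5, 3, 3) + 0 * diag(3)
  om <- far_omnibus(metric_table(v))
  # all aligned values are 0 in every block: columns tie completely, the
  # statistic is 0/positive-denominator -> defined and 0 here
  expect_true(om$statistic == 0 || is.na(om$statistic))
  expect_error(aligned_ranks(metric_table(matrix(1, 1, 3))), "2 blocks")
})

test_that("the full comparison report is internally consistent", {
  rep <- far_compare(benchmark_table("gm"))
  expect_s3_class(rep, "far_report")
  expect_equal(unname(rep$ranking$avg_rank[c("CAE", "MD", "Traditional")]),
               c(11.5000, 17.8333, 26.1667), tolerance = 1e-4)
  expect_equal(rep$posthoc$control, "CAE")
  expect_output(print(rep), "Omnibus")
})
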