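test_that("negative sets are uniform, distinct and seed-reproducible", {
  full <- build_negative_set(c("m1", "m2"), c("g1", "g2", "g3"), 6, 99)
  expect_equal(nrow(full), 6L)
  expect_equal(nrow(unique(full[, 1:2])), 6L)     # exhaustive universe
  expect_true(all(full$label == "nonfunctional"))

  a <- build_negative_set(letters[1:5], LETTERS[1:8], 10, 123)
  b <- build_negative_set(letters[1:5], LETTERS[1:8], 10, 123)
  expect_identical(a, b)
  c <- build_negative_set(letters[1:5], LETTERS[1:8], 10, 124)
  expect_false(identical(a, c))

  expect_equal(nrow(build_negative_set("m", "g", 0, 1)), 0L)
  expect_error(build_negative_set("m", "g", 2, 1), "cannot draw")
})

test_that("small-dataset splits have sizes differing by at most one", {
  s74 <- split_small_datasets(sprintf("m%02d", 1:74), 3, 7)
  expect_equal(unname(sort(lengths(s74), decreasing = TRUE)),
               c(25L, 25L, 24L))
  s26 <- split_small_datasets(sprintf("m%02d", 1:26), 3, 7)
  expect_equal(unname(sort(lengths(s26), decreasing = TRUE)),
               c(9L, 9L, 8L))
  s3 <- split_small_datasets(c("a", "b", "c"), 3, 7)
  expect_equal(unname(lengths(s3)), c(1L, 1L, 1L))
  expect_setequal(unlist(s74), sprintf("m%02d", 1:74))
  expect_identical(split_small_datasets(letters, 3, 5),
                   split_small_datasets(letters, 3, 5))

  pairs <- pairs_from_labels(rep(TRUE, 4))
  pairs$mirna_id <- c("a", "a", "b", "c")
  expect_equal(nrow(subset_pairs(pairs, c("a", "c"))), 3L)
})

test_that("depth metrics report targets per miRNA and precision", {
  # perfect ranking: positives first
  ranked <- ranked_from_labels(rep(c(TRUE, FALSE), each = 10))
  pairs <- pairs_from_labels(rep(c(TRUE, FALSE), each = 10))
  m <- metrics_at_depth(ranked, pairs, depth_per_mirna = 10, n_mirnas = 1)
  expect_equal(m$precision, 1)
  expect_equal(m$targets_per_mirna, 10)
  # full depth: precision equals the positive fraction
  mfull <- metrics_at_depth(ranked, pairs, 20, 1)
  expect_equal(mfull$precision, 0.5)
  expect_equal(mfull$targets_per_mirna, 10)
  # no labeled predictions at all -> precision undefined
  m0 <- metrics_at_depth(ranked, pairs_from_labels(logical(0)), 5, 1)
  expect_true(is.na(m0$precision))
  expect_equal(m0$targets_per_mirna, 0)
  # predictions outside the labeled universe are ignored
  extra <- ranked
  extra$gene_id <- paste0("x", extra$gene_id)
  expect_true(is.na(metrics_at_depth(extra, pairs, 5, 1)$precision))

  # random balanced ranking at large depth: precision near 1/2
  set.seed(31)
  labs <- sample(rep(c(TRUE, FALSE), 500))
  mr <- metrics_at_depth(ranked_from_labels(labs), pairs_from_labels(labs),
                         1000, 1)
  expect_equal(mr$precision, 0.5)
  mr2 <- metrics_at_depth(ranked_from_labels(labs), pairs_from_labels(labs),
                          600, 1)
  expect_lt(abs(mr2$precision - 0.5), 0.07)
})

test_that("true positives before the k-th false positive walk the list", {
  labs <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  ranked <- ranked_from_labels(labs)
  pairs <- pairs_from_labels(labs)
  expect_equal(tp_before_kth_fp(ranked, pairs, 1), 2L)
  expect_equal(tp_before_kth_fp(ranked, pairs, 2), 3L)
  expect_equal(tp_before_kth_fp(ranked, pairs, 3), 3L)   # fewer FPs than k
  allpos <- ranked_from_labels(rep(TRUE, 4))
  expect_equal(tp_before_kth_fp(allpos, pairs_from_labels(rep(TRUE, 4)), 1),
               4L)
  expect_true(all(diff(vapply(1:3, tp_before_kth_fp, 0L,
                              ranked = ranked, pairs = pairs)) >= 0))
})

test_that("rank bins have the documented sizes, means and SEMs", {
  ranked <- ranked_from_labels(rep(TRUE, 70))
  expr <- data.frame(mirna_id = ranked$mirna_id, gene_id = ranked$gene_id,
                     log2fc = rep(-1, 70), stringsAsFactors = FALSE)
  bins <- rank_bin_means(ranked, expr, "doubling")
  expect_equal(bins$n, c(10L, 20L, 40L))
  expect_equal(bins$mean_log2fc, rep(-1, 3))
  expect_equal(bins$sem, rep(0, 3))

  e3 <- expr[1:3, ]; e3$log2fc <- c(-1, 0, 1)
  b3 <- rank_bin_means(ranked[1:3, ], e3, "fixed", bin_size = 3)
  expect_equal(b3$mean_log2fc, 0)
  expect_equal(b3$sem, 1 / sqrt(3))

  bfix <- rank_bin_means(ranked, expr, "fixed", bin_size = 30)
  expect_equal(bfix$n, c(30L, 30L, 10L))

  # unmatched predictions are dropped with a message
  expr2 <- expr[11:70, ]
  expect_message(b2 <- rank_bin_means(ranked, expr2, "doubling"),
                 "10 prediction")
  expect_equal(sum(b2$n), 60L)
  expect_error(suppressMessages(rank_bin_means(ranked, expr[0, ], "doubling")),
               "no prediction joins")
})

test_that("precision-sensitivity curves trace the labeled ranking", {
  labs <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  curve <- precision_sensitivity_curve(ranked_from_labels(labs),
                                       pairs_from_labels(labs))
  expect_equal(curve$sensitivity, c(1, 2, 2, 3, 3) / 3)
  expect_equal(curve$precision, c(1, 1, 2 / 3, 3 / 4, 3 / 5))
  # perfect ranking: precision 1 until all positives are found
  perf <- precision_sensitivity_curve(ranked_from_labels(c(TRUE, TRUE, FALSE)),
                                      pairs_from_labels(c(TRUE, TRUE, FALSE)))
  expect_equal(perf$precision[1:2], c(1, 1))
  expect_equal(perf$sensitivity[2], 1)
  # inverted balanced ranking ends at precision 1/2
  inv <- precision_sensitivity_curve(ranked_from_labels(c(FALSE, TRUE)),
                                     pairs_from_labels(c(FALSE, TRUE)))
  expect_equal(inv$precision[2], 0.5)
  expect_equal(inv$sensitivity[2], 1)
})

test_that("expression labeling uses the -0.2 log2FC rule", {
  expr <- data.frame(mirna_id = "m", gene_id = c("g1", "g2", "g3"),
                     log2fc = c(-0.2, -0.1999, -1.5))
  lab <- label_by_log2fc(expr)
  expect_equal(lab$label, c("functional", "nonfunctional", "functional"))
})

test_that("method comparison delegates to one-sided standard tests", {
  x <- c(0.9, 0.85, 0.92); y <- c(0.5, 0.55, 0.48)
  expect_lt(compare_methods_test(x, y, "t"), 0.01)
  expect_gt(compare_methods_test(y, x, "t"), 0.95)
  expect_lt(compare_methods_test(x, y, "wilcoxon"), 0.05)
})
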