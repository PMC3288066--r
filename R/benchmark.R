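## benchmark: labeled-pair construction, dataset splitting, and the ranked-
## prediction evaluation statistics (targets per miRNA, precision at depth,
## true positives before the k-th false positive, rank-binned expression
## fold changes, precision-sensitivity curves).
##
## "Predictions per miRNA" is realized as a global ranking depth divided by
## the number of miRNAs, matching how the horizontal axes of the evaluation
## are normalized; a per-miRNA top-k variant is available via
## `per_mirna = TRUE` for sensitivity analysis.

.pair_key <- function(mirna_id, gene_id) paste(mirna_id, gene_id, sep = "\r")

#' Sample a balanced negative (non-functional) set
#'
#' Draws `N` distinct miRNA-gene pairs uniformly without replacement from
#' the Cartesian product of the miRNAs with the unbound genes (genes with no
#' experimental binding evidence).  `N` is typically chosen equal to the
#' number of functional pairs so that precision values are well spread
#' between 0 and 1.
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param unbound_genes Character vector of gene identifiers.
#' @param N Number of pairs to draw.
#' @param rng_seed Integer seed; the draw is reproducible bit-for-bit.
#' @return Data frame with columns `mirna_id`, `gene_id`, `label`
#'   (all `"nonfunctional"`).
#' @export
build_negative_set <- function(mirna_ids, unbound_genes, N, rng_seed) {
  withr::with_seed(rng_seed, .sample_pairs(mirna_ids, unbound_genes, N))
}

# uniform sample of N distinct pairs using the current RNG state
.sample_pairs <- function(mirna_ids, unbound_genes, N) {
  nm <- length(mirna_ids); ng <- length(unbound_genes)
  N <- as.integer(N)
  if (N > nm * ng)
    stop(sprintf("cannot draw %d pairs from a universe of %d", N, nm * ng))
  idx <- sample.int(nm * ng, N) - 1L
  data.frame(mirna_id = mirna_ids[idx %% nm + 1L],
             gene_id = unbound_genes[idx %/% nm + 1L],
             label = rep("nonfunctional", N),
             stringsAsFactors = FALSE)
}

#' Partition miRNAs into small datasets
#'
#' Randomly divides the miRNAs into `n_splits` subgroups whose sizes differ
#' by at most one (74 miRNAs give 25/25/24; 26 give 9/9/8), for estimating
#' the spread of evaluation statistics across independent subsets.
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @param n_splits Number of subgroups (default 3).
#' @param rng_seed Integer seed.
#' @return List of `n_splits` character vectors.
#' @export
split_small_datasets <- function(mirna_ids, n_splits = 3L, rng_seed) {
  n <- length(mirna_ids)
  n_splits <- as.integer(n_splits)
  if (n < n_splits) stop("need at least ", n_splits, " miRNAs")
  shuffled <- withr::with_seed(rng_seed, sample(mirna_ids))
  sizes <- rep(n %/% n_splits, n_splits)
  extra <- n %% n_splits
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(shuffled, rep(seq_len(n_splits), times = sizes))
}

#' Restrict labeled pairs to a miRNA subgroup
#' @param pairs Labeled-pair data frame (`mirna_id`, `gene_id`, `label`).
#' @param mirna_ids miRNA subgroup.
#' @return The pair subset whose miRNA belongs to the subgroup.
#' @export
subset_pairs <- function(pairs, mirna_ids) {
  pairs[pairs$mirna_id %in% mirna_ids, , drop = FALSE]
}

# inner-join ranked predictions with labels, keeping rank order
.labeled_ranking <- function(ranked, pairs) {
  key <- .pair_key(ranked$mirna_id, ranked$gene_id)
  lab <- setNames(pairs$label, .pair_key(pairs$mirna_id, pairs$gene_id))
  hit <- key %in% names(lab)
  out <- ranked[hit, , drop = FALSE]
  out$label <- unname(lab[key[hit]])
  out
}

#' Targets per miRNA and precision at a ranking depth
#'
#' Restricts the ranked predictions to the labeled pairs, takes the top
#' `depth_per_mirna * n_mirnas` of them, and reports the number of true
#' positives per miRNA and the precision TP / (TP + FP).  When no labeled
#' prediction is available at the requested depth, precision is undefined
#' and reported as `NA`.
#'
#' @param ranked Ranked predictions (see [rank_predictions()]).
#' @param pairs Labeled pairs (`mirna_id`, `gene_id`,
#'   `label` in functional/nonfunctional).
#' @param depth_per_mirna Ranking depth per miRNA.
#' @param n_mirnas Number of miRNAs the depth is normalized by.
#' @param per_mirna If TRUE, take the top `depth_per_mirna` predictions of
#'   each miRNA separately instead of a global depth.
#' @return One-row data frame: `depth_per_mirna`, `n_taken`, `tp`, `fp`,
#'   `targets_per_mirna`, `precision`.
#' @export
metrics_at_depth <- function(ranked, pairs, depth_per_mirna, n_mirnas,
                             per_mirna = FALSE) {
  lab <- .labeled_ranking(ranked, pairs)
  if (per_mirna) {
    taken <- do.call(rbind, lapply(split(lab, lab$mirna_id),
                                   head, n = depth_per_mirna))
  } else {
    taken <- head(lab, n = depth_per_mirna * n_mirnas)
  }
  tp <- sum(taken$label == "functional")
  fp <- nrow(taken) - tp
  data.frame(depth_per_mirna = depth_per_mirna, n_taken = nrow(taken),
             tp = tp, fp = fp,
             targets_per_mirna = tp / n_mirnas,
             precision = if (nrow(taken) == 0L) NA_real_ else tp / (tp + fp))
}

#' True positives found before the k-th false positive
#'
#' Walks the labeled ranking and counts functional pairs seen strictly
#' before the `kth` non-functional pair; if fewer than `kth` false
#' positives exist, all true positives are counted.
#'
#' @inheritParams metrics_at_depth
#' @param kth Which false positive to stop at (>= 1).
#' @return Integer count.
#' @export
tp_before_kth_fp <- function(ranked, pairs, kth) {
  if (kth < 1L) stop("kth must be >= 1")
  lab <- .labeled_ranking(ranked, pairs)
  is_fp <- lab$label != "functional"
  cut <- which(cumsum(is_fp) == kth)[1L]
  if (is.na(cut)) sum(!is_fp) else sum(!is_fp[seq_len(cut - 1L)])
}

#' Mean expression change in rank bins
#'
#' Joins ranked predictions to a per-pair log2 fold-change table and reports
#' the mean, standard error of the mean and size of each rank bin.  The
#' `"doubling"` scheme uses bins of sizes 10, 20, 40, 80, ... (top 10
#' predictions, next 20, next 40, ...); the `"fixed"` scheme uses constant
#' bins of `bin_size` predictions.  Predictions without an expression entry
#' are dropped (count reported via a message).
#'
#' @param ranked Ranked predictions.
#' @param expr Expression table: data frame with `mirna_id`, `gene_id`,
#'   `log2fc` (log2 fold change in protein expression; more negative means
#'   stronger repression).
#' @param scheme `"doubling"` or `"fixed"`.
#' @param first_bin Size of the first doubling bin (default 10).
#' @param bin_size Size of fixed bins (default 100).
#' @return Data frame with columns `bin`, `from`, `to`, `n`, `mean_log2fc`,
#'   `sem`.
#' @export
rank_bin_means <- function(ranked, expr, scheme = c("doubling", "fixed"),
                           first_bin = 10L, bin_size = 100L) {
  scheme <- match.arg(scheme)
  key <- .pair_key(ranked$mirna_id, ranked$gene_id)
  fc <- setNames(expr$log2fc, .pair_key(expr$mirna_id, expr$gene_id))
  hit <- key %in% names(fc)
  dropped <- sum(!hit)
  if (dropped > 0L)
    message(dropped, " prediction(s) without expression entry dropped")
  vals <- unname(fc[key[hit]])
  n <- length(vals)
  if (n == 0L) stop("no prediction joins the expression table")
  sizes <- if (scheme == "doubling") {
    s <- first_bin * 2^(0:ceiling(log2(max(n / first_bin, 1)) + 1))
    s[cumsum(s) - s < n]
  } else rep(bin_size, ceiling(n / bin_size))
  bins <- rep(seq_along(sizes), times = sizes)[seq_len(n)]
  res <- lapply(split(vals, bins), function(v) {
    data.frame(n = length(v), mean_log2fc = mean(v),
               sem = if (length(v) > 1L) sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- do.call(rbind, res)
  out$bin <- seq_len(nrow(out))
  ends <- cumsum(out$n)
  out$from <- ends - out$n + 1L
  out$to <- ends
  rownames(out) <- NULL
  out[, c("bin", "from", "to", "n", "mean_log2fc", "sem")]
}

#' Precision-sensitivity curve over the labeled universe
#'
#' Standard PR curve: at every rank of the labeled ranking, sensitivity is
#' TP / (total positives) and precision TP / rank.
#'
#' @inheritParams metrics_at_depth
#' @return Data frame with columns `rank`, `sensitivity`, `precision`.
#' @export
precision_sensitivity_curve <- function(ranked, pairs) {
  lab <- .labeled_ranking(ranked, pairs)
  total_pos <- sum(pairs$label == "functional")
  if (total_pos == 0L) stop("no functional pair in the labeled universe")
  tp <- cumsum(lab$label == "functional")
  r <- seq_len(nrow(lab))
  data.frame(rank = r, sensitivity = tp / total_pos, precision = tp / r)
}

#' Label miRNA-gene pairs from expression fold changes
#'
#' Training-label rule: pairs with `log2fc <= cutoff` (default -0.2) are
#' functional targets, the rest non-functional.
#'
#' @param expr Expression table (`mirna_id`, `gene_id`, `log2fc`).
#' @param cutoff Fold-change threshold (default -0.2).
#' @return Labeled-pair data frame (`mirna_id`, `gene_id`, `label`).
#' @export
label_by_log2fc <- function(expr, cutoff = -0.2) {
  data.frame(mirna_id = expr$mirna_id, gene_id = expr$gene_id,
             label = ifelse(expr$log2fc <= cutoff, "functional",
                            "nonfunctional"),
             stringsAsFactors = FALSE)
}

#' Compare an evaluation statistic between two methods across small datasets
#'
#' Convenience wrapper delegating to the standard one-sided two-sample
#' t test (`stats::t.test`) or Wilcoxon rank-sum test
#' (`stats::wilcox.test`), testing whether `x` is greater than `y`.
#'
#' @param x,y Numeric vectors of the statistic (e.g. precision per small
#'   dataset, or log2 fold changes of two prediction sets).
#' @param test `"t"` or `"wilcoxon"`.
#' @return The p-value of the one-sided test.
#' @export
compare_methods_test <- function(x, y, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (test == "t") stats::t.test(x, y, alternative = "greater")$p.value
  else stats::wilcox.test(x, y, alternative = "greater", exact = FALSE)$p.value
}
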