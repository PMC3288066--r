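## scoring: filtered counts (t_filter, c_filter), the word background
## probability, the single-hypothesis over-representation P value P_SH, and
## the ranked prediction list.
##
## P_SH is the upper-tail binomial probability that the seed-match word
## occurs by chance at least c times among the t windows passing the active
## filter, with per-window word probability p from a zeroth-order
## (mononucleotide) background.  Lower values mean a more significant
## over-representation; the prediction list is always ranked by P_SH.

#' Filter configuration for interaction scoring
#'
#' @param mode One of `"none"`, `"access"`, `"cons"`, `"cons+access"`:
#'   which windows are counted in t and which seed matches in c.
#' @param p_cutoff Accessibility cutoff on the unpaired probability
#'   (default 0.2, the optimized value; inclusive comparison).
#' @param cons A [cons_config()]; defaults to the Selected-4 ladder
#'   (human, chimp, rhesus, mouse), required for the conservation modes.
#' @param seed_start,seed_len Seed definition (defaults: positions 2-8).
#' @return Object of class `filter_config`.
#' @export
filter_config <- function(mode = c("none", "access", "cons", "cons+access"),
                          p_cutoff = 0.2, cons = NULL,
                          seed_start = 2L, seed_len = 7L) {
  mode <- match.arg(mode)
  if (p_cutoff < 0 || p_cutoff > 1) stop("p_cutoff must be in [0, 1]")
  if (mode %in% c("cons", "cons+access") && is.null(cons))
    cons <- cons_config("selected", species = selected_species_ladder(4L))
  structure(list(mode = mode, p_cutoff = p_cutoff, cons = cons,
                 seed_start = as.integer(seed_start),
                 seed_len = as.integer(seed_len)),
            class = "filter_config")
}

#' Background probability of a word under the UTR's composition
#'
#' Zeroth-order model: the product over word letters of the mononucleotide
#' frequency of that letter in the scored UTR (N excluded from the counts).
#' A global composition table can be supplied instead of the per-UTR one.
#'
#' @param utr A [utr_record()].
#' @param word A [seed_word()] or DNA string.
#' @param composition Optional named frequency vector over A/C/G/T summing
#'   to 1; overrides the per-UTR composition.
#' @return Probability in `[0, 1]`.
#' @export
word_probability <- function(utr, word, composition = NULL) {
  w <- if (inherits(word, "seed_word")) word$word else word
  if (is.null(composition)) {
    ch <- .chars(utr$sequence)
    ch <- ch[ch != "N"]
    if (length(ch) == 0L) stop("UTR '", utr$gene_id, "' is all N")
    composition <- table(factor(ch, levels = c("A", "C", "G", "T")))
    composition <- as.numeric(composition) / sum(composition)
    names(composition) <- c("A", "C", "G", "T")
  } else {
    if (is.null(names(composition)) ||
        !all(c("A", "C", "G", "T") %in% names(composition)))
      stop("composition must be named with A, C, G, T")
    composition <- composition[c("A", "C", "G", "T")] / sum(composition)
  }
  prod(composition[.chars(w)])
}

#' Window flags of the active filter
#'
#' Logical vector over the 0-based window starts of the UTR: TRUE where the
#' window belongs to the filtered universe.  All modes exclude windows
#' containing N, so that c <= t by construction.
#'
#' @param utr A [utr_record()].
#' @param cfg A [filter_config()].
#' @param profile [pfree_profile()], required for the accessibility modes.
#' @param aln [aligned_utr()], required for the conservation modes.
#' @param k Window length; defaults to `cfg$seed_len`.
#' @return Logical vector of length `max(length - k + 1, 0)`.
#' @export
filter_window_flags <- function(utr, cfg, profile = NULL, aln = NULL,
                                k = cfg$seed_len) {
  flags <- .nfree_mask(utr$sequence, k)
  if (cfg$mode %in% c("access", "cons+access")) {
    if (is.null(profile))
      stop("filter mode '", cfg$mode, "' requires an unpaired-probability ",
           "profile for gene '", utr$gene_id, "'", call. = FALSE)
    if (length(profile$p_free) != utr$length)
      stop("profile length disagrees with UTR '", utr$gene_id, "'")
    flags <- flags & accessible_window_flags(profile, k, cfg$p_cutoff)
  }
  if (cfg$mode %in% c("cons", "cons+access")) {
    if (is.null(aln))
      stop("filter mode '", cfg$mode, "' requires an alignment for gene '",
           utr$gene_id, "'", call. = FALSE)
    flags <- flags & conserved_window_flags(utr, aln, NULL, k, cfg$cons)
  }
  flags
}

#' Filtered window and seed-match counts
#'
#' t_filter is the total number of k-windows of the 3'UTR meeting the filter
#' requirement (regardless of their sequence); c_filter is the number of
#' seed matches meeting the same requirement.  With `mode = "none"` these
#' are the N-free window total and the raw match count.
#'
#' @inheritParams filter_window_flags
#' @param word A [seed_word()] or DNA string.
#' @return List with integer fields `t_filter` and `c_filter`.
#' @export
filtered_counts <- function(utr, word, cfg, profile = NULL, aln = NULL) {
  w <- if (inherits(word, "seed_word")) word$word else word
  flags <- filter_window_flags(utr, cfg, profile, aln, k = nchar(w))
  pos <- find_seed_matches(utr, w)$positions
  list(t_filter = sum(flags), c_filter = sum(flags[pos + 1L]))
}

#' Single-hypothesis over-representation P value
#'
#' Upper-tail binomial probability `P(X >= c)` with `X ~ Binomial(t, p)`,
#' evaluated through the survival function so that values down to the
#' double-precision floor remain representable.  `p_sh(t, 0, p) = 1`
#' exactly.
#'
#' @param t Number of windows passing the filter (trials).
#' @param c Number of seed matches passing the filter (successes).
#' @param p Per-window word probability.
#' @return Probability in `(0, 1]`.
#' @export
#' @examples
#' p_sh(10, 2, 0.1)   # 1 - 0.9^10 - 10 * 0.1 * 0.9^9
p_sh <- function(t, c, p) {
  t <- as.integer(t); c <- as.integer(c)
  if (any(c > t)) stop("c must not exceed t")
  if (any(c < 0L) || any(t < 0L)) stop("t and c must be non-negative")
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  out <- ifelse(c == 0L, 1, pbinom(c - 1L, t, p, lower.tail = FALSE))
  # guard against survival-function results rounding to exactly 0 for
  # astronomically small tails: clamp to the smallest positive double
  ifelse(out == 0 & c > 0L & p > 0, .Machine$double.xmin, out)
}

#' Score one miRNA-3'UTR interaction
#'
#' Composes [seed_word()], [filtered_counts()], [word_probability()] and
#' [p_sh()].  Interactions with `c_filter = 0` are flagged as
#' non-predictions (`prediction = FALSE`, `p_sh = 1`): they never enter the
#' ranked list.
#'
#' @param mir A [mirna()].
#' @param utr A [utr_record()].
#' @param cfg A [filter_config()].
#' @param profile,aln Side inputs required by the filter mode.
#' @param composition Optional global background composition (see
#'   [word_probability()]).
#' @return One-row data frame with columns `mirna_id`, `gene_id`,
#'   `t_filter`, `c_filter`, `p_word`, `p_sh`, `prediction`.
#' @export
score_interaction <- function(mir, utr, cfg = filter_config(),
                              profile = NULL, aln = NULL,
                              composition = NULL) {
  word <- seed_word(mir, cfg$seed_start, cfg$seed_len)
  counts <- filtered_counts(utr, word, cfg, profile, aln)
  p <- word_probability(utr, word, composition)
  if (p == 0 && counts$c_filter > 0L)
    stop(sprintf(
      "inconsistency for %s x %s: %d matches observed but word '%s' has zero background probability",
      mir$mirna_id, utr$gene_id, counts$c_filter, word$word), call. = FALSE)
  data.frame(mirna_id = mir$mirna_id, gene_id = utr$gene_id,
             t_filter = counts$t_filter, c_filter = counts$c_filter,
             p_word = p, p_sh = p_sh(counts$t_filter, counts$c_filter, p),
             prediction = counts$c_filter > 0L,
             stringsAsFactors = FALSE)
}

#' Score many miRNA-3'UTR interactions
#'
#' Batch scorer with per-gene caching of window strings and filter flags;
#' equivalent to [score_interaction()] applied to every pair.
#'
#' @param mirnas Named list of [mirna()]s.
#' @param utrs Named list of [utr_record()]s.
#' @param cfg A [filter_config()].
#' @param profiles Named list of [pfree_profile()]s keyed by gene id
#'   (accessibility modes).
#' @param alignments Named list of [aligned_utr()]s keyed by gene id
#'   (conservation modes).
#' @param pairs Optional data frame with columns `mirna_id`, `gene_id`
#'   restricting scoring to those pairs; by default every combination is
#'   scored.
#' @param composition Optional global background composition.
#' @return Data frame with one row per scored pair (see
#'   [score_interaction()] for the columns), unranked.
#' @export
predict_targets <- function(mirnas, utrs, cfg = filter_config(),
                            profiles = NULL, alignments = NULL,
                            pairs = NULL, composition = NULL) {
  k <- cfg$seed_len
  words <- vapply(mirnas, function(m) seed_word(m, cfg$seed_start, k)$word, "")
  mirna_ids <- vapply(mirnas, `[[`, "", "mirna_id")
  names(words) <- mirna_ids
  if (is.null(names(utrs)))
    names(utrs) <- vapply(utrs, `[[`, "", "gene_id")

  if (is.null(pairs)) {
    by_gene <- setNames(rep(list(mirna_ids), length(utrs)), names(utrs))
  } else {
    by_gene <- split(pairs$mirna_id, pairs$gene_id)
  }

  res <- vector("list", length(by_gene))
  gi <- 0L
  for (gene_id in names(by_gene)) {
    gi <- gi + 1L
    utr <- utrs[[gene_id]]
    if (is.null(utr)) stop("unknown gene '", gene_id, "' in pairs")
    flags <- filter_window_flags(utr, cfg, profiles[[gene_id]],
                                 alignments[[gene_id]], k = k)
    wins <- .windows(utr$sequence, k)
    t_filter <- sum(flags)
    if (is.null(composition)) {
      ch <- .chars(utr$sequence); ch <- ch[ch != "N"]
      comp <- as.numeric(table(factor(ch, levels = c("A", "C", "G", "T"))))
      comp <- setNames(comp / sum(comp), c("A", "C", "G", "T"))
    } else comp <- composition
    ids <- by_gene[[gene_id]]
    ws <- words[ids]
    cs <- integer(length(ids)); ps <- numeric(length(ids))
    for (j in seq_along(ids)) {
      pos <- which(wins == ws[j])
      cs[j] <- if (length(pos)) sum(flags[pos]) else 0L
      ps[j] <- prod(comp[.chars(ws[j])])
    }
    if (any(ps == 0 & cs > 0L))
      stop("matches observed for a word with zero background probability ",
           "in gene '", gene_id, "'", call. = FALSE)
    res[[gi]] <- data.frame(mirna_id = ids, gene_id = gene_id,
                            t_filter = t_filter, c_filter = cs,
                            p_word = ps, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_sh <- p_sh(out$t_filter, out$c_filter, out$p_word)
  out$prediction <- out$c_filter > 0L
  out
}

#' Rank predictions by P_SH
#'
#' Ascending P_SH (most significant first); exact ties broken by descending
#' `c_filter`, then ascending `gene_id`, then ascending `mirna_id`, so the
#' ranking is deterministic.  Non-predictions (`c_filter = 0`) are dropped.
#'
#' @param scores Data frame from [predict_targets()] /
#'   [score_interaction()].
#' @return The ranked subset with a 1-based `rank` column added.
#' @export
rank_predictions <- function(scores) {
  keep <- scores$c_filter > 0L
  out <- scores[keep, , drop = FALSE]
  if (nrow(out) > 0L) {
    ord <- order(out$p_sh, -out$c_filter, out$gene_id, out$mirna_id,
                 method = "radix")
    out <- out[ord, , drop = FALSE]
  }
  rownames(out) <- NULL
  out$rank <- seq_len(nrow(out))
  out
}
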