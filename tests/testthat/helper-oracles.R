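# Independent brute-force oracles and tiny fixture builders used across the
# suite.  These deliberately avoid the vectorized code paths they check.

# naive O(n*k) sliding-window match enumeration (0-based starts)
naive_matches <- function(seq, word) {
  k <- nchar(word)
  L <- nchar(seq)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (s in 0:(L - k)) {
    win <- substr(seq, s + 1L, s + k)
    if (grepl("N", win, fixed = TRUE)) next
    if (win == word) hits <- c(hits, s)
  }
  hits
}

# naive N-free window count
naive_total_windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(0L)
  n <- 0L
  for (s in 0:(L - k))
    if (!grepl("N", substr(seq, s + 1L, s + k), fixed = TRUE)) n <- n + 1L
  n
}

# direct binomial upper-tail summation from first principles
naive_psh <- function(t, c, p) {
  if (c == 0) return(1)
  sum(vapply(c:t, function(j) choose(t, j) * p^j * (1 - p)^(t - j), 0))
}

# random DNA string
rand_seq <- function(L, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, L, replace = TRUE), collapse = "")
}

# build a small aligned_utr from a named vector of per-species strings
toy_aln <- function(rows, ref = "human", gene_id = "g") {
  aligned_utr(gene_id, ref, rows)
}

# one-row-per-pair ranked data frame from a label pattern, for metric tests;
# ranks follow the input order
ranked_from_labels <- function(labels) {
  n <- length(labels)
  data.frame(mirna_id = rep("m1", n), gene_id = sprintf("g%02d", seq_len(n)),
             t_filter = 100L, c_filter = 1L, p_word = 1e-4,
             p_sh = seq_len(n) * 1e-6, prediction = TRUE,
             rank = seq_len(n), stringsAsFactors = FALSE)
}

pairs_from_labels <- function(labels) {
  n <- length(labels)
  data.frame(mirna_id = rep("m1", n), gene_id = sprintf("g%02d", seq_len(n)),
             label = ifelse(labels, "functional", "nonfunctional"),
             stringsAsFactors = FALSE)
}
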