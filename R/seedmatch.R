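## seedmatch: derive the target-site word from a miRNA seed and enumerate
## its (possibly overlapping) occurrences in a 3'UTR.

#' Target-site word of a miRNA seed
#'
#' The word a target site must spell in the mRNA: the reverse complement of
#' the miRNA subsequence at positions `seed_start .. seed_start+seed_len-1`,
#' written in the DNA alphabet (U -> T).  With the defaults (positions 2-8)
#' this is the canonical 7-mer seed match.
#'
#' @param mir A [mirna()].
#' @param seed_start,seed_len Override the record's seed definition.
#' @return Object of class `seed_word` with fields `word`, `source_mirna`,
#'   `seed_start`, `seed_len`.
#' @export
#' @examples
#' let7a <- mirna("hsa-let-7a", "UGAGGUAGUAGGUUGUAUAGUU")
#' seed_word(let7a)$word   # "CTACCTC"
seed_word <- function(mir, seed_start = mir$seed_start,
                      seed_len = mir$seed_len) {
  seed_start <- as.integer(seed_start); seed_len <- as.integer(seed_len)
  if (seed_start < 1L || seed_len < 1L ||
      seed_start + seed_len - 1L > nchar(mir$sequence))
    stop(sprintf("seed window [%d, %d] outside miRNA '%s'",
                 seed_start, seed_start + seed_len - 1L, mir$mirna_id))
  sub <- substr(mir$sequence, seed_start, seed_start + seed_len - 1L)
  structure(list(word = .revcomp_dna(chartr("U", "T", sub)),
                 source_mirna = mir$mirna_id,
                 seed_start = seed_start, seed_len = seed_len),
            class = "seed_word")
}

#' Enumerate seed matches in a 3'UTR
#'
#' All exact occurrences of the word, overlapping ones included; windows
#' containing `N` never match.  Positions are 0-based starts in the ungapped
#' UTR.
#'
#' @param utr A [utr_record()].
#' @param word A [seed_word()] (or plain DNA string).
#' @return Object of class `site_list` with fields `gene_id`, `word`,
#'   `positions` (strictly increasing integer vector).
#' @export
find_seed_matches <- function(utr, word) {
  w <- if (inherits(word, "seed_word")) word$word else word
  k <- nchar(w)
  pos <- which(.windows(utr$sequence, k) == w) - 1L
  structure(list(gene_id = utr$gene_id, word = w, positions = pos),
            class = "site_list")
}

#' Number of N-free k-windows in a 3'UTR
#'
#' The window universe over which both the total count t and the seed-match
#' count c are defined: windows containing `N` are excluded from both, so
#' `c <= t` holds by construction.  Equals `length - k + 1` when the
#' sequence has no `N`, and 0 when the sequence is shorter than `k`.
#'
#' @param utr A [utr_record()].
#' @param k Window length (>= 1).
#' @return Integer count.
#' @export
total_windows <- function(utr, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sum(.nfree_mask(utr$sequence, k))
}
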