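## conservation: decide whether seed-match windows are conserved across
## species under the Any-S or Selected-S rule, using orthologous alignment
## columns (positional conservation, not presence-anywhere).
##
## Gap handling: any gap in the species row within the window's
## reference-bearing columns breaks the site (an indel interrupts a
## contiguous site).  Insertion columns relative to the reference (reference
## gap) are skipped: the species must match the reference across the same
## reference-bearing columns.

#' Conservation filter configuration
#'
#' Two stringency ladders: `"any"` requires the site in at least `S` species
#' (the reference included), regardless of identity; `"selected"` requires
#' the site in every species of a fixed, pre-ordered list.  The canonical
#' selected ladder starts at \{human, chimp\} and adds rhesus, mouse, dog,
#' cow and chicken in order of increasing distance from human (see
#' [selected_species_ladder()]).
#'
#' @param mode `"any"` or `"selected"`.
#' @param S Minimum species count (any mode; >= 1).
#' @param species Ordered species names (selected mode; reference first).
#' @return Object of class `cons_config`.
#' @export
#' @examples
#' cons_config("any", S = 4)
#' cons_config("selected", species = selected_species_ladder(4))
cons_config <- function(mode = c("any", "selected"), S = NULL,
                        species = NULL) {
  mode <- match.arg(mode)
  if (mode == "any") {
    if (is.null(S) || as.integer(S) < 1L)
      stop("any mode requires S >= 1")
    S <- as.integer(S)
  } else {
    if (is.null(species) || length(species) == 0L)
      stop("selected mode requires a non-empty species list")
    S <- length(species)
  }
  structure(list(mode = mode, S = S, species_list = species),
            class = "cons_config")
}

#' The canonical selected-species ladder
#'
#' Order in which species are added when tightening the selected-species
#' filter: human, chimp, rhesus, mouse, dog, cow, chicken.  `Selected-4`
#' (human, chimp, rhesus, mouse) is the default filter of the package, the
#' configuration found optimal on training data.
#'
#' @param S Number of species (2..7 are the studied rungs; 1..7 accepted).
#' @return Character vector of `S` species names.
#' @export
selected_species_ladder <- function(S) {
  ladder <- c("human", "chimp", "rhesus", "mouse", "dog", "cow", "chicken")
  S <- as.integer(S)
  if (S < 1L || S > length(ladder))
    stop("S must be between 1 and ", length(ladder))
  ladder[seq_len(S)]
}

#' Map ungapped reference positions to alignment columns
#'
#' @param aln An [aligned_utr()].
#' @return Integer vector: entry `p + 1` (for 0-based reference position `p`)
#'   is the 0-based alignment column holding the `(p+1)`-th non-gap
#'   reference character.
#' @export
column_map <- function(aln) {
  which(.chars(aln$rows[[aln$ref_species]]) != .GAP) - 1L
}

#' Does one species carry the site at an orthologous position?
#'
#' TRUE iff the species row, restricted to the reference-bearing columns
#' `cmap[start] .. cmap[start + k - 1]`, has no gap and spells exactly
#' `word`.  The reference must itself carry `word` at `start` (checked).
#' Species absent from the alignment are treated as all-gap.
#'
#' @param aln An [aligned_utr()].
#' @param cmap Column map from [column_map()].
#' @param species Species name.
#' @param start 0-based reference position of the site.
#' @param word A [seed_word()] or DNA string.
#' @return Logical scalar.
#' @export
species_has_site <- function(aln, cmap, species, start, word) {
  w <- if (inherits(word, "seed_word")) word$word else word
  k <- nchar(w)
  if (start < 0L || start + k > length(cmap))
    stop("site window outside the reference sequence")
  cols <- cmap[(start + 1L):(start + k)] + 1L
  ref_site <- paste(.chars(aln$rows[[aln$ref_species]])[cols], collapse = "")
  if (ref_site != w)
    stop(sprintf(
      "reference does not carry '%s' at position %d (found '%s')",
      w, start, ref_site), call. = FALSE)
  if (!species %in% names(aln$rows)) return(FALSE)
  sp <- .chars(aln$rows[[species]])[cols]
  !any(sp == .GAP) && paste(sp, collapse = "") == w
}

#' Is a site conserved under a conservation configuration?
#'
#' Any mode: the number of species carrying the site (reference included) is
#' at least `S`.  Selected mode: every species in the list carries the site;
#' a listed species absent from the alignment counts as all-gap, hence not
#' conserved.
#'
#' @inheritParams species_has_site
#' @param cfg A [cons_config()].
#' @return Logical scalar.
#' @export
is_conserved <- function(aln, cmap, start, word, cfg) {
  others <- setdiff(names(aln$rows), aln$ref_species)
  if (cfg$mode == "any") {
    n <- 1L   # the reference carries the site by precondition
    for (sp in others) {
      if (species_has_site(aln, cmap, sp, start, word)) n <- n + 1L
      if (n >= cfg$S) return(TRUE)
    }
    # validate the precondition even when S == 1
    species_has_site(aln, cmap, aln$ref_species, start, word)
    n >= cfg$S
  } else {
    for (sp in cfg$species_list) {
      if (sp == aln$ref_species) {
        species_has_site(aln, cmap, sp, start, word)   # precondition check
        next
      }
      if (!species_has_site(aln, cmap, sp, start, word)) return(FALSE)
    }
    TRUE
  }
}

#' Conservation classification of every k-window
#'
#' Applies the conservation rule to every window of the reference, testing
#' the reference k-mer at that window as the site word (so the filter is
#' defined for all windows, not only seed matches).  Windows containing `N`
#' in the reference are excluded, keeping the window universe identical to
#' [total_windows()].
#'
#' @param utr The reference [utr_record()] (must equal the ungapped
#'   reference row).
#' @param aln An [aligned_utr()].
#' @param cmap Column map from [column_map()]; computed when `NULL`.
#' @param k Window length.
#' @param cfg A [cons_config()].
#' @return Logical vector over 0-based window starts.
#' @export
conserved_window_flags <- function(utr, aln, cmap = NULL, k, cfg) {
  if (ungapped_ref(aln) != utr$sequence)
    stop("alignment reference row disagrees with UTR '", utr$gene_id, "'")
  cmap <- cmap %||% column_map(aln)
  L <- utr$length
  if (L < k) return(logical(0))
  ref_ch <- .chars(utr$sequence)
  nfree <- .nfree_mask(utr$sequence, k)

  # per species: ok[p] <=> species matches the reference at ref position p
  sp_window <- function(sp) {
    if (!sp %in% names(aln$rows)) return(rep(FALSE, L - k + 1L))
    ch <- .chars(aln$rows[[sp]])[cmap + 1L]
    .window_all(ch != .GAP & ch == ref_ch, k)
  }
  others <- setdiff(names(aln$rows), aln$ref_species)
  if (cfg$mode == "any") {
    count <- rep(1L, L - k + 1L)        # reference always carries its k-mer
    for (sp in others) count <- count + sp_window(sp)
    flags <- count >= cfg$S
  } else {
    flags <- rep(TRUE, L - k + 1L)
    for (sp in setdiff(cfg$species_list, aln$ref_species))
      flags <- flags & sp_window(sp)
  }
  flags & nfree
}

#' Total number of conserved k-windows
#'
#' `sum(conserved_window_flags(...))`: the filtered total count t entering
#' the over-representation score under the conservation filter.
#'
#' @inheritParams conserved_window_flags
#' @return Integer count.
#' @export
conserved_window_total <- function(utr, aln, cmap = NULL, k, cfg) {
  sum(conserved_window_flags(utr, aln, cmap, k, cfg))
}
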