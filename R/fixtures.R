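## fixtures: synthetic inputs with controlled structure.  Sequences are
## i.i.d. draws from a base composition; target sites are planted at chosen
## positions; accessibility and conservation of each planted site are
## guaranteed BY CONSTRUCTION (probability profiles with a hi/lo separation
## around the cutoff, alignments that copy the reference inside conserved
## windows and mutate outside), so filter logic can be tested without any
## thermodynamics or real evolutionary data.

.BASES <- c("A", "C", "G", "T")

.gen_seq <- function(length, composition) {
  paste(sample(.BASES, length, replace = TRUE, prob = composition),
        collapse = "")
}

#' Generate a random 3'UTR
#'
#' i.i.d. letters from a base composition; reproducible when `rng_seed` is
#' given, otherwise drawn from the current RNG state.
#'
#' @param gene_id Gene identifier.
#' @param length UTR length (>= 1).
#' @param composition Frequency vector over A, C, G, T (sums to 1).
#' @param rng_seed Optional integer seed.
#' @return A [utr_record()].
#' @export
gen_utr <- function(gene_id, length, composition = rep(0.25, 4),
                    rng_seed = NULL) {
  stopifnot(length >= 1L, length(composition) == 4L,
            abs(sum(composition) - 1) < 1e-8)
  seq <- if (is.null(rng_seed)) .gen_seq(length, composition)
         else withr::with_seed(rng_seed, .gen_seq(length, composition))
  utr_record(gene_id, seq)
}

#' Plant target-site words into a UTR
#'
#' Writes `word` at each 0-based position.  Planted windows must not
#' overlap; the background sequence may still create additional matches
#' elsewhere, so the planted set is a subset of, not equal to, the match
#' set.
#'
#' @param utr A [utr_record()].
#' @param word A [seed_word()] or DNA string.
#' @param positions 0-based start positions.
#' @return The modified [utr_record()].
#' @export
plant_matches <- function(utr, word, positions) {
  w <- if (inherits(word, "seed_word")) word$word else word
  k <- nchar(w)
  positions <- sort(as.integer(positions))
  if (any(positions < 0L) || any(positions + k > utr$length))
    stop("planted position leaves no room for the word")
  if (length(positions) > 1L && any(diff(positions) < k))
    stop("planted windows overlap")
  seq <- utr$sequence
  for (p in positions) substr(seq, p + 1L, p + k) <- w
  utr_record(utr$gene_id, seq)
}

#' Generate an unpaired-probability profile with prescribed accessibility
#'
#' Every listed k-window receives at least one contained u-mer with
#' `p_free = hi`; every u-mer not contained in a listed window stays at
#' `lo`.  With `lo < p_cutoff <= hi` all listed windows therefore classify
#' accessible, and any window farther than `k - u` positions from every
#' listed window classifies inaccessible.  Windows overlapping a listed
#' window by at least `u` positions can share its hi u-mer and classify
#' accessible as well (the hi u-mer is placed to minimize such spillover);
#' callers needing a clean separation place listed windows at least `k`
#' positions away from windows whose classification matters.
#'
#' @param gene_id Gene identifier.
#' @param utr_length UTR length.
#' @param accessible_windows 0-based starts of the k-windows to make
#'   accessible.
#' @param k Window length (default 7).
#' @param u Stretch length (default 4).
#' @param hi,lo Unpaired probabilities for accessible stretches and
#'   background (defaults 0.9 and 0.01; require `lo < hi`).
#' @return A [pfree_profile()].
#' @export
gen_pfree_profile <- function(gene_id, utr_length, accessible_windows,
                              k = 7L, u = 4L, hi = 0.9, lo = 0.01) {
  if (lo >= hi) stop("need lo < hi")
  if (utr_length < k) stop("UTR shorter than the window length")
  n_win <- utr_length - k + 1L
  listed <- sort(unique(as.integer(accessible_windows)))
  if (length(listed) > 0L && (min(listed) < 0L || max(listed) >= n_win))
    stop("accessible window start outside the valid range")
  pf <- rep(lo, utr_length)
  listed_set <- rep(FALSE, n_win)
  listed_set[listed + 1L] <- TRUE
  for (w in listed) {
    cand <- w:(w + k - u)                       # contained u-mer starts
    spill <- vapply(cand, function(q) {
      xs <- max(0L, q - (k - u)):min(n_win - 1L, q)
      sum(!listed_set[xs + 1L])
    }, 0L)
    q <- cand[which.min(spill)]
    pf[q + u] <- hi                              # u-mer ends at 1-based q+u
  }
  pfree_profile(gene_id, pf, u = u)
}

#' Generate a toy multi-species alignment around a UTR
#'
#' Inside the listed conserved k-windows every species copies the
#' reference; outside, each non-reference letter mutates independently to a
#' different base with probability `mutation_rate_outside` and is deleted
#' (gap) with probability `indel_rate`.  No insertion columns are created,
#' so the column space equals the UTR coordinates.
#'
#' @param utr The reference [utr_record()].
#' @param species Species names; must include `ref_species`.
#' @param conserved_windows 0-based starts of k-windows to conserve.
#' @param k Window length (default 7).
#' @param mutation_rate_outside Per-letter substitution probability outside
#'   conserved windows (default 0.5).
#' @param indel_rate Per-letter deletion probability outside conserved
#'   windows (default 0).
#' @param ref_species Reference species (default first of `species`).
#' @param rng_seed Optional integer seed.
#' @return An [aligned_utr()].
#' @export
gen_toy_alignment <- function(utr, species, conserved_windows, k = 7L,
                              mutation_rate_outside = 0.5, indel_rate = 0,
                              ref_species = species[1L], rng_seed = NULL) {
  if (!ref_species %in% species) stop("species must include the reference")
  run <- function() {
    L <- utr$length
    ref_ch <- .chars(utr$sequence)
    keep <- rep(FALSE, L)
    for (w in conserved_windows) {
      if (w < 0L || w + k > L) stop("conserved window outside the UTR")
      keep[(w + 1L):(w + k)] <- TRUE
    }
    rows <- setNames(vector("list", length(species)), species)
    for (sp in species) {
      if (sp == ref_species) { rows[[sp]] <- utr$sequence; next }
      ch <- ref_ch
      free <- which(!keep)
      mut <- free[runif(length(free)) < mutation_rate_outside]
      for (i in mut) ch[i] <- sample(setdiff(.BASES, ch[i]), 1L)
      if (indel_rate > 0) {
        del <- free[runif(length(free)) < indel_rate]
        ch[del] <- .GAP
      }
      rows[[sp]] <- paste(ch, collapse = "")
    }
    aligned_utr(utr$gene_id, ref_species, unlist(rows))
  }
  if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
}

#' Convert an aligned UTR into one MAF block
#'
#' Rows are named `<species>.<gene_id>` so that the species comes back out
#' of [read_maf()]'s source-name truncation rule; coordinates are the
#' 0-based ungapped extents on the + strand.
#'
#' @param aln An [aligned_utr()].
#' @return A MAF block as used by [read_maf()] / [write_maf()].
#' @export
alignment_to_maf_block <- function(aln) {
  sizes <- vapply(aln$rows,
                  function(r) nchar(gsub(.GAP, "", r, fixed = TRUE)), 0L)
  list(score = 0, line = NA_integer_,
       rows = data.frame(src = paste0(names(aln$rows), ".", aln$gene_id),
                         species = names(aln$rows),
                         start = 0L, size = unname(sizes), strand = "+",
                         src_size = unname(sizes),
                         text = unname(aln$rows),
                         stringsAsFactors = FALSE))
}

# ---------------------------------------------------------------------------
# full benchmark generator

#' Specification of a synthetic benchmark
#'
#' Describes a synthetic twin of a CLIP-style evaluation dataset: miRNAs,
#' genes split into a bound half (functional pairs get planted sites there)
#' and an unbound half (non-functional pairs are sampled there and receive
#' decoy sites), plus per-pair expression fold changes.
#'
#' Two scenarios control the planted-site properties.  In the
#' `"highly_conserved"` scenario functional sites are both conserved and
#' accessible and decoy sites violate conservation (mostly accessible-only,
#' some conserved-only, some neither, per `decoy_type_probs`).  In the
#' `"weakly_conserved"` scenario functional sites are accessible but NOT
#' conserved, while decoys are never accessible and are often conserved,
#' which by design makes conservation-filtered rankings uninformative.
#'
#' @param rng_seed Integer seed; all randomness flows from it.
#' @param scenario `"highly_conserved"` or `"weakly_conserved"`.
#' @param n_mirnas,n_genes Numbers of miRNAs and genes.
#' @param n_functional,n_nonfunctional Numbers of labeled pairs (equal by
#'   default: balanced design).
#' @param utr_length_range Integer pair of UTR lengths (uniform draw).
#' @param composition Base composition of the background sequence.
#' @param functional_sites,decoy_sites Planted sites per functional /
#'   non-functional pair (recycled to the pair counts).
#' @param decoy_type_probs Named probabilities over decoy site types
#'   `access_only`, `cons_only`, `neither`; defaults depend on the
#'   scenario.
#' @param effect Mean downregulation of functional pairs: their log2 fold
#'   change is `-effect` plus noise (log2 units, default 0.5).
#' @param noise_sd Standard deviation of the expression noise (default
#'   0.3).
#' @param species Aligned species (reference first; default the Selected-4
#'   ladder).
#' @param seed_start,seed_len Seed definition (defaults 2 and 7).
#' @param p_hi,p_lo Unpaired probabilities for accessible / background
#'   stretches.
#' @param mutation_rate Substitution rate outside conserved windows.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(rng_seed = 1L,
                         scenario = c("highly_conserved", "weakly_conserved"),
                         n_mirnas = 50L, n_genes = 400L,
                         n_functional = 400L,
                         n_nonfunctional = n_functional,
                         utr_length_range = c(300L, 600L),
                         composition = rep(0.25, 4),
                         functional_sites = 1L, decoy_sites = 1L,
                         decoy_type_probs = NULL,
                         effect = 0.5, noise_sd = 0.3,
                         species = selected_species_ladder(4L),
                         seed_start = 2L, seed_len = 7L,
                         p_hi = 0.9, p_lo = 0.01,
                         mutation_rate = 0.5) {
  scenario <- match.arg(scenario)
  if (is.null(decoy_type_probs)) {
    decoy_type_probs <- if (scenario == "highly_conserved")
      c(access_only = 0.6, cons_only = 0.25, neither = 0.15)
    else c(cons_only = 0.6, neither = 0.4)
  }
  types <- names(decoy_type_probs)
  if (!all(types %in% c("access_only", "cons_only", "neither")))
    stop("decoy types must be among access_only, cons_only, neither")
  stopifnot(abs(sum(composition) - 1) < 1e-8,
            length(utr_length_range) == 2L,
            utr_length_range[1L] >= 8L * seed_len)
  n_bound <- n_genes %/% 2L
  per_gene <- ceiling(n_functional / n_bound)
  if (per_gene > n_mirnas)
    stop("too many functional pairs per bound gene for distinct miRNAs")
  if (n_nonfunctional > (n_genes - n_bound) * n_mirnas)
    stop("non-functional universe too small")
  structure(list(rng_seed = as.integer(rng_seed), scenario = scenario,
                 n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 n_functional = as.integer(n_functional),
                 n_nonfunctional = as.integer(n_nonfunctional),
                 utr_length_range = as.integer(utr_length_range),
                 composition = composition,
                 functional_sites = as.integer(functional_sites),
                 decoy_sites = as.integer(decoy_sites),
                 decoy_type_probs = decoy_type_probs,
                 effect = effect, noise_sd = noise_sd,
                 species = species, ref_species = species[1L],
                 seed_start = as.integer(seed_start),
                 seed_len = as.integer(seed_len),
                 p_hi = p_hi, p_lo = p_lo,
                 mutation_rate = mutation_rate),
            class = "fixture_spec")
}

#' Generate a complete synthetic benchmark
#'
#' Produces every input the prediction and evaluation pipeline consumes:
#' UTRs with planted sites, miRNAs, unpaired-probability profiles,
#' per-gene alignments, labeled pairs and an expression table.  Functional
#' pairs receive planted sites whose accessibility/conservation follows the
#' scenario; non-functional pairs (sampled uniformly from the unbound
#' genes) receive decoy sites violating the scenario's defining property.
#' Planted sites within a gene are separated by at least the window length,
#' so their filter classification is exact by construction.  Expression is
#' `-effect + noise` for functional pairs and pure noise otherwise.  Two
#' runs with equal specs produce identical objects (and byte-identical
#' files through [write_benchmark_files()]).
#'
#' @param spec A [fixture_spec()].
#' @return Object of class `paccmit_benchmark`: list with `spec`, `utrs`,
#'   `mirnas`, `profiles`, `alignments`, `pairs`, `expression`, `sites`
#'   (per-site bookkeeping with accessibility/conservation flags).
#' @export
gen_benchmark <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$rng_seed, .gen_benchmark_impl(spec))
}

.gen_benchmark_impl <- function(spec) {
  k <- spec$seed_len
  # miRNAs with pairwise-distinct seed words (avoids cross-matching between
  # planted sites of different miRNAs)
  mirna_ids <- sprintf("mir%03d", seq_len(spec$n_mirnas))
  mirnas <- list(); words <- character(0)
  for (id in mirna_ids) {
    repeat {
      seq <- paste(sample(c("A", "C", "G", "U"), 22L, replace = TRUE),
                   collapse = "")
      m <- mirna(id, seq, spec$seed_start, k)
      w <- seed_word(m)$word
      if (!w %in% words) break
    }
    mirnas[[id]] <- m; words <- c(words, w)
  }
  names(words) <- mirna_ids

  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  lens <- sample(spec$utr_length_range[1L]:spec$utr_length_range[2L],
                 spec$n_genes, replace = TRUE)
  utrs <- setNames(lapply(seq_len(spec$n_genes), function(i)
    utr_record(gene_ids[i], .gen_seq(lens[i], spec$composition))), gene_ids)

  n_bound <- spec$n_genes %/% 2L
  bound <- gene_ids[seq_len(n_bound)]
  unbound <- gene_ids[(n_bound + 1L):spec$n_genes]

  per_gene <- ceiling(spec$n_functional / n_bound)
  j <- seq_len(spec$n_functional) - 1L
  fun_pairs <- data.frame(mirna_id = mirna_ids[j %% spec$n_mirnas + 1L],
                          gene_id = bound[j %/% per_gene + 1L],
                          label = "functional", stringsAsFactors = FALSE)
  neg_pairs <- .sample_pairs(mirna_ids, unbound, spec$n_nonfunctional)
  pairs <- rbind(fun_pairs, neg_pairs)

  # site bookkeeping: one row per planted site
  n_sites_fun <- rep_len(spec$functional_sites, spec$n_functional)
  n_sites_dec <- rep_len(spec$decoy_sites, spec$n_nonfunctional)
  fun_acc <- TRUE
  fun_cons <- spec$scenario == "highly_conserved"
  dec_types <- sample(names(spec$decoy_type_probs),
                      spec$n_nonfunctional, replace = TRUE,
                      prob = spec$decoy_type_probs)
  sites <- list()
  occupied <- setNames(vector("list", spec$n_genes), gene_ids)
  place_sites <- function(gene_id, n, word) {
    L <- utrs[[gene_id]]$length
    cand <- 0:(L - k)
    for (occ in occupied[[gene_id]])
      cand <- cand[abs(cand - occ) >= k]
    if (n == 0L) return(integer(0))
    pick <- function(v) v[sample.int(length(v), 1L)]  # sample() scalar trap
    if (length(cand) == 0L)
      stop("cannot place ", n, " non-overlapping sites in gene ", gene_id)
    pos <- pick(cand)
    while (length(pos) < n) {
      cand <- cand[vapply(cand, function(x) all(abs(x - pos) >= k), TRUE)]
      if (length(cand) == 0L)
        stop("cannot place ", n, " non-overlapping sites in gene ", gene_id)
      pos <- sort(c(pos, pick(cand)))
    }
    occupied[[gene_id]] <<- c(occupied[[gene_id]], pos)
    utrs[[gene_id]] <<- plant_matches(utrs[[gene_id]], word, pos)
    pos
  }
  add_site_rows <- function(pair_row, pos, accessible, conserved) {
    sites[[length(sites) + 1L]] <<- data.frame(
      mirna_id = pair_row$mirna_id, gene_id = pair_row$gene_id,
      position = pos, accessible = accessible, conserved = conserved,
      label = pair_row$label, stringsAsFactors = FALSE)
  }
  for (i in seq_len(spec$n_functional)) {
    pr <- fun_pairs[i, ]
    pos <- place_sites(pr$gene_id, n_sites_fun[i], words[[pr$mirna_id]])
    add_site_rows(pr, pos, fun_acc, fun_cons)
  }
  for (i in seq_len(spec$n_nonfunctional)) {
    pr <- neg_pairs[i, ]
    acc <- dec_types[i] == "access_only"
    cons <- dec_types[i] == "cons_only"
    pos <- place_sites(pr$gene_id, n_sites_dec[i], words[[pr$mirna_id]])
    add_site_rows(pr, pos, acc, cons)
  }
  sites <- do.call(rbind, sites)

  profiles <- setNames(vector("list", spec$n_genes), gene_ids)
  alignments <- setNames(vector("list", spec$n_genes), gene_ids)
  for (g in gene_ids) {
    gs <- sites[sites$gene_id == g, , drop = FALSE]
    profiles[[g]] <- gen_pfree_profile(
      g, utrs[[g]]$length, gs$position[gs$accessible], k = k,
      hi = spec$p_hi, lo = spec$p_lo)
    alignments[[g]] <- gen_toy_alignment(
      utrs[[g]], spec$species, gs$position[gs$conserved], k = k,
      mutation_rate_outside = spec$mutation_rate,
      ref_species = spec$ref_species)
  }

  noise <- rnorm(nrow(pairs), mean = 0, sd = spec$noise_sd)
  expression <- data.frame(
    mirna_id = pairs$mirna_id, gene_id = pairs$gene_id,
    log2fc = ifelse(pairs$label == "functional", -spec$effect, 0) + noise,
    stringsAsFactors = FALSE)

  structure(list(spec = spec, utrs = utrs, mirnas = mirnas,
                 profiles = profiles, alignments = alignments,
                 pairs = pairs, expression = expression, sites = sites),
            class = "paccmit_benchmark")
}

# ---------------------------------------------------------------------------
# file emission

.write_tsv <- function(df, path, num_cols = character(0)) {
  cols <- names(df)
  body <- vapply(seq_len(nrow(df)), function(i) {
    cells <- vapply(cols, function(cn) {
      v <- df[[cn]][i]
      if (cn %in% num_cols) sprintf("%.6e", v) else as.character(v)
    }, "")
    paste(cells, collapse = "\t")
  }, "")
  .write_lines_atomic(c(paste(cols, collapse = "\t"), body), path)
}

#' Read a labeled-pair TSV (`mirna_id`, `gene_id`, `label`)
#' @param path TSV file.
#' @return Data frame.
#' @export
read_pairs_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character")
}

#' Read an expression TSV (`mirna_id`, `gene_id`, `log2fc`)
#' @param path TSV file.
#' @return Data frame.
#' @export
read_expression_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
}

#' Write every benchmark artifact to a directory
#'
#' Emits `utrs.fa`, `mirnas.fa`, `alignments.maf` (one block per gene),
#' `lunp/<gene_id>_lunp`, `pairs.tsv` and `expression.tsv` in exactly the
#' dialects the package readers accept.  Deterministic: equal benchmarks
#' give byte-identical trees.
#'
#' @param bench A `paccmit_benchmark` from [gen_benchmark()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark_files <- function(bench, dir) {
  dir.create(file.path(dir, "lunp"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(bench$utrs, file.path(dir, "utrs.fa"))
  write_fasta(bench$mirnas, file.path(dir, "mirnas.fa"))
  write_maf(lapply(bench$alignments, alignment_to_maf_block),
            file.path(dir, "alignments.maf"))
  for (g in names(bench$profiles))
    write_lunp(bench$profiles[[g]], file.path(dir, "lunp", paste0(g, "_lunp")))
  .write_tsv(bench$pairs, file.path(dir, "pairs.tsv"))
  .write_tsv(bench$expression, file.path(dir, "expression.tsv"),
             num_cols = "log2fc")
  invisible(dir)
}
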