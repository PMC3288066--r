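## seqio: readers/writers for FASTA, MAF, per-gene alignment FASTA and the
## prediction TSV, plus the in-memory data model they populate.
##
## Conventions: 0-based half-open coordinates internally; 3'UTRs stored as
## sense-strand mRNA DNA (U converted to T); alignments normalized to the
## reference + strand at read time.

# ---------------------------------------------------------------------------
# constructors

#' 3'UTR record
#'
#' One gene's 3'UTR as sense-strand mRNA sequence over the DNA alphabet
#' (A/C/G/T/N).  `U` is converted to `T` and lowercase to uppercase.
#'
#' @param gene_id Gene identifier.
#' @param sequence Nucleotide string, 5'->3'.
#' @return An object of class `utr_record` with fields `gene_id`, `sequence`
#'   and `length`.
#' @export
#' @examples
#' utr_record("g1", "acguACGT")$sequence
utr_record <- function(gene_id, sequence) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  seq <- .normalize_seq(sequence, "dna", paste0("UTR '", gene_id, "'"))
  if (nchar(seq) == 0L) stop("empty sequence for UTR '", gene_id, "'")
  structure(list(gene_id = gene_id, sequence = seq, length = nchar(seq)),
            class = "utr_record")
}

#' Mature miRNA record
#'
#' Mature miRNA sequence (RNA alphabet, 5'->3') together with its seed
#' definition.  The default seed covers miRNA positions 2-8 (a 7-mer), the
#' canonical seed used for target recognition; shorter, longer or shifted
#' seeds are supported through `seed_start`/`seed_len`.
#'
#' @param mirna_id miRNA identifier.
#' @param sequence RNA string (T converted to U).
#' @param seed_start 1-based first seed position (default 2).
#' @param seed_len Seed length in nucleotides (default 7).
#' @return An object of class `mirna`.
#' @export
mirna <- function(mirna_id, sequence, seed_start = 2L, seed_len = 7L) {
  stopifnot(is.character(mirna_id), length(mirna_id) == 1L, nzchar(mirna_id))
  seq <- .normalize_seq(sequence, "rna", paste0("miRNA '", mirna_id, "'"))
  seed_start <- as.integer(seed_start)
  seed_len <- as.integer(seed_len)
  if (seed_start < 1L || seed_len < 1L)
    stop("seed_start and seed_len must be >= 1")
  if (seed_start + seed_len - 1L > nchar(seq))
    stop(sprintf("seed window [%d, %d] outside miRNA '%s' (length %d)",
                 seed_start, seed_start + seed_len - 1L, mirna_id, nchar(seq)))
  structure(list(mirna_id = mirna_id, sequence = seq,
                 seed_start = seed_start, seed_len = seed_len),
            class = "mirna")
}

#' Gap-aligned 3'UTR across species
#'
#' Per-species aligned rows over a shared column space.  Ungapping the
#' reference row must reproduce the UTR sequence; species missing from the
#' underlying alignment are represented as all-gap rows.
#'
#' @param gene_id Gene identifier.
#' @param ref_species Name of the reference species (must be a row).
#' @param rows Named character vector of aligned strings (gap `-`).
#' @return An object of class `aligned_utr` with `n_columns` set.
#' @export
aligned_utr <- function(gene_id, ref_species, rows) {
  stopifnot(is.character(rows), !is.null(names(rows)))
  if (!ref_species %in% names(rows))
    stop("reference species '", ref_species, "' missing from rows")
  rows <- setNames(toupper(rows), names(rows))
  nc <- unique(nchar(rows))
  if (length(nc) != 1L)
    stop("aligned rows of unequal length for gene '", gene_id, "'")
  structure(list(gene_id = gene_id, ref_species = ref_species,
                 rows = rows, n_columns = nc),
            class = "aligned_utr")
}

#' Ungapped reference sequence of an aligned UTR
#' @param aln An `aligned_utr`.
#' @return Character scalar: the reference row with gaps removed.
#' @export
ungapped_ref <- function(aln) {
  gsub(.GAP, "", aln$rows[[aln$ref_species]], fixed = TRUE)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a FASTA file into UTR or miRNA records
#'
#' Identifiers are truncated at the first whitespace and must be unique.
#' With `alphabet = "dna"` records become [utr_record()]s (U -> T); with
#' `alphabet = "rna"` they become [mirna()]s (T -> U) with the given seed
#' definition.
#'
#' @param path FASTA file (wrapped or unwrapped).
#' @param alphabet `"dna"` or `"rna"`.
#' @param seed_start,seed_len Seed definition applied to miRNA records.
#' @return Named list of `utr_record` or `mirna` objects, input order kept.
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna"),
                       seed_start = 2L, seed_len = 7L) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate identifier '", dup[1L], "' in ", path, call. = FALSE)
  seqs <- unname(as.character(set))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- if (alphabet == "dna") utr_record(ids[i], seqs[i])
                else mirna(ids[i], seqs[i], seed_start, seed_len)
  }
  setNames(out, ids)
}

#' Write UTR or miRNA records as FASTA
#'
#' @param records List of `utr_record` or `mirna` objects.
#' @param path Output file.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- character(0)
  for (r in records) {
    id <- r$gene_id %||% r$mirna_id
    body <- r$sequence
    n <- nchar(body)
    starts <- seq(1L, max(n, 1L), by = width)
    lines <- c(lines, paste0(">", id),
               substring(body, starts, pmin(starts + width - 1L, n)))
  }
  .write_lines_atomic(lines, path)
}

#' Keep one record per gene: the longest 3'UTR
#'
#' Mirrors the common isoform rule of keeping, for each gene, the mRNA
#' isoform with the longest 3'UTR.  Records are expected to carry the gene
#' identity in `gene_id` (identical ids compete); ties keep the first seen.
#'
#' @param utrs List of `utr_record`s (possibly with repeated `gene_id`).
#' @return Named list with one record per `gene_id`.
#' @export
dedupe_longest <- function(utrs) {
  best <- list()
  for (u in utrs) {
    cur <- best[[u$gene_id]]
    if (is.null(cur) || u$length > cur$length) best[[u$gene_id]] <- u
  }
  best
}

# ---------------------------------------------------------------------------
# MAF

.maf_species <- function(src) sub("\\..*$", "", src)

#' Read a MAF (multiple alignment format) file
#'
#' UCSC dialect: `a` lines open a block, `s` lines carry
#' `src start size strand srcSize text`.  Starts are kept 0-based as MAF
#' specifies; on the `-` strand they count from the reverse-complemented
#' source, again as MAF specifies.  Other line types (`i`, `e`, `q`, `#`)
#' are ignored.
#'
#' @param path MAF file.
#' @return List of blocks; each block is a list with `score` and `rows`, a
#'   data frame with columns `src`, `species` (text before the first dot of
#'   `src`), `start`, `size`, `strand`, `src_size`, `text`.
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur) || nrow(cur$rows) == 0L) return(blocks)
    if (length(unique(nchar(cur$rows$text))) != 1L)
      stop("row text length mismatch in MAF block starting at line ",
           cur$line, call. = FALSE)
    c(blocks, list(cur))
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^a( |$)", ln)) {
      blocks <- flush(cur, blocks)
      score <- 0
      m <- regmatches(ln, regexec("score=([-0-9.eE+]+)", ln))[[1]]
      if (length(m) == 2L) score <- as.numeric(m[2L])
      cur <- list(score = score, line = i,
                  rows = data.frame(src = character(0), species = character(0),
                                    start = integer(0), size = integer(0),
                                    strand = character(0), src_size = integer(0),
                                    text = character(0)))
    } else if (grepl("^s( |\t)", ln)) {
      if (is.null(cur)) stop("'s' line outside a block at line ", i, call. = FALSE)
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) != 7L || is.na(suppressWarnings(as.integer(f[3L]))) ||
          is.na(suppressWarnings(as.integer(f[4L]))) || !f[5L] %in% c("+", "-"))
        stop("malformed 's' line at line ", i, call. = FALSE)
      cur$rows <- rbind(cur$rows, data.frame(
        src = f[2L], species = .maf_species(f[2L]),
        start = as.integer(f[3L]), size = as.integer(f[4L]),
        strand = f[5L], src_size = as.integer(f[6L]),
        text = toupper(f[7L])))
    } else if (grepl("^\\s*$", ln)) {
      blocks <- flush(cur, blocks)
      cur <- NULL
    }
    # other line types ignored
  }
  flush(cur, blocks)
}

#' Write alignment blocks as MAF
#'
#' Canonical single-space formatting; `read_maf(write_maf(x))` is lossless
#' for the retained fields.
#'
#' @param blocks List of blocks as returned by [read_maf()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  lines <- c("##maf version=1", "")
  for (b in blocks) {
    lines <- c(lines, sprintf("a score=%.6f", b$score))
    for (j in seq_len(nrow(b$rows))) {
      r <- b$rows[j, ]
      lines <- c(lines, sprintf("s %s %d %d %s %d %s", r$src, r$start,
                                r$size, r$strand, r$src_size, r$text))
    }
    lines <- c(lines, "")
  }
  .write_lines_atomic(lines, path)
}

# ---------------------------------------------------------------------------
# stitching MAF blocks into a per-gene alignment

#' Assemble a per-gene alignment from MAF blocks
#'
#' Restricts blocks to the reference interval of one 3'UTR and concatenates
#' their columns into an [aligned_utr()].  Reverse-strand reference rows are
#' reverse-complemented into + orientation first.  Reference positions not
#' covered by any block are emitted as columns in which all non-reference
#' species are gaps (the reference letter is taken from `utr`).  Insertion
#' columns (reference gap) are kept only when they fall strictly between two
#' retained reference positions.
#'
#' @param blocks MAF blocks (see [read_maf()]).
#' @param utr The reference [utr_record()]; supplies uncovered letters and is
#'   checked against the stitched reference row.
#' @param ref_species Reference species name (matched against the `species`
#'   field of the rows, i.e. `src` truncated at the first dot).
#' @param ref_interval Integer pair `c(start, end)`: 0-based half-open
#'   interval on the reference + strand corresponding to `utr`.
#' @param species Character vector of species to retain (reference included
#'   automatically); species absent from all blocks come out as all-gap rows.
#' @return An [aligned_utr()].
#' @export
stitch_aligned_utr <- function(blocks, utr, ref_species, ref_interval,
                               species) {
  a <- as.integer(ref_interval[1L]); b <- as.integer(ref_interval[2L])
  if (b - a != utr$length)
    stop("ref_interval width does not match UTR length")
  species <- union(ref_species, species)
  utr_chars <- .chars(utr$sequence)

  pieces <- list()   # each: list(start, end, cols = matrix species x ncol)
  for (blk in blocks) {
    rows <- blk$rows
    ri <- which(rows$species == ref_species)
    if (length(ri) == 0L) next
    if (length(ri) > 1L)
      stop("MAF block has multiple rows for reference species '",
           ref_species, "'")
    ref <- rows[ri, ]
    texts <- setNames(rows$text, rows$species)
    if (ref$strand == "-") {               # normalize to ref + strand
      plus_start <- ref$src_size - ref$start - ref$size
      texts <- vapply(texts, .revcomp_dna, "")
    } else plus_start <- ref$start

    ref_ch <- .chars(texts[[ref_species]])
    is_ref <- ref_ch != .GAP
    refpos <- rep(NA_integer_, length(ref_ch))
    refpos[is_ref] <- plus_start + seq_len(sum(is_ref)) - 1L

    keep_ref <- is_ref & refpos >= a & refpos < b
    if (!any(keep_ref)) next
    # insertion columns strictly between two kept reference columns
    idx_keep <- which(keep_ref)
    keep <- keep_ref
    gaps <- which(!is_ref)
    for (g in gaps) {
      prv <- idx_keep[idx_keep < g]
      nxt <- idx_keep[idx_keep > g]
      if (length(prv) && length(nxt) &&
          refpos[max(prv)] + 1L == refpos[min(nxt)]) keep[g] <- TRUE
    }
    cols <- do.call(rbind, lapply(species, function(sp) {
      if (sp %in% names(texts)) .chars(texts[[sp]])[keep]
      else rep(.GAP, sum(keep))
    }))
    rownames(cols) <- species
    pieces[[length(pieces) + 1L]] <-
      list(start = min(refpos[keep], na.rm = TRUE),
           end = max(refpos[keep], na.rm = TRUE) + 1L, cols = cols)
  }

  if (length(pieces) > 0L) {
    ord <- order(vapply(pieces, `[[`, 0L, "start"))
    pieces <- pieces[ord]
    ends <- vapply(pieces, `[[`, 0L, "end")
    starts <- vapply(pieces, `[[`, 0L, "start")
    if (length(pieces) > 1L && any(starts[-1L] < ends[-length(ends)]))
      stop("overlapping MAF blocks on the reference for gene '",
           utr$gene_id, "'", call. = FALSE)
  }

  # concatenate, padding uncovered reference stretches with all-gap columns
  out <- matrix(character(0), nrow = length(species),
                dimnames = list(species, NULL))
  pad <- function(from, to) {       # ref positions [from, to) uncovered
    if (to <= from) return(NULL)
    m <- matrix(.GAP, nrow = length(species), ncol = to - from,
                dimnames = list(species, NULL))
    m[ref_species, ] <- utr_chars[(from - a + 1L):(to - a)]
    m
  }
  cursor <- a
  for (p in pieces) {
    out <- cbind(out, pad(cursor, p$start), p$cols)
    cursor <- p$end
  }
  out <- cbind(out, pad(cursor, b))

  rows <- apply(out, 1L, paste, collapse = "")
  aln <- aligned_utr(utr$gene_id, ref_species, rows)
  if (ungapped_ref(aln) != utr$sequence)
    stop("stitched reference row disagrees with UTR sequence for gene '",
         utr$gene_id, "'", call. = FALSE)
  aln
}

#' Read a pre-stitched per-gene alignment FASTA
#'
#' Alternative input to MAF: one FASTA per gene whose records are named by
#' species and already share a common column space (gap `-`).
#'
#' @param path Alignment FASTA.
#' @param gene_id Gene identifier to attach.
#' @param ref_species Reference species (must be one of the records).
#' @return An [aligned_utr()].
#' @export
read_alignment_fasta <- function(path, gene_id, ref_species) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment FASTA: ", path)
  rows <- setNames(as.character(set), sub("\\s.*$", "", names(set)))
  aligned_utr(gene_id, ref_species, rows)
}

#' Write an aligned UTR as alignment FASTA
#' @param aln An [aligned_utr()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  lines <- as.vector(rbind(paste0(">", names(aln$rows)), unname(aln$rows)))
  .write_lines_atomic(lines, path)
}

# ---------------------------------------------------------------------------
# prediction TSV

.PRED_COLS <- c("mirna_id", "gene_id", "c_filter", "t_filter",
                "p_word", "p_sh", "rank")

#' Write ranked predictions as TSV
#'
#' Columns: `mirna_id, gene_id, c_filter, t_filter, p_word, p_sh, rank`.
#' Floats are printed in scientific notation with 6 significant digits after
#' the point; re-reading reproduces the values at printed precision and
#' `write(read(x))` is byte-identical.
#'
#' @param scores Ranked prediction data frame (see [rank_predictions()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(scores, path) {
  if (nrow(scores) > 0L && is.null(scores$rank))
    stop("predictions must be ranked before writing (see rank_predictions)")
  header <- paste(.PRED_COLS, collapse = "\t")
  if (nrow(scores) == 0L) return(.write_lines_atomic(header, path))
  body <- sprintf("%s\t%s\t%d\t%d\t%.6e\t%.6e\t%d",
                  scores$mirna_id, scores$gene_id,
                  as.integer(scores$c_filter), as.integer(scores$t_filter),
                  scores$p_word, scores$p_sh, as.integer(scores$rank))
  .write_lines_atomic(c(header, body), path)
}

#' Read a prediction TSV written by [write_predictions()]
#' @param path Prediction TSV.
#' @return Data frame with the prediction columns.
#' @export
read_predictions <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "integer", "numeric", "numeric",
                                         "integer"))
  if (!identical(names(df), .PRED_COLS))
    stop("unexpected prediction TSV header in ", path)
  df
}
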