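## accessibility: per-position unpaired-probability profiles (RNAplfold
## `_lunp` dialect) and the accessible-window classification.
##
## A k-window is accessible iff at least one contained u-mer (u = 4 by
## default) is unpaired with probability P_free >= P_cutoff; the comparison
## is inclusive and the optimized default cutoff is 0.2.

#' Unpaired-probability profile of one 3'UTR
#'
#' `p_free[i]` is the probability that the u-mer ENDING at 1-based position
#' `i` is fully unpaired in the thermodynamic ensemble; entries for `i < u`
#' are undefined (`NA`), as are positions the producing tool could not
#' evaluate.  `window_W` and `span_L` record the folding window and maximum
#' pairing span the profile was computed with (defaults 80 and 40).
#'
#' @param gene_id Gene identifier.
#' @param p_free Numeric vector, one entry per UTR position, values in
#'   `[0, 1]` or `NA`.
#' @param u Stretch length (default 4).
#' @param window_W,span_L Provenance integers.
#' @return Object of class `pfree_profile`.
#' @export
pfree_profile <- function(gene_id, p_free, u = 4L, window_W = 80L,
                          span_L = 40L) {
  u <- as.integer(u)
  if (u < 1L) stop("u must be >= 1")
  bad <- which(!is.na(p_free) & (p_free < 0 | p_free > 1))
  if (length(bad) > 0L)
    stop(sprintf("p_free value %g at position %d outside [0, 1]",
                 p_free[bad[1L]], bad[1L]), call. = FALSE)
  if (u <= length(p_free) && u > 1L) p_free[seq_len(u - 1L)] <- NA_real_
  structure(list(gene_id = gene_id, u = u, p_free = as.numeric(p_free),
                 window_W = as.integer(window_W), span_L = as.integer(span_L)),
            class = "pfree_profile")
}

#' Parse an RNAplfold `_lunp` table
#'
#' Whitespace-separated table: comment lines start with `#`, data rows carry
#' the 1-based end position `i` followed by one column per stretch length
#' `l = 1, 2, ...`.  The column for stretch length `u` is extracted; `NA`
#' cells become undefined positions.  `W=` / `L=` annotations in the header
#' comments are picked up as provenance when present.
#'
#' @param path `_lunp` file.
#' @param u Stretch length column to extract (default 4).
#' @param gene_id Gene identifier; defaults to the file name with a trailing
#'   `_lunp` stripped.
#' @return A [pfree_profile()].
#' @export
parse_lunp <- function(path, u = 4L, gene_id = NULL) {
  u <- as.integer(u)
  gene_id <- gene_id %||% sub("_lunp$", "", basename(path))
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  data <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  W <- 80L; L <- 40L
  for (h in hdr) {
    mW <- regmatches(h, regexec("W=([0-9]+)", h))[[1]]
    mL <- regmatches(h, regexec("L=([0-9]+)", h))[[1]]
    if (length(mW) == 2L) W <- as.integer(mW[2L])
    if (length(mL) == 2L) L <- as.integer(mL[2L])
  }
  if (length(data) == 0L) stop("no data rows in ", path)
  fields <- strsplit(trimws(data), "[ \t]+")
  n <- length(fields)
  p_free <- rep(NA_real_, n)
  for (r in seq_len(n)) {
    f <- fields[[r]]
    if (length(f) < u + 1L)
      stop(sprintf("row %d of %s has no column for stretch length u=%d",
                   r, path, u), call. = FALSE)
    i <- as.integer(f[1L])
    if (is.na(i) || i < 1L || i > n)
      stop("bad position index in row ", r, " of ", path, call. = FALSE)
    v <- f[u + 1L]
    if (v != "NA") {
      x <- suppressWarnings(as.numeric(v))
      if (is.na(x)) stop("unreadable value '", v, "' in row ", r, " of ", path)
      if (x < 0 || x > 1)
        stop(sprintf("p_free value %g in row %d of %s outside [0, 1]",
                     x, r, path), call. = FALSE)
      p_free[i] <- x
    }
  }
  pfree_profile(gene_id, p_free, u = u, window_W = W, span_L = L)
}

#' Write a profile in the `_lunp` dialect
#'
#' Emits columns for stretch lengths `1 .. u`; only column `u` carries the
#' profile values, shorter stretches are written as `NA` (they are not part
#' of the data model).  `parse_lunp(write_lunp(x), u)` reproduces `x`.
#'
#' @param profile A [pfree_profile()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_lunp <- function(profile, path) {
  u <- profile$u
  n <- length(profile$p_free)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.9g", x))
  lines <- c(sprintf("#unpaired probabilities W=%d L=%d",
                     profile$window_W, profile$span_L),
             paste(c("#i$", paste0("l=", 1L), if (u > 1L) 2:u),
                   collapse = "\t"))
  for (i in seq_len(n)) {
    cells <- rep("NA", u)
    cells[u] <- fmt(profile$p_free[i])
    lines <- c(lines, paste(c(i, cells), collapse = "\t"))
  }
  .write_lines_atomic(lines, path)
}

#' Load all `<gene_id>_lunp` profiles from a directory
#' @param dir Directory of `_lunp` files.
#' @param u Stretch length (default 4).
#' @return Named list of [pfree_profile()]s keyed by gene id.
#' @export
read_lunp_dir <- function(dir, u = 4L) {
  files <- list.files(dir, pattern = "_lunp$", full.names = TRUE)
  profs <- lapply(files, parse_lunp, u = u)
  setNames(profs, vapply(profs, `[[`, "", "gene_id"))
}

#' Maximum unpaired probability of the u-mers contained in a window
#'
#' A k-window starting at 0-based `start` contains the `k - u + 1` u-mers
#' ending at 1-based positions `start + u .. start + k`.  Undefined entries
#' are skipped; if every contained entry is undefined the result is `NA`.
#'
#' @param profile A [pfree_profile()].
#' @param start 0-based window start.
#' @param k Window length (>= `profile$u`).
#' @return Numeric scalar, or `NA` if undefined.
#' @export
window_pfree <- function(profile, start, k) {
  u <- profile$u
  if (k < u) stop("window length k must be >= stretch length u")
  L <- length(profile$p_free)
  if (start < 0L || start + k > L)
    stop(sprintf("window [%d, %d) outside profile of length %d",
                 start, start + k, L))
  v <- profile$p_free[(start + u):(start + k)]
  if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
}

#' Is a window accessible?
#'
#' TRUE iff the maximum contained u-mer unpaired probability is `>=`
#' `p_cutoff` (inclusive).  Windows whose contained entries are all
#' undefined are classified inaccessible.
#'
#' @inheritParams window_pfree
#' @param p_cutoff Probability cutoff (default 0.2).
#' @return Logical scalar.
#' @export
is_accessible <- function(profile, start, k, p_cutoff = 0.2) {
  m <- window_pfree(profile, start, k)
  !is.na(m) && m >= p_cutoff
}

#' Accessibility classification of every k-window
#'
#' Vectorized equivalent of calling [is_accessible()] on each window start.
#'
#' @param profile A [pfree_profile()].
#' @param k Window length.
#' @param p_cutoff Probability cutoff (default 0.2).
#' @return Logical vector over 0-based window starts `0 .. L-k`.
#' @export
accessible_window_flags <- function(profile, k, p_cutoff = 0.2) {
  u <- profile$u
  if (k < u) stop("window length k must be >= stretch length u")
  pf <- profile$p_free
  L <- length(pf)
  if (L < k) return(logical(0))
  n <- L - k + 1L
  m <- rep(-Inf, n)
  for (off in u:k) {                    # running max over contained u-mers
    v <- pf[(1:n) + off - 1L]
    v[is.na(v)] <- -Inf
    m <- pmax(m, v)
  }
  m >= p_cutoff
}
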