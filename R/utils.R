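## Internal helpers shared across modules.  All sequence strings are kept as
## plain character scalars; positions are 0-based half-open internally.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a sequence string into single characters
#' @noRd
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Reverse complement of a DNA string (gaps and N preserved)
#' @noRd
.revcomp_dna <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) paste(rev(.chars(s)), collapse = ""), "",
         USE.NAMES = FALSE)
}

#' Normalize a raw sequence to the requested alphabet
#'
#' Uppercases, converts U<->T, and validates the residue set.  `what` is used
#' only for the error message.
#' @noRd
.normalize_seq <- function(seq, alphabet = c("dna", "rna"), what = "sequence") {
  alphabet <- match.arg(alphabet)
  s <- toupper(seq)
  s <- if (alphabet == "dna") chartr("U", "T", s) else chartr("T", "U", s)
  allowed <- if (alphabet == "dna") c("A", "C", "G", "T", "N")
             else c("A", "C", "G", "U", "N")
  ch <- .chars(s)
  bad <- which(!ch %in% allowed)
  if (length(bad) > 0L) {
    stop(sprintf("illegal character '%s' at position %d in %s",
                 ch[bad[1L]], bad[1L], what), call. = FALSE)
  }
  s
}

#' Sliding window of k-mer strings over a sequence
#'
#' Returns all windows, including those containing N; callers mask N windows
#' via [.nfree_mask()].
#' @noRd
.windows <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  substring(seq, 1:(L - k + 1L), k:L)
}

#' Logical mask over window starts: TRUE where the k-window contains no N
#' @noRd
.nfree_mask <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(logical(0))
  n <- L - k + 1L
  ch <- .chars(seq)
  if (!any(ch == "N")) return(rep(TRUE, n))
  cs <- c(0L, cumsum(ch == "N"))
  (cs[(1:n) + k] - cs[1:n]) == 0L
}

#' Count of TRUE entries per k-window of a logical position vector
#' @noRd
.window_all <- function(ok, k) {
  L <- length(ok)
  if (L < k) return(logical(0))
  n <- L - k + 1L
  cs <- c(0L, cumsum(ok))
  (cs[(1:n) + k] - cs[1:n]) == k
}

#' Write lines to `path` atomically (temp file + rename)
#' @noRd
.write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  con <- file(tmp, open = "wb")          # "wb": byte-identical across platforms
  writeLines(lines, con, sep = "\n")
  close(con)
  if (!file.rename(tmp, path)) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}
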