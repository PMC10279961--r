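# Low-level nucleotide string helpers shared across modules.
# Sequences are plain uppercase character scalars; alignments are character
# matrices (rows = samples, single characters, rownames = sample ids).

IUPAC_CODES <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")
BASES <- c("A", "C", "G", "T")

.comp_map <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
               R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
               B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented to their mirror codes; gaps are
#' preserved.
#'
#' @param x Character scalar (nucleotide sequence) or character vector of
#'   single residues.
#' @return Object of the same shape as `x`, reverse complemented.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  if (length(x) == 1L && nchar(x[1L]) > 1L) {
    ch <- strsplit(x, "", fixed = TRUE)[[1L]]
    return(paste(rev(unname(.comp_map[ch])), collapse = ""))
  }
  rev(unname(.comp_map[x]))
}

# Normalize a sequence: uppercase, T for U, validate residues.
normalize_seq <- function(x, what = "sequence") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  ch <- unique(strsplit(x, "", fixed = TRUE)[[1L]])
  bad <- setdiff(ch, IUPAC_CODES)
  if (length(bad) > 0L) {
    stop(sprintf("%s contains non-IUPAC residues: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  x
}

# Rotate a circular sequence left by `offset` positions (0 <= offset < n).
rotate_seq <- function(x, offset) {
  n <- nchar(x)
  offset <- ((offset %% n) + n) %% n
  if (offset == 0L) return(x)
  paste0(substr(x, offset + 1L, n), substr(x, 1L, offset))
}

#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T). Ambiguity codes and gaps are excluded
#' from both numerator and denominator.
#'
#' @param x Character scalar, a [circular_genome()], or a character vector of
#'   single residues.
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' gc_content("ATGCN")  # 0.5, N excluded
gc_content <- function(x) {
  if (inherits(x, "circular_genome")) x <- x$seq
  if (length(x) == 1L) x <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  gc <- sum(x %in% c("G", "C"))
  at <- sum(x %in% c("A", "T"))
  if (gc + at == 0L) {
    stop("GC content undefined: no unambiguous A/C/G/T residues", call. = FALSE)
  }
  gc / (gc + at)
}

# Split a string into a character vector of residues.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# 1-based inclusive span helpers ------------------------------------------

span <- function(start, end) {
  stopifnot(start >= 1L, end >= start)
  c(start = as.integer(start), end = as.integer(end))
}

span_len <- function(s) s[["end"]] - s[["start"]] + 1L
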