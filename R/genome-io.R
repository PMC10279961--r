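# File IO: FASTA (via Biostrings), GenBank flat files (minimal reader),
# sample-group tables, alignments, relaxed PHYLIP, BED.

#' Construct a circular genome object
#'
#' Container for a (usually circular) plastid genome sequence with optional
#' feature annotations.
#'
#' @param id Sequence identifier.
#' @param seq Nucleotide string (IUPAC codes; normalized to uppercase).
#' @param circular Logical; is the molecule circular?
#' @param features Optional data.frame with columns `name`, `start`, `end`
#'   (1-based inclusive), `strand` ("+"/"-") and `kind`
#'   ("gene", "tRNA", "rRNA", "other").
#' @return Object of class `circular_genome`.
#' @export
circular_genome <- function(id, seq, circular = TRUE, features = NULL) {
  seq <- normalize_seq(seq, what = sprintf("genome '%s'", id))
  if (nchar(seq) == 0L) stop("empty genome sequence", call. = FALSE)
  if (!is.null(features)) {
    stopifnot(all(c("name", "start", "end", "strand", "kind") %in%
                    names(features)))
    n <- nchar(seq)
    if (any(features$start < 1L) || any(features$end > 2L * n)) {
      stop("feature coordinates outside the genome", call. = FALSE)
    }
  }
  structure(list(id = id, seq = seq, circular = isTRUE(circular),
                 features = features),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %s bp%s, %d features\n", x$id,
              format(nchar(x$seq), big.mark = ","),
              if (x$circular) " (circular)" else " (linear)",
              if (is.null(x$features)) 0L else nrow(x$features)))
  invisible(x)
}

#' Read sequences from a FASTA file
#'
#' @param path Path to a (multi-)FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read genomes from FASTA as circular genome objects
#'
#' @param path FASTA file path.
#' @param circular Logical flag applied to every record.
#' @return List of [circular_genome()] objects, named by id.
#' @export
read_genomes <- function(path, circular = TRUE) {
  seqs <- read_fasta(path)
  out <- lapply(names(seqs), function(id) {
    circular_genome(id, seqs[[id]], circular = circular)
  })
  names(out) <- names(seqs)
  out
}

# GenBank flat file -------------------------------------------------------

#' Read a GenBank flat file
#'
#' Minimal reader for GenBank nucleotide records: locus name and length,
#' gene/tRNA/rRNA feature names with locations, and the ORIGIN sequence.
#' Supports multi-record files, `complement(...)` and `join(...)` locations
#' (reduced to their outer span).
#'
#' @param path Path to a GenBank flat file (plain text).
#' @return List of [circular_genome()] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(TRUE, grepl("^//\\s*$", lines)[-length(lines)])))
  out <- list()
  for (rec in recs) {
    if (!any(grepl("^LOCUS", rec))) next
    out[[length(out) + 1L]] <- .parse_genbank_record(rec)
  }
  names(out) <- vapply(out, function(g) g$id, character(1))
  out
}

.parse_genbank_record <- function(lines) {
  locus <- lines[grepl("^LOCUS", lines)][1L]
  toks <- strsplit(trimws(locus), "\\s+")[[1L]]
  id <- toks[2L]
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  # FEATURES block: feature keys start at column 6, qualifiers at column 22.
  fstart <- which(grepl("^FEATURES", lines))
  fend <- which(grepl("^(ORIGIN|CONTIG|BASE COUNT)", lines))
  features <- NULL
  if (length(fstart) == 1L && length(fend) >= 1L) {
    block <- lines[(fstart + 1L):(min(fend) - 1L)]
    is_key <- grepl("^ {5}\\S", block)
    idx <- cumsum(is_key)
    feats <- split(block, idx)
    feats <- feats[names(feats) != "0"]  # anything before the first key
    rows <- lapply(feats, .parse_genbank_feature)
    rows <- Filter(Negate(is.null), rows)
    if (length(rows) > 0L) features <- do.call(rbind, rows)
  }

  ostart <- which(grepl("^ORIGIN", lines))
  seq <- ""
  if (length(ostart) == 1L && ostart < length(lines)) {
    body <- lines[(ostart + 1L):length(lines)]
    body <- body[!grepl("^//", body)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
  }
  if (nchar(seq) == 0L) {
    stop(sprintf("GenBank record %s has no ORIGIN sequence", id),
         call. = FALSE)
  }
  circular_genome(id, seq, circular = circular, features = features)
}

.parse_genbank_feature <- function(ln) {
  key <- sub("^ {5}(\\S+).*$", "\\1", ln[1L])
  kind <- switch(key, gene = "gene", CDS = "gene", tRNA = "tRNA",
                 rRNA = "rRNA", NULL)
  if (is.null(kind)) return(NULL)
  loc <- sub("^ {5}\\S+\\s+", "", ln[1L])
  # continuation lines of the location (no '/')
  i <- 2L
  while (i <= length(ln) && !grepl("^\\s+/", ln[i])) {
    loc <- paste0(loc, trimws(ln[i])); i <- i + 1L
  }
  strand <- if (grepl("complement", loc)) "-" else "+"
  pos <- as.integer(regmatches(loc, gregexpr("[0-9]+", loc))[[1L]])
  if (length(pos) == 0L) return(NULL)
  quals <- ln[grepl("^\\s+/", ln)]
  gq <- quals[grepl("^\\s+/gene=", quals)]
  name <- if (length(gq) > 0L) {
    gsub('.*=\"?([^\"]*)\"?.*', "\\1", gq[1L])
  } else {
    pq <- quals[grepl("^\\s+/product=", quals)]
    if (length(pq) > 0L) gsub('.*=\"?([^\"]*)\"?.*', "\\1", pq[1L]) else NA_character_
  }
  data.frame(name = name, start = min(pos), end = max(pos),
             strand = strand, kind = kind, stringsAsFactors = FALSE)
}

# Alignments and groups ----------------------------------------------------

#' Read a multiple alignment from FASTA
#'
#' @param path Aligned FASTA file; all records must have equal length.
#' @return Character matrix (rows = samples, single uppercase characters),
#'   rownames = sample ids.
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path)
  as_alignment(seqs)
}

#' Coerce named sequences to an alignment matrix
#'
#' @param seqs Named character vector of equal-length sequences, or an
#'   existing character matrix.
#' @return Character matrix with rownames = sample ids.
#' @export
as_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    stopifnot(is.character(seqs), !is.null(rownames(seqs)))
    return(seqs)
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sample ids", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}

# Collapse an alignment matrix back to named strings.
alignment_strings <- function(aln) {
  out <- apply(aln, 1L, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' Read a sample-to-group table
#'
#' Tab-separated file with columns `sample`, `group`, and optionally a third
#' column marking outgroups (the literal `outgroup`, `TRUE` or `1`).
#' A header line is detected and skipped if present.
#'
#' @param path TSV path.
#' @return data.frame with columns `sample`, `group`, `outgroup` (logical).
#' @export
read_groups <- function(path) {
  raw <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  raw <- raw[lengths(raw) >= 2L]
  if (length(raw) == 0L) stop("empty group table", call. = FALSE)
  df <- data.frame(sample = vapply(raw, `[`, "", 1L),
                   group = vapply(raw, `[`, "", 2L),
                   outgroup = vapply(raw, function(x)
                     if (length(x) >= 3L) x[3L] else "", ""),
                   stringsAsFactors = FALSE)
  if (tolower(df$sample[1L]) == "sample") df <- df[-1L, , drop = FALSE]
  if (is.null(df$outgroup)) df$outgroup <- ""
  df$outgroup <- tolower(trimws(as.character(df$outgroup))) %in%
    c("outgroup", "true", "1", "yes")
  rownames(df) <- NULL
  validate_groups(df)
  df
}

validate_groups <- function(groups) {
  stopifnot(all(c("sample", "group") %in% names(groups)))
  if (anyDuplicated(groups$sample)) {
    stop("duplicate sample ids in group table", call. = FALSE)
  }
  invisible(groups)
}

#' Write a sample-to-group table
#' @param groups data.frame with `sample`, `group`, `outgroup`.
#' @param path Output TSV path.
#' @export
write_groups <- function(groups, path) {
  out <- data.frame(sample = groups$sample, group = groups$group,
                    outgroup = ifelse(isTRUE(groups$outgroup) |
                                        groups$outgroup %in% TRUE,
                                      "outgroup", ""))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Check that every aligned sample is labeled; return labels in row order.
match_groups <- function(aln, groups) {
  validate_groups(groups)
  miss <- setdiff(rownames(aln), groups$sample)
  if (length(miss) > 0L) {
    stop("unlabeled samples in alignment: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  groups[match(rownames(aln), groups$sample), , drop = FALSE]
}

#' Write an alignment in relaxed PHYLIP format
#'
#' @param aln Alignment matrix.
#' @param path Output path.
#' @export
write_phylip <- function(aln, path) {
  con <- file(path, "w"); on.exit(close(con))
  cat(sprintf("%d %d\n", nrow(aln), ncol(aln)), file = con)
  strs <- alignment_strings(aln)
  for (id in names(strs)) cat(id, " ", strs[[id]], "\n", sep = "", file = con)
  invisible(path)
}

#' Write intervals as a BED file
#'
#' Converts 1-based inclusive spans to BED's 0-based half-open convention.
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`, `score`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    name = if (is.null(df$name)) "." else df$name,
                    score = if (is.null(df$score)) 0 else df$score)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
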