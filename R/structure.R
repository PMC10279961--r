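# Quadripartite structure detection for circular plastomes.
#
# Plastid genomes carry two identical (or near-identical) inverted repeats
# (IRa/IRb) separating a large and a small single-copy region (LSC/SSC).
# The IR pair is found by seed-and-extend on the doubled sequence (which
# makes the search origin-agnostic): exact 21-mer seeds of the genome are
# matched against 21-mers of its reverse complement, candidate diagonals are
# scanned in full, and the longest run with at most `max_mismatch`
# non-matching positions wins. Ambiguity codes never match (they count as
# mismatches), so with `max_mismatch = 0` the two copies are exact reverse
# complements.

#' Find the maximal inverted repeat of a circular genome
#'
#' Returns the longest pair of non-overlapping spans A, B such that A equals
#' the reverse complement of B with at most `max_mismatch` mismatches. The
#' search crosses the circular origin.
#'
#' @param genome A [circular_genome()] or a nucleotide string.
#' @param min_len Minimum repeat length to report (>= 100).
#' @param max_mismatch Mismatch budget within the repeat (default 0; plastome
#'   IRs are typically identical copies).
#' @return `NULL` if no repeat of at least `min_len` exists, otherwise a list
#'   with `a_start`, `b_start` (1-based start positions on the circle),
#'   `length`, and `mismatches`.
#' @export
find_maximal_inverted_repeat <- function(genome, min_len = 1000L,
                                         max_mismatch = 0L) {
  s <- if (inherits(genome, "circular_genome")) genome$seq else
    normalize_seq(genome)
  n <- nchar(s)
  if (min_len < 100L) stop("min_len must be >= 100", call. = FALSE)
  if (n <= 2L * min_len) {
    stop("genome shorter than twice min_len", call. = FALSE)
  }

  k <- 21L
  tch <- seq_chars(paste0(s, s))                   # genome, doubled
  uch <- seq_chars(paste0(revcomp(s), revcomp(s))) # reverse complement, doubled

  tkmer <- substring(paste(tch, collapse = ""), 1:n, 1:n + k - 1L)
  ukmer <- substring(paste(uch, collapse = ""), 1:n, 1:n + k - 1L)
  hit <- match(tkmer, ukmer)
  cand <- which(!is.na(hit))
  if (length(cand) == 0L) return(NULL)
  # diagonals (offset of the reverse-complement copy relative to the genome)
  diags <- sort(unique((hit[cand] - cand) %% n))

  best <- NULL
  usable <- tch %in% BASES
  for (d in diags) {
    # compare t[i] with u[i + d] for i = 1..n (indices into doubled strings)
    i <- seq_len(n)
    eq <- (tch[i] == uch[i + d]) & usable[i]
    run <- .longest_run(eq, max_mismatch)
    if (is.null(run) || run$len < min_len) next
    L <- min(run$len, n %/% 2L)  # a repeat pair cannot exceed half the circle
    if (L < run$len) run$start <- run$start  # keep left anchor, trim length
    a0 <- (run$start - 1L) %% n              # 0-based start in genome
    j0 <- (a0 + d) %% n                      # 0-based start in revcomp
    b0 <- (n - j0 - L) %% n                  # 0-based start of partner span
    mm <- sum(!eq[run$start:(run$start + L - 1L)])
    if (.spans_overlap(a0, b0, L, n)) next
    cand_hit <- list(a_start = a0 + 1L, b_start = b0 + 1L,
                     length = L, mismatches = mm)
    if (is.null(best) || cand_hit$length > best$length ||
        (cand_hit$length == best$length &&
         min(cand_hit$a_start, cand_hit$b_start) <
           min(best$a_start, best$b_start))) {
      # canonical orientation: report the copy with the smaller start as A
      if (cand_hit$b_start < cand_hit$a_start) {
        cand_hit[c("a_start", "b_start")] <- cand_hit[c("b_start", "a_start")]
      }
      best <- cand_hit
    }
  }
  if (is.null(best)) {
    message("inverted-repeat candidates all self-overlap (palindrome-like); ",
            "reporting none")
    return(NULL)
  }
  best
}

# Longest segment of `eq` containing at most `mm` FALSE values, two-pointer.
.longest_run <- function(eq, mm) {
  n <- length(eq)
  bad <- cumsum(!eq)
  best_len <- 0L; best_start <- NA_integer_
  lo <- 1L
  for (hi in seq_len(n)) {
    while (bad[hi] - (if (lo > 1L) bad[lo - 1L] else 0L) > mm) lo <- lo + 1L
    len <- hi - lo + 1L
    if (len > best_len) { best_len <- len; best_start <- lo }
  }
  if (best_len == 0L) return(NULL)
  # trim flanking mismatches (a repeat should not start or end on one)
  s <- best_start; e <- best_start + best_len - 1L
  while (s <= e && !eq[s]) s <- s + 1L
  while (e >= s && !eq[e]) e <- e - 1L
  if (e < s) return(NULL)
  list(start = s, len = e - s + 1L)
}

# Do two circular spans of length L starting at 0-based a0, b0 overlap?
.spans_overlap <- function(a0, b0, L, n) {
  gap1 <- (b0 - (a0 + L)) %% n
  gap2 <- (a0 - (b0 + L)) %% n
  # disjoint iff both inter-span arcs are consistent with total length
  gap1 + gap2 + 2L * L != n
}

#' Partition a circular genome into LSC, IRa, SSC, IRb
#'
#' Labels the two inter-repeat arcs as LSC (the longer) and SSC (the
#' shorter), and reports the partition on the canonical rotation: genome
#' rotated so the LSC starts at position 1, region order LSC-IRa-SSC-IRb.
#'
#' @param genome A [circular_genome()].
#' @param ir Result of [find_maximal_inverted_repeat()] on the same genome.
#' @return Object of class `quadripartite` with 1-based inclusive spans
#'   `lsc`, `ira`, `ssc`, `irb` on canonical coordinates, the sizes of each
#'   region, `rotation_offset` (0-based offset of the canonical origin in the
#'   input coordinates), and `mismatches`.
#' @export
partition_quadripartite <- function(genome, ir) {
  stopifnot(inherits(genome, "circular_genome"))
  if (is.null(ir)) stop("no inverted repeat to partition on", call. = FALSE)
  n <- nchar(genome$seq)
  L <- ir$length
  a0 <- ir$a_start - 1L; b0 <- ir$b_start - 1L
  arc1_start <- (a0 + L) %% n               # arc following copy A
  arc1_len <- (b0 - arc1_start) %% n
  arc2_start <- (b0 + L) %% n               # arc following copy B
  arc2_len <- (a0 - arc2_start) %% n
  stopifnot(arc1_len + arc2_len + 2L * L == n)

  if (arc1_len == arc2_len) {
    s1 <- substr(rotate_seq(genome$seq, arc1_start), 1L, arc1_len)
    s2 <- substr(rotate_seq(genome$seq, arc2_start), 1L, arc2_len)
    warning("single-copy arcs have equal length; labeling LSC by ",
            "lexicographic arc sequence")
    lsc_first <- s1 <= s2
  } else {
    lsc_first <- arc1_len > arc2_len
  }
  if (lsc_first) {
    lsc_start <- arc1_start; lsc_len <- arc1_len; ssc_len <- arc2_len
  } else {
    lsc_start <- arc2_start; lsc_len <- arc2_len; ssc_len <- arc1_len
  }

  structure(list(
    lsc = span(1L, lsc_len),
    ira = span(lsc_len + 1L, lsc_len + L),
    ssc = span(lsc_len + L + 1L, lsc_len + L + ssc_len),
    irb = span(lsc_len + L + ssc_len + 1L, n),
    lsc_size = lsc_len, ssc_size = ssc_len, ir_size = L,
    genome_length = n,
    rotation_offset = lsc_start,
    mismatches = ir$mismatches
  ), class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  cat(sprintf(paste0("<quadripartite> total %s bp | LSC %s | SSC %s | ",
                     "IR %s (x2) | rotation offset %d | %d IR mismatch(es)\n"),
              format(x$genome_length, big.mark = ","),
              format(x$lsc_size, big.mark = ","),
              format(x$ssc_size, big.mark = ","),
              format(x$ir_size, big.mark = ","),
              x$rotation_offset, x$mismatches))
  invisible(x)
}

#' Genome sequence on the canonical rotation
#'
#' @param genome A [circular_genome()].
#' @param partition A `quadripartite` partition of the same genome.
#' @return Nucleotide string starting at LSC base 1 (order LSC-IRa-SSC-IRb).
#' @export
canonical_sequence <- function(genome, partition) {
  rotate_seq(genome$seq, partition$rotation_offset)
}

#' Drop one inverted-repeat copy
#'
#' Returns LSC + IRa + SSC on the canonical rotation; this is the linear
#' sequence conventionally used when aligning plastomes (the second, fully
#' redundant IR copy is removed first).
#'
#' @inheritParams canonical_sequence
#' @return Nucleotide string of length `genome_length - ir_size`.
#' @export
remove_one_ir <- function(genome, partition) {
  stopifnot(inherits(genome, "circular_genome"))
  if (!genome$circular) {
    stop("genome is already linear; one IR copy has presumably been removed",
         call. = FALSE)
  }
  can <- canonical_sequence(genome, partition)
  substr(can, 1L, partition$genome_length - partition$ir_size)
}

#' Detect structure for a set of genomes
#'
#' Convenience wrapper: runs [find_maximal_inverted_repeat()] and
#' [partition_quadripartite()] on each genome and tabulates per-genome
#' metrics (length, GC%, region sizes).
#'
#' @param genomes List of [circular_genome()] objects.
#' @param min_len,max_mismatch Passed to [find_maximal_inverted_repeat()].
#' @return List with `table` (data.frame: id, length, gc_percent, lsc, ssc,
#'   ir, rotation_offset) and `partitions` (named list of `quadripartite`
#'   objects, `NULL` where no IR was found).
#' @export
plastome_structure <- function(genomes, min_len = 1000L, max_mismatch = 0L) {
  rows <- list(); parts <- list()
  for (g in genomes) {
    ir <- find_maximal_inverted_repeat(g, min_len = min_len,
                                       max_mismatch = max_mismatch)
    part <- if (is.null(ir)) NULL else partition_quadripartite(g, ir)
    parts[[g$id]] <- part
    rows[[g$id]] <- data.frame(
      id = g$id, length = nchar(g$seq),
      gc_percent = round(100 * gc_content(g), 1),
      lsc = if (is.null(part)) NA_integer_ else part$lsc_size,
      ssc = if (is.null(part)) NA_integer_ else part$ssc_size,
      ir = if (is.null(part)) NA_integer_ else part$ir_size,
      rotation_offset = if (is.null(part)) NA_integer_ else
        part$rotation_offset,
      stringsAsFactors = FALSE)
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       partitions = parts)
}

#' Summarize a feature-bearing genome record
#'
#' Counts distinct gene names per kind, collapsing IR-duplicated copies to
#' one (plastomes carry a number of genes twice, once per repeat).
#'
#' @param record A [circular_genome()] (e.g., from [read_genbank()]).
#' @return List with `id`, `length`, `gc_percent`, `genes_available`, and
#'   unique counts `n_gene`, `n_trna`, `n_rrna`, `n_total`.
#' @export
summarize_genbank_record <- function(record) {
  stopifnot(inherits(record, "circular_genome"))
  out <- list(id = record$id, length = nchar(record$seq),
              gc_percent = round(100 * gc_content(record), 1))
  f <- record$features
  if (is.null(f) || nrow(f) == 0L) {
    out$genes_available <- FALSE
    out[c("n_gene", "n_trna", "n_rrna", "n_total")] <- NA_integer_
    return(out)
  }
  f <- f[!is.na(f$name), , drop = FALSE]
  uniq <- unique(f[, c("name", "kind")])
  # a name annotated both as a bare gene and as tRNA/rRNA counts once,
  # under its specific kind
  specific <- uniq$name[uniq$kind %in% c("tRNA", "rRNA")]
  uniq <- uniq[!(uniq$kind == "gene" & uniq$name %in% specific), , drop = FALSE]
  uniq <- unique(uniq)
  out$genes_available <- TRUE
  out$n_gene <- sum(uniq$kind == "gene")
  out$n_trna <- sum(uniq$kind == "tRNA")
  out$n_rrna <- sum(uniq$kind == "rRNA")
  out$n_total <- nrow(uniq)
  out
}
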