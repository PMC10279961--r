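# Independent oracles and small fixture builders. These deliberately share
# no code with the package internals they check.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# Build a genome with one planted inverted repeat:
# L + R + S + revcomp(R). The single-copy segments carry non-complementary
# guard bases ("A") at both ends so the planted repeat cannot extend past
# its boundaries by chance and is provably maximal.
planted_ir_genome <- function(lsc = 1000L, ir = 300L, ssc = 200L,
                              id = "planted") {
  guard <- function(n) paste0("A", rand_seq(n - 2L), "A")
  L <- guard(lsc); R <- rand_seq(ir); S <- guard(ssc)
  list(genome = circular_genome(id, paste0(L, R, S, revcomp(R))),
       lsc = lsc, ir = ir, ssc = ssc)
}

# Low-divergence random alignment: a base sequence with a few substitutions
# per row (keeps distances far from saturation).
diverged_alignment <- function(nseq, ncol, nmut = 10L) {
  base <- strsplit(rand_seq(ncol), "")[[1L]]
  m <- do.call(rbind, lapply(seq_len(nseq), function(i) {
    row <- base
    at <- sample(ncol, nmut)
    row[at] <- vapply(row[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    row
  }))
  rownames(m) <- paste0("s", seq_len(nseq))
  m
}

# Exhaustive inverted-repeat search by full diagonal enumeration with rle.
# Returns NULL or list(length, a_start, b_start) (1-based starts).
oracle_find_ir <- function(s, min_len) {
  n <- nchar(s)
  sc <- strsplit(s, "")[[1L]]
  rc <- strsplit(revcomp(s), "")[[1L]]
  acgt <- sc %in% c("A", "C", "G", "T")
  best <- NULL
  for (shift in 0:(n - 1L)) {
    idx <- ((seq_len(n) + shift - 1L) %% n) + 1L
    eq <- (sc == rc[idx]) & acgt
    eq2 <- rep(eq, 2L)
    r <- rle(eq2)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      if (starts[k] > n) next
      L <- min(r$lengths[k], n %/% 2L)
      if (L < min_len) next
      a0 <- (starts[k] - 1L) %% n
      j0 <- (a0 + shift) %% n
      b0 <- (n - j0 - L) %% n
      g1 <- (b0 - (a0 + L)) %% n; g2 <- (a0 - (b0 + L)) %% n
      if (g1 + g2 + 2L * L != n) next  # overlapping pair
      if (is.null(best) || L > best$length) {
        aa <- min(a0, b0); bb <- max(a0, b0)
        best <- list(length = L, a_start = aa + 1L, b_start = bb + 1L)
      }
    }
  }
  best
}

# Brute-force nucleotide diversity, complete deletion: direct pair loops.
oracle_pi_complete <- function(aln) {
  n <- nrow(aln)
  usable <- which(apply(aln, 2L, function(co)
    all(co %in% c("A", "C", "G", "T"))))
  if (length(usable) == 0L) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      tot <- tot + sum(aln[i, usable] != aln[j, usable]) / length(usable)
    }
  }
  tot / (n * (n - 1L) / 2L)
}

# Random alignment with given missing-data rate.
rand_alignment <- function(nseq, ncol, miss = 0.05) {
  m <- matrix(sample(c("A", "C", "G", "T"), nseq * ncol, TRUE), nseq, ncol)
  if (miss > 0) {
    k <- rbinom(1L, nseq * ncol, miss)
    m[sample(length(m), k)] <- sample(c("-", "N"), k, TRUE)
  }
  rownames(m) <- paste0("s", seq_len(nseq))
  m
}

# Overlap of a candidate with the true core, as a fraction of core length.
core_overlap <- function(cand_start, cand_end, core) {
  max(0L, min(cand_end, core[2L]) - max(cand_start, core[1L]) + 1L) /
    (core[2L] - core[1L] + 1L)
}

# Random label permutation of the non-outgroup samples of a group table.
permute_groups <- function(groups) {
  ing <- !groups$outgroup
  groups$group[ing] <- sample(groups$group[ing])
  groups
}
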