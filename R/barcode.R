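# Barcode mining: in-silico PCR, conserved-flank checks, constraint-based
# candidate window scanning, region extraction and concatenation.
#
# A usable barcode window is short enough to amplify (core <= max_len),
# variable enough to separate groups (>= min_variable variable sites, at
# least min_diag_per_group strictly diagnostic sites for every required
# group), alignment-reliable (gap fraction and window pi capped), and is
# flanked on both sides by fully conserved, gap-free blocks where universal
# primers can sit.

#' Construct a primer pair
#'
#' @param name Locus/pair name.
#' @param forward,reverse Primer sequences, 5'->3', 15-35 unambiguous bases.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- normalize_seq(forward, "forward primer")
  reverse <- normalize_seq(reverse, "reverse primer")
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15L || nchar(p) > 35L) {
      stop("primer length must be 15-35 nt", call. = FALSE)
    }
    if (!all(seq_chars(p) %in% BASES)) {
      stop("primers must be unambiguous A/C/G/T", call. = FALSE)
    }
  }
  structure(list(name = name, forward = forward, reverse = reverse),
            class = "primer_pair")
}

#' Read primer pairs from a TSV file
#'
#' Columns: `name<TAB>forward<TAB>reverse` (header optional).
#'
#' @param path TSV path.
#' @return List of [primer_pair()] objects, named.
#' @export
read_primers <- function(path) {
  raw <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
  raw <- raw[lengths(raw) >= 3L]
  if (length(raw) > 0L && tolower(raw[[1L]][1L]) == "name") raw <- raw[-1L]
  out <- lapply(raw, function(x) primer_pair(x[1L], x[2L], x[3L]))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' In-silico PCR on a template
#'
#' Matches the forward primer on the sense strand and the reverse
#' complement of the reverse primer downstream of it, within `max_product`.
#' Circular templates may yield origin-spanning products.
#'
#' @param template A [circular_genome()] or a nucleotide string (linear).
#' @param primers A [primer_pair()].
#' @param max_mismatch Mismatches tolerated per primer footprint.
#' @param max_product Maximum product length in bp.
#' @return data.frame with columns `template_id`, `start`, `end` (1-based on
#'   the template; `end` may exceed the template length for origin-spanning
#'   products), `length`, `fwd_mismatches`, `rev_mismatches`, sorted by
#'   length. Zero rows when nothing amplifies.
#' @export
in_silico_pcr <- function(template, primers, max_mismatch = 0L,
                          max_product = 2000L) {
  stopifnot(inherits(primers, "primer_pair"))
  if (inherits(template, "circular_genome")) {
    id <- template$id; s <- template$seq; circ <- template$circular
  } else {
    id <- "template"; s <- normalize_seq(template); circ <- FALSE
  }
  n <- nchar(s)
  if (max_product <= nchar(primers$forward) + nchar(primers$reverse)) {
    stop("max_product must exceed the combined primer length", call. = FALSE)
  }
  search <- if (circ) paste0(s, substr(s, 1L, min(n, max_product))) else s
  subject <- Biostrings::DNAString(search)
  fhits <- Biostrings::matchPattern(Biostrings::DNAString(primers$forward),
                                    subject, max.mismatch = max_mismatch)
  rpat <- revcomp(primers$reverse)
  rhits <- Biostrings::matchPattern(Biostrings::DNAString(rpat),
                                    subject, max.mismatch = max_mismatch)
  fstart <- BiocGenerics::start(fhits)
  rstart <- BiocGenerics::start(rhits)
  if (circ) fstart <- fstart[fstart <= n]  # one copy of each circular hit
  flen <- nchar(primers$forward); rlen <- nchar(rpat)
  rows <- list()
  for (f in fstart) {
    for (r in rstart) {
      if (r < f + flen) next                 # footprints must not overlap
      prod_len <- r + rlen - f
      if (prod_len > max_product) next
      if (circ && prod_len > n) next         # cannot exceed the circle
      fmm <- sum(seq_chars(substr(search, f, f + flen - 1L)) !=
                   seq_chars(primers$forward))
      rmm <- sum(seq_chars(substr(search, r, r + rlen - 1L)) !=
                   seq_chars(rpat))
      rows[[length(rows) + 1L]] <- data.frame(
        template_id = id, start = f, end = f + prod_len - 1L,
        length = prod_len, fwd_mismatches = fmm, rev_mismatches = rmm,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_mismatches = integer(0),
                      rev_mismatches = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$length, out$start), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > 10L) {
    warning(sprintf("primer pair '%s' is non-specific: %d products",
                    primers$name, nrow(out)))
  }
  out
}

#' Check flank conservation around an interval
#'
#' A flank passes when all `flank_len` columns immediately adjacent to the
#' interval are invariant and gap-free across all considered samples
#' (outgroups excluded by default when a group table is supplied).
#'
#' @param aln Alignment matrix.
#' @param interval Core interval, 1-based inclusive `c(start, end)`.
#' @param flank_len Flank width in columns (default 25).
#' @param groups Optional group table; outgroup rows are then excluded.
#' @param include_outgroups Set `TRUE` to keep outgroup rows in the check.
#' @return List with `left_ok`, `right_ok`, `left_span`, `right_span`
#'   (NULL when the flank falls off the alignment), and `reasons`.
#' @export
check_flank_conservation <- function(aln, interval, flank_len = 25L,
                                     groups = NULL,
                                     include_outgroups = FALSE) {
  if (!is.null(groups) && !include_outgroups) {
    g <- match_groups(aln, groups)
    aln <- aln[!g$outgroup, , drop = FALSE]
  }
  L <- ncol(aln)
  conserved <- function(cols) {
    sub <- aln[, cols, drop = FALSE]
    all(sub %in% BASES) &&
      all(apply(sub, 2L, function(co) length(unique(co)) == 1L))
  }
  res <- list(left_ok = FALSE, right_ok = FALSE,
              left_span = NULL, right_span = NULL,
              reasons = c(left = "", right = ""))
  ls <- interval[1L] - flank_len; le <- interval[1L] - 1L
  if (ls < 1L) {
    res$reasons[["left"]] <- "edge"
  } else {
    res$left_span <- span(ls, le)
    res$left_ok <- conserved(ls:le)
    if (!res$left_ok) res$reasons[["left"]] <- "variable_or_gapped"
  }
  rs <- interval[2L] + 1L; re <- interval[2L] + flank_len
  if (re > L) {
    res$reasons[["right"]] <- "edge"
  } else {
    res$right_span <- span(rs, re)
    res$right_ok <- conserved(rs:re)
    if (!res$right_ok) res$reasons[["right"]] <- "variable_or_gapped"
  }
  res
}

#' Scan an alignment for barcode candidate windows
#'
#' Slides cores of length `max_len` (and `max_len / 2`, for a short option)
#' at the given step, keeping cores that satisfy every constraint, then ranks
#' by (parsimony-informative sites desc, gap fraction asc, leftmost) and
#' greedily selects non-overlapping candidates.
#'
#' @param aln Alignment matrix.
#' @param groups Group table; >= 2 non-outgroup groups.
#' @param max_len Maximum core length (default 800).
#' @param flank_len Conserved flank width (default 25).
#' @param min_diag_per_group Minimum strict diagnostic sites per required
#'   group inside the core (default 1). Required groups are the non-outgroup
#'   groups with at least two samples.
#' @param min_variable Minimum variable sites in the core (default 3).
#' @param max_gap_frac Maximum fraction of gap cells in the core (default 0.05).
#' @param step Core start step (default 50).
#' @param pi_cap Maximum core nucleotide diversity; guards against
#'   alignment-unreliable hypervariable regions (default 0.05).
#' @param top Keep at most this many non-overlapping candidates (default 5).
#' @return data.frame of class `barcode_candidates` with per-candidate core
#'   span, site-class summary, gap fraction, pi, rank score, and one
#'   `diag_<group>` column per required group. When empty, the attribute
#'   `rejections` tallies windows failing each constraint.
#' @export
scan_candidates <- function(aln, groups, max_len = 800L, flank_len = 25L,
                            min_diag_per_group = 1L, min_variable = 3L,
                            max_gap_frac = 0.05, step = 50L, pi_cap = 0.05,
                            top = 5L) {
  g <- match_groups(aln, groups)
  labs <- unique(g$group[!g$outgroup])
  if (length(labs) < 2L) stop("need >= 2 non-outgroup groups", call. = FALSE)
  required <- labs[vapply(labs, function(l)
    sum(g$group == l & !g$outgroup) >= 2L, logical(1))]

  ing <- aln[!g$outgroup, , drop = FALSE]
  L <- ncol(aln)
  cls <- classify_sites(ing)
  is_pi <- cls == "parsimony_informative"
  is_var <- is_pi | cls == "singleton"
  gapcell <- colSums(ing == "-")
  # per-column mean pairwise difference (for window pi, complete deletion)
  okcol <- colSums(ing == "A" | ing == "C" | ing == "G" | ing == "T") ==
    nrow(ing)
  cnt <- .base_counts(ing)
  npair <- nrow(ing) * (nrow(ing) - 1L) / 2L
  het <- (npair - colSums(choose(cnt, 2L))) / npair
  het[!okcol] <- NA_real_
  conserved_col <- okcol & gapcell == 0L & het == 0
  conserved_col[is.na(conserved_col)] <- FALSE

  diag <- find_diagnostic_sites(aln, groups)
  diag <- diag[diag$strict, , drop = FALSE]
  diag_ind <- sapply(required, function(l) {
    v <- rep(0L, L); v[diag$column[diag$group == l]] <- 1L; v
  })
  if (length(required) == 1L) diag_ind <- matrix(diag_ind, ncol = 1L,
                                                 dimnames = list(NULL, required))

  csum <- function(v) c(0, cumsum(v))
  cs_pi <- csum(is_pi); cs_var <- csum(is_var); cs_gap <- csum(gapcell)
  cs_cons <- csum(conserved_col)
  cs_ok <- csum(okcol); cs_het <- csum(ifelse(okcol, het, 0))
  cs_diag <- apply(diag_ind, 2L, function(v) c(0, cumsum(v)))
  wsum <- function(cs, st, en) cs[en + 1L] - cs[st]

  lens <- unique(c(max_len, max(2L, max_len %/% 2L)))
  cand <- list()
  rej <- c(diagnostic_coverage = 0L, min_variable = 0L, gap_fraction = 0L,
           pi_cap = 0L, flanks = 0L)
  for (clen in lens) {
    if (L < clen + 2L * flank_len) next
    starts <- seq(flank_len + 1L, L - clen - flank_len + 1L, by = step)
    for (st in starts) {
      en <- st + clen - 1L
      dcov <- vapply(required, function(l) wsum(cs_diag[, l], st, en),
                     numeric(1))
      nvar <- wsum(cs_var, st, en)
      gapf <- wsum(cs_gap, st, en) / (clen * nrow(ing))
      nok <- wsum(cs_ok, st, en)
      wpi <- if (nok > 0L) wsum(cs_het, st, en) / nok else NA_real_
      flank_ok <- wsum(cs_cons, st - flank_len, st - 1L) == flank_len &&
        wsum(cs_cons, en + 1L, en + flank_len) == flank_len
      fails <- c(diagnostic_coverage = any(dcov < min_diag_per_group),
                 min_variable = nvar < min_variable,
                 gap_fraction = gapf > max_gap_frac,
                 pi_cap = is.na(wpi) || wpi > pi_cap,
                 flanks = !flank_ok)
      if (any(fails)) { rej <- rej + fails; next }
      row <- data.frame(start = st, end = en, length = clen,
                        n_variable = nvar, n_pi = wsum(cs_pi, st, en),
                        gap_frac = gapf, pi = wpi,
                        stringsAsFactors = FALSE)
      for (l in required) row[[paste0("diag_", l)]] <- dcov[[l]]
      cand[[length(cand) + 1L]] <- row
    }
  }
  if (length(cand) == 0L) {
    out <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0), n_variable = integer(0),
                      n_pi = integer(0), gap_frac = numeric(0),
                      pi = numeric(0))
    attr(out, "rejections") <- rej
    attr(out, "required_groups") <- required
    class(out) <- c("barcode_candidates", "data.frame")
    return(out)
  }
  all_cand <- do.call(rbind, cand)
  ord <- order(-all_cand$n_pi, all_cand$gap_frac, all_cand$start,
               -all_cand$length)
  all_cand <- all_cand[ord, , drop = FALSE]
  # greedy non-overlapping selection
  keep <- logical(nrow(all_cand))
  taken <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(all_cand))) {
    st <- all_cand$start[i]; en <- all_cand$end[i]
    if (nrow(taken) == 0L ||
        all(en < taken[, 1L] | st > taken[, 2L])) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(st, en))
      if (sum(keep) >= top) break
    }
  }
  out <- all_cand[keep, , drop = FALSE]
  out$rank_score <- out$n_pi
  rownames(out) <- NULL
  attr(out, "rejections") <- rej
  attr(out, "required_groups") <- required
  attr(out, "flank_len") <- flank_len
  class(out) <- c("barcode_candidates", "data.frame")
  out
}

#' Re-validate barcode candidates independently
#'
#' Post-hoc validator sharing no code with the scanner: every constraint is
#' re-checked column by column with direct loops.
#'
#' @param aln,groups As in [scan_candidates()].
#' @param candidates Result of [scan_candidates()].
#' @param max_len,flank_len,min_diag_per_group,min_variable,max_gap_frac,pi_cap
#'   Constraint parameters as in [scan_candidates()].
#' @return Logical vector, one entry per candidate.
#' @export
validate_candidates <- function(aln, groups, candidates, max_len = 800L,
                                flank_len = 25L, min_diag_per_group = 1L,
                                min_variable = 3L, max_gap_frac = 0.05,
                                pi_cap = 0.05) {
  g <- match_groups(aln, groups)
  ing_idx <- which(!g$outgroup)
  labs <- unique(g$group[ing_idx])
  required <- labs[vapply(labs, function(l)
    sum(g$group[ing_idx] == l) >= 2L, logical(1))]
  vapply(seq_len(nrow(candidates)), function(i) {
    st <- candidates$start[i]; en <- candidates$end[i]
    if (en - st + 1L > max_len) return(FALSE)
    nvar <- 0L; ngap <- 0L
    diagc <- stats::setNames(rep(0L, length(required)), required)
    het_sum <- 0; het_n <- 0L
    for (col in st:en) {
      states <- aln[ing_idx, col]
      ngap <- ngap + sum(states == "-")
      obs <- states[states %in% BASES]
      if (length(unique(obs)) >= 2L) nvar <- nvar + 1L
      if (length(obs) == length(ing_idx)) {
        pairs <- 0L; diff <- 0L
        for (a in seq_along(obs)[-length(obs)]) for (b in (a + 1L):length(obs)) {
          pairs <- pairs + 1L; if (obs[a] != obs[b]) diff <- diff + 1L
        }
        het_sum <- het_sum + diff / pairs; het_n <- het_n + 1L
      }
      for (l in required) {
        gs <- aln[ing_idx[g$group[ing_idx] == l], col]
        gs <- gs[gs %in% BASES]
        os <- aln[ing_idx[g$group[ing_idx] != l], col]
        os <- os[os %in% BASES]
        if (length(gs) > 0L && length(unique(gs)) == 1L &&
            !(gs[1L] %in% os)) {
          diagc[[l]] <- diagc[[l]] + 1L
        }
      }
    }
    flank_cons <- function(cols) {
      if (any(cols < 1L) || any(cols > ncol(aln))) return(FALSE)
      for (col in cols) {
        states <- aln[ing_idx, col]
        if (any(!(states %in% BASES))) return(FALSE)
        if (length(unique(states)) != 1L) return(FALSE)
      }
      TRUE
    }
    all(diagc >= min_diag_per_group) &&
      nvar >= min_variable &&
      ngap / ((en - st + 1L) * length(ing_idx)) <= max_gap_frac &&
      het_n > 0L && het_sum / het_n <= pi_cap &&
      flank_cons((st - flank_len):(st - 1L)) &&
      flank_cons((en + 1L):(en + flank_len))
  }, logical(1))
}

#' Extract a region from an alignment or from genomes by primers
#'
#' @param x Alignment matrix (span mode) or a list of [circular_genome()]
#'   objects (primer mode).
#' @param locator 1-based inclusive `c(start, end)` span, or a
#'   [primer_pair()].
#' @param max_mismatch,max_product Primer-mode settings, see
#'   [in_silico_pcr()].
#' @return Span mode: a sub-alignment matrix. Primer mode: a named character
#'   vector of (unaligned) amplicon sequences with attribute `aligned =
#'   FALSE`; errors when any genome does not yield exactly one product.
#' @export
extract_region <- function(x, locator, max_mismatch = 0L,
                           max_product = 2000L) {
  if (is.matrix(x) && !inherits(locator, "primer_pair")) {
    stopifnot(length(locator) == 2L)
    return(x[, locator[1L]:locator[2L], drop = FALSE])
  }
  stopifnot(inherits(locator, "primer_pair"), is.list(x))
  hits <- lapply(x, in_silico_pcr, primers = locator,
                 max_mismatch = max_mismatch, max_product = max_product)
  nhit <- vapply(hits, nrow, integer(1))
  bad <- names(x)[nhit != 1L]
  if (length(bad) > 0L) {
    stop(sprintf("primer pair '%s' does not yield exactly one product in: %s",
                 locator$name, paste(bad, collapse = ", ")), call. = FALSE)
  }
  amp <- vapply(seq_along(x), function(i) {
    g <- x[[i]]; h <- hits[[i]]
    s2 <- paste0(g$seq, g$seq)  # tolerate origin-spanning products
    substr(s2, h$start, h$end)
  }, character(1))
  names(amp) <- names(x)
  attr(amp, "aligned") <- FALSE
  amp
}

#' Concatenate sub-alignments into one matrix
#'
#' @param parts Named list of alignment matrices over the same sample set.
#' @return Alignment matrix with attribute `partition_map`, a data.frame
#'   recording each source interval.
#' @export
concatenate_regions <- function(parts) {
  stopifnot(is.list(parts), length(parts) >= 1L)
  ids <- rownames(parts[[1L]])
  for (p in parts) {
    if (!setequal(rownames(p), ids)) {
      stop("sample sets differ between regions", call. = FALSE)
    }
  }
  parts <- lapply(parts, function(p) p[ids, , drop = FALSE])
  out <- do.call(cbind, parts)
  lens <- vapply(parts, ncol, integer(1))
  ends <- cumsum(lens)
  nm <- names(parts)
  if (is.null(nm)) nm <- paste0("region", seq_along(parts))
  attr(out, "partition_map") <- data.frame(
    region = nm, start = c(1L, utils::head(ends, -1L) + 1L), end = ends,
    length = lens, row.names = NULL)
  out
}
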