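# Alignment-column statistics: site classification, nucleotide diversity
# (pi), sliding-window scans, and group-diagnostic fixed sites.
#
# Missing-data policy: gaps and IUPAC ambiguity codes are missing everywhere.
# A column is variable iff it carries >= 2 distinct unambiguous states among
# the non-missing samples, parsimony-informative iff >= 2 states each occur
# in >= 2 samples.

# Per-column base counts: 4 x L integer matrix (A, C, G, T).
.base_counts <- function(aln) {
  rbind(A = colSums(aln == "A"), C = colSums(aln == "C"),
        G = colSums(aln == "G"), T = colSums(aln == "T"))
}

#' Classify every column of an alignment
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @return Character vector of length `ncol(aln)` with values `"invariant"`,
#'   `"singleton"`, `"parsimony_informative"`, or `"excluded"` (fewer than
#'   two non-missing states).
#' @export
classify_sites <- function(aln) {
  cnt <- .base_counts(aln)
  nonmiss <- colSums(cnt)
  n_states <- colSums(cnt > 0L)
  n_ge2 <- colSums(cnt >= 2L)
  out <- rep("invariant", ncol(aln))
  out[n_states >= 2L] <- "singleton"
  out[n_ge2 >= 2L & n_states >= 2L] <- "parsimony_informative"
  out[nonmiss < 2L] <- "excluded"
  out
}

#' Classify a single alignment column
#'
#' @param column Character vector of per-sample states.
#' @return One of `"invariant"`, `"singleton"`, `"parsimony_informative"`,
#'   `"excluded"`.
#' @export
classify_site <- function(column) {
  classify_sites(matrix(toupper(column), ncol = 1L,
                        dimnames = list(seq_along(column), NULL)))
}

#' Count site classes over an interval
#'
#' @param aln Alignment matrix.
#' @param interval 1-based inclusive `c(start, end)`; default whole alignment.
#' @return Object of class `site_class_summary`: interval, interval length,
#'   `n_variable`, `n_parsimony_informative`, `n_singleton`, `n_excluded`,
#'   and percentages of the interval length (two decimals).
#' @export
count_site_classes <- function(aln, interval = c(1L, ncol(aln))) {
  start <- interval[1L]; end <- interval[2L]
  if (end < start || start < 1L || end > ncol(aln)) {
    stop("invalid interval", call. = FALSE)
  }
  cls <- classify_sites(aln[, start:end, drop = FALSE])
  len <- end - start + 1L
  n_pi <- sum(cls == "parsimony_informative")
  n_sing <- sum(cls == "singleton")
  structure(list(
    interval = span(start, end), length = len,
    n_variable = n_pi + n_sing,
    n_parsimony_informative = n_pi,
    n_singleton = n_sing,
    n_excluded = sum(cls == "excluded"),
    pct_variable = round(100 * (n_pi + n_sing) / len, 2),
    pct_parsimony_informative = round(100 * n_pi / len, 2)
  ), class = "site_class_summary")
}

#' @export
print.site_class_summary <- function(x, ...) {
  cat(sprintf(paste0("<site classes> cols %d-%d (%d bp): %d variable ",
                     "(%.2f%%), %d parsimony-informative (%.2f%%), ",
                     "%d singleton, %d excluded\n"),
              x$interval[["start"]], x$interval[["end"]], x$length,
              x$n_variable, x$pct_variable, x$n_parsimony_informative,
              x$pct_parsimony_informative, x$n_singleton, x$n_excluded))
  invisible(x)
}

#' Nucleotide diversity (pi) over an interval
#'
#' Average per-site proportion of differences between two sampled sequences,
#' over all sample pairs. Under complete deletion (the default, matching the
#' common population-genetics convention) only columns with no missing state
#' in any sample are compared; under pairwise deletion comparability is
#' decided per pair.
#'
#' @param aln Alignment matrix (>= 2 samples).
#' @param interval 1-based inclusive `c(start, end)`.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return List with `pi` (NA if no comparable site) and `usable_sites`
#'   (columns entering at least one comparison).
#' @export
nucleotide_diversity <- function(aln, interval = c(1L, ncol(aln)),
                                 deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  stopifnot(nrow(aln) >= 2L)
  sub <- aln[, interval[1L]:interval[2L], drop = FALSE]
  n <- nrow(sub)
  npair <- n * (n - 1L) / 2L
  ok <- sub == "A" | sub == "C" | sub == "G" | sub == "T"

  if (deletion == "complete") {
    usable <- which(colSums(ok) == n)
    if (length(usable) == 0L) {
      return(list(pi = NA_real_, usable_sites = 0L))
    }
    cnt <- .base_counts(sub[, usable, drop = FALSE])
    # per-column mean pairwise difference
    het <- (npair - colSums(choose(cnt, 2L))) / npair
    return(list(pi = mean(het), usable_sites = length(usable)))
  }

  # pairwise deletion: per-pair proportion of differing comparable sites
  tot <- 0; used <- rep(FALSE, ncol(sub))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0L) next
      used <- used | comp
      tot <- tot + sum(sub[i, comp] != sub[j, comp]) / m
    }
  }
  if (!any(used)) return(list(pi = NA_real_, usable_sites = 0L))
  list(pi = tot / npair, usable_sites = sum(used))
}

#' Sliding-window nucleotide diversity
#'
#' Windows start at columns 1, 1 + step, 1 + 2*step, ...; the final window is
#' truncated at the alignment end and flagged.
#'
#' @param aln Alignment matrix.
#' @param window_len Window length in alignment columns (default 800).
#' @param step Step size (default 200); must satisfy
#'   `window_len >= step >= 1`.
#' @param deletion Deletion policy, see [nucleotide_diversity()].
#' @return data.frame of class `window_diversity_track` with columns `start`,
#'   `end`, `midpoint`, `usable_sites`, `pi`, `truncated`; attributes
#'   `window_len` and `step`.
#' @export
sliding_window_diversity <- function(aln, window_len = 800L, step = 200L,
                                     deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (!(window_len >= step && step >= 1L)) {
    stop("need window_len >= step >= 1", call. = FALSE)
  }
  L <- ncol(aln)
  if (window_len > L) {
    warning("window longer than alignment; returning one truncated window")
  }
  starts <- integer(0); s <- 1L
  repeat {
    starts <- c(starts, s)
    if (s + window_len - 1L >= L || s + step > L) break
    s <- s + step
  }
  rows <- lapply(starts, function(st) {
    en <- min(st + window_len - 1L, L)
    nd <- nucleotide_diversity(aln, c(st, en), deletion = deletion)
    data.frame(start = st, end = en, midpoint = (st + en) / 2,
               usable_sites = nd$usable_sites, pi = nd$pi,
               truncated = (en - st + 1L) < window_len)
  })
  out <- do.call(rbind, rows)
  attr(out, "window_len") <- window_len
  attr(out, "step") <- step
  class(out) <- c("window_diversity_track", "data.frame")
  out
}

#' Plot a window diversity track
#'
#' @param x A `window_diversity_track`.
#' @param ... Passed to [plot()].
#' @export
plot.window_diversity_track <- function(x, ...) {
  plot(x$midpoint, x$pi, type = "l", xlab = "alignment position (window midpoint)",
       ylab = expression(pi), ...)
  invisible(x)
}

#' Find group-diagnostic fixed sites
#'
#' A column is a diagnostic site for a group when the group's non-missing
#' samples all carry one state and that state is absent from every other
#' non-outgroup sample's non-missing state. `complete` marks sites with no
#' missing data inside the group; `strict` additionally requires no missing
#' data among the other non-outgroup samples (so absence is certain).
#' Outgroup samples are ignored throughout.
#'
#' @param aln Alignment matrix.
#' @param groups Group table (see [read_groups()]); >= 2 non-outgroup groups.
#' @return data.frame with columns `column`, `group`, `state`, `complete`,
#'   `strict`.
#' @export
find_diagnostic_sites <- function(aln, groups) {
  g <- match_groups(aln, groups)
  ing <- !g$outgroup
  labs <- unique(g$group[ing])
  if (length(labs) < 2L) {
    stop("need >= 2 non-outgroup groups", call. = FALSE)
  }
  sub <- aln[ing, , drop = FALSE]
  glab <- g$group[ing]
  cnt_all <- .base_counts(sub)
  nonmiss_all <- colSums(cnt_all)
  out <- list()
  for (lab in labs) {
    inl <- glab == lab
    cnt_g <- .base_counts(sub[inl, , drop = FALSE])
    nonmiss_g <- colSums(cnt_g)
    # fixed within group: exactly one state present, at least one observation
    fixed <- colSums(cnt_g > 0L) == 1L & nonmiss_g > 0L
    if (!any(fixed)) next
    state_idx <- max.col(t(cnt_g), ties.method = "first")
    cnt_o <- cnt_all - cnt_g
    state_cnt_o <- cnt_o[cbind(state_idx, seq_len(ncol(sub)))]
    diag_col <- fixed & state_cnt_o == 0L
    if (!any(diag_col)) next
    cols <- which(diag_col)
    nonmiss_o <- nonmiss_all - nonmiss_g
    out[[lab]] <- data.frame(
      column = cols,
      group = lab,
      state = rownames(cnt_g)[state_idx[cols]],
      complete = nonmiss_g[cols] == sum(inl),
      strict = nonmiss_o[cols] == sum(!inl),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(column = integer(0), group = character(0),
                      state = character(0), complete = logical(0),
                      strict = logical(0)))
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res[order(res$column, res$group), , drop = FALSE]
}

#' Mask columns by gap fraction
#'
#' Plumbing helper: returns the indices of columns whose gap fraction is at
#' most `max_gap_frac`.
#'
#' @param aln Alignment matrix.
#' @param max_gap_frac Maximum tolerated fraction of gap characters.
#' @return Integer vector of retained column indices.
#' @export
gap_mask <- function(aln, max_gap_frac = 0.05) {
  which(colMeans(aln == "-") <= max_gap_frac)
}
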