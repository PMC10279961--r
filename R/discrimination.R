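# Tree-based discrimination testing. A barcode region discriminates a
# species or lineage when its samples form a monophyletic group on the
# region's tree with bootstrap support above a threshold (default: strictly
# greater than 50%).
#
# Trees are built by neighbor joining on p/JC69/K2P distances; support comes
# from the standard nonparametric bootstrap (column resampling with
# replacement). This is deliberately desk-scale plumbing around the
# monophyly-plus-support criterion; alignments can be exported in relaxed
# PHYLIP for external maximum-likelihood runs.

#' Pairwise distance matrix from an alignment
#'
#' @param aln Alignment matrix (>= 3 samples for downstream tree building).
#' @param model `"JC69"` (default), `"p"` (raw proportion of differing
#'   comparable sites), or `"K2P"`.
#' @param deletion `"pairwise"` (default) or `"complete"` treatment of
#'   missing data (gaps/ambiguities).
#' @return Symmetric matrix with zero diagonal, attribute `model`. Saturated
#'   pairs (p >= 0.75 under JC69, or a non-positive log argument under K2P)
#'   are replaced by twice the maximum finite distance, with a warning.
#' @export
distance_matrix <- function(aln, model = c("JC69", "p", "K2P"),
                            deletion = c("pairwise", "complete")) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  n <- nrow(aln)
  ok <- aln == "A" | aln == "C" | aln == "G" | aln == "T"
  if (deletion == "complete") {
    keep <- colSums(ok) == n
    aln <- aln[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  purine <- aln == "A" | aln == "G"
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- ok[i, ] & ok[j, ]
      m <- sum(comp)
      if (m == 0L) { d[i, j] <- d[j, i] <- NA_real_; next }
      diffs <- aln[i, comp] != aln[j, comp]
      p <- sum(diffs) / m
      val <- switch(model,
        p = p,
        JC69 = if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_,
        K2P = {
          ts <- sum(diffs & (purine[i, comp] == purine[j, comp])) / m
          tv <- p - ts
          a1 <- 1 - 2 * ts - tv; a2 <- 1 - 2 * tv
          if (a1 > 0 && a2 > 0) -0.5 * log(a1) - 0.25 * log(a2) else NA_real_
        })
      d[i, j] <- d[j, i] <- val
    }
  }
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    warning("saturated or incomparable pairs; distances capped at ",
            signif(2 * mx, 4))
    d[is.na(d)] <- 2 * mx
  }
  attr(d, "model") <- model
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration with the Q criterion. Ties on Q are broken
#' deterministically by the smallest index pair. Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch (their sum is
#' preserved). For additive inputs the tree's path distances reproduce the
#' matrix.
#'
#' @param dm Symmetric distance matrix with row/column names.
#' @return Unrooted `phylo` object (ape).
#' @export
neighbor_joining <- function(dm) {
  if (!isSymmetric(unname(dm))) stop("distance matrix must be symmetric",
                                     call. = FALSE)
  labels <- rownames(dm)
  n <- length(labels)
  if (n < 2L) stop("need at least 2 taxa", call. = FALSE)
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1L],
                                        fmt(dm[1L, 2L] / 2),
                                        labels[2L], fmt(dm[1L, 2L] / 2)))
    return(tr)
  }
  d <- unname(dm)
  nwk <- labels  # newick fragment per active node
  repeat {
    m <- nrow(d)
    if (m == 3L) break
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # smallest Q; ties by smallest (i, j), i < j
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- d[i, j]; li <- 0 }
    if (lj < 0) { li <- d[i, j]; lj <- 0 }
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], merged)
  }
  # final three nodes: three-point formulas
  la <- (d[1L, 2L] + d[1L, 3L] - d[2L, 3L]) / 2
  lb <- (d[1L, 2L] + d[2L, 3L] - d[1L, 3L]) / 2
  lc <- (d[1L, 3L] + d[2L, 3L] - d[1L, 2L]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1L], fmt(la), nwk[2L], fmt(lb),
                 nwk[3L], fmt(lc))
  ape::read.tree(text = txt)
}

# Canonical bipartition keys of a tree: for every edge, the tip-label set on
# the side not containing the alphabetically first tip, sorted and joined.
# Trivial (pendant) bipartitions are included. With `drop_zero_internal`,
# internal edges of zero length are treated as unresolved polytomies and
# contribute no bipartition (so a star-like tree supports nothing).
bipartition_keys <- function(tree, drop_zero_internal = FALSE) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  node_ids <- as.integer(names(pp))
  if (is.null(node_ids) || anyNA(node_ids)) {
    # prop.part numbers clades from the root in preorder
    node_ids <- length(tips) + seq_along(pp)
  }
  keys <- character(0)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (drop_zero_internal && !is.null(tree$edge.length)) {
      ei <- which(tree$edge[, 2L] == node_ids[k])
      if (length(ei) == 1L && tree$edge.length[ei] <= 0) next
    }
    keys <- c(keys, .bip_key(side, tips, anchor))
  }
  for (t in tips) keys <- c(keys, .bip_key(t, tips, anchor))
  unique(keys[nzchar(keys)])  # drop the trivial all-tips split
}

.bip_key <- function(side, tips, anchor = sort(tips)[1L]) {
  if (anchor %in% side) side <- setdiff(tips, side)
  paste(sort(side), collapse = "|")
}

#' Is a group monophyletic on an unrooted tree?
#'
#' True iff one edge's bipartition separates exactly the group from the rest.
#' Singleton groups are trivially monophyletic via their pendant edge.
#'
#' @param tree A `phylo` object.
#' @param group Character vector of tip labels, a proper non-empty subset of
#'   the tree's tips.
#' @return List with `monophyletic` (logical) and `key` (the canonical
#'   bipartition identifier of the defining edge, or `NA`).
#' @export
is_group_monophyletic <- function(tree, group) {
  tips <- tree$tip.label
  stopifnot(all(group %in% tips))
  if (length(group) == 0L || length(group) >= length(tips)) {
    stop("group must be a proper non-empty subset of the tips", call. = FALSE)
  }
  key <- .bip_key(group, tips)
  mono <- length(group) == 1L || key %in% bipartition_keys(tree)
  list(monophyletic = mono, key = if (mono) key else NA_character_)
}

# Precomputed per-pair difference/comparability indicators, for fast
# bootstrap resampling. Returns P x L logical matrices.
.pair_profiles <- function(aln) {
  n <- nrow(aln); L <- ncol(aln)
  ok <- aln == "A" | aln == "C" | aln == "G" | aln == "T"
  purine <- aln == "A" | aln == "G"
  P <- n * (n - 1L) / 2L
  cmp <- matrix(FALSE, P, L); mis <- matrix(FALSE, P, L)
  tsi <- matrix(FALSE, P, L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      cmp[k, ] <- ok[i, ] & ok[j, ]
      mis[k, ] <- cmp[k, ] & (aln[i, ] != aln[j, ])
      tsi[k, ] <- mis[k, ] & (purine[i, ] == purine[j, ])
    }
  }
  list(cmp = cmp, mis = mis, tsi = tsi, n = n, labels = rownames(aln))
}

.pair_dist <- function(prof, cols, model) {
  cmp <- rowSums(prof$cmp[, cols, drop = FALSE])
  mis <- rowSums(prof$mis[, cols, drop = FALSE])
  p <- ifelse(cmp > 0L, mis / cmp, NA_real_)
  val <- switch(model,
    p = p,
    JC69 = ifelse(!is.na(p) & p < 0.75, -0.75 * log(1 - 4 * p / 3),
                  NA_real_),
    K2P = {
      ts <- rowSums(prof$tsi[, cols, drop = FALSE]) / cmp
      tv <- p - ts
      a1 <- 1 - 2 * ts - tv; a2 <- 1 - 2 * tv
      ifelse(!is.na(p) & a1 > 0 & a2 > 0,
             -0.5 * log(a1) - 0.25 * log(a2), NA_real_)
    })
  if (anyNA(val)) {
    mx <- suppressWarnings(max(val, na.rm = TRUE))
    if (!is.finite(mx)) mx <- 0.75
    val[is.na(val)] <- 2 * mx
  }
  d <- matrix(0, prof$n, prof$n, dimnames = list(prof$labels, prof$labels))
  k <- 0L
  for (i in seq_len(prof$n - 1L)) {
    for (j in (i + 1L):prof$n) {
      k <- k + 1L
      d[i, j] <- d[j, i] <- val[k]
    }
  }
  d
}

#' Bootstrap support for an alignment's NJ tree
#'
#' Resamples alignment columns with replacement `B` times, rebuilds the NJ
#' tree each time, and maps bipartition frequencies (as percentages) onto the
#' tree built from the original data.
#'
#' @param aln Alignment matrix (>= 3 samples).
#' @param model Distance model, see [distance_matrix()].
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; supports are reproducible given
#'   `(aln, model, B, seed)`.
#' @return Object of class `supported_tree`: list with `tree` (`phylo`, node
#'   labels = supports), `support` (named numeric vector keyed by canonical
#'   bipartition), `B`, `model`.
#' @export
bootstrap_support <- function(aln, model = "JC69", B = 1000L, seed = 1L) {
  stopifnot(nrow(aln) >= 3L, B >= 1L)
  prof <- .pair_profiles(aln)
  if (!any(prof$cmp)) stop("alignment has zero comparable columns",
                           call. = FALSE)
  L <- ncol(aln)
  main_tree <- neighbor_joining(.pair_dist(prof, seq_len(L), model))
  counts <- new.env(parent = emptyenv())
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    cols <- sample.int(L, L, replace = TRUE)
    tr <- neighbor_joining(.pair_dist(prof, cols, model))
    for (key in bipartition_keys(tr, drop_zero_internal = TRUE)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  support <- stats::setNames(
    vapply(keys, function(k) 100 * counts[[k]] / B, numeric(1)), keys)
  # node labels on the original tree: support of each internal edge
  main_keys <- vapply(ape::prop.part(main_tree), function(cl)
    .bip_key(main_tree$tip.label[cl], main_tree$tip.label), character(1))
  lab <- support[main_keys]
  lab[is.na(lab)] <- 0
  main_tree$node.label <- sprintf("%g", round(lab, 1))
  structure(list(tree = main_tree, support = support, B = B, model = model),
            class = "supported_tree")
}

#' @export
print.supported_tree <- function(x, ...) {
  cat(sprintf("<supported_tree> %d tips, %d bootstrap replicates (%s)\n",
              length(x$tree$tip.label), x$B, x$model))
  invisible(x)
}

#' Evaluate species/lineage discrimination for a region
#'
#' Builds the region's NJ tree (outgroups included as samples), bootstraps
#' it, and applies the success rule: a group is successfully discriminated
#' when its samples are monophyletic on the original-data tree with
#' bootstrap support strictly greater than `threshold`. Singleton groups are
#' trivially monophyletic; their support is not defined and success is
#' indeterminate (`NA`).
#'
#' @param aln Region sub-alignment.
#' @param groups Group table; outgroup rows are placed in the tree but never
#'   evaluated.
#' @param model Distance model (default `"JC69"`).
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param threshold Support threshold in percent (default 50; strict
#'   inequality).
#' @return Object of class `discrimination_result`: data.frame with one row
#'   per non-outgroup group (`group`, `n`, `monophyletic`, `support`,
#'   `success`); attributes `tree` (a `supported_tree`) and `threshold`.
#' @export
evaluate_discrimination <- function(aln, groups, model = "JC69", B = 1000L,
                                    seed = 1L, threshold = 50) {
  g <- match_groups(aln, groups)
  labs <- unique(g$group[!g$outgroup])
  st <- bootstrap_support(aln, model = model, B = B, seed = seed)
  rows <- lapply(labs, function(lab) {
    members <- g$sample[g$group == lab & !g$outgroup]
    n <- length(members)
    if (n == 1L) {
      return(data.frame(group = lab, n = n, monophyletic = TRUE,
                        support = NA_real_, success = NA,
                        stringsAsFactors = FALSE))
    }
    mono <- is_group_monophyletic(st$tree, members)
    supp <- if (mono$monophyletic) {
      v <- st$support[[mono$key]]
      if (is.null(v) || is.na(v)) 0 else v
    } else NA_real_
    data.frame(group = lab, n = n, monophyletic = mono$monophyletic,
               support = supp,
               success = isTRUE(mono$monophyletic) && !is.na(supp) &&
                 supp > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "tree") <- st
  attr(out, "threshold") <- threshold
  class(out) <- c("discrimination_result", "data.frame")
  out
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("Discrimination at support > %g%% (%d bootstrap replicates):\n",
              attr(x, "threshold"), attr(x, "tree")$B))
  print.data.frame(x)
  invisible(x)
}
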