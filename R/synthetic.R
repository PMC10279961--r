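# Synthetic plastome datasets with recorded ground truth.
#
# The generator emulates the sample structure of a genus-level plastome
# barcoding study: one outgroup, two small species-level clades, one large
# species split into an east and a west lineage, and one phylogenetically
# unstable singleton. Sequences evolve under Jukes-Cantor along a guide tree
# (phangorn::simSeq does the substitution work); group-diagnostic columns,
# conserved flank blocks, and a single high-mutability hotspot inside the
# inverted repeat are then planted deterministically, so the recorded truth
# is exact. Genomes are assembled as LSC + IRa + SSC + revcomp(IRa) with
# per-group IR length realized by hotspot deletions, then randomly rotated.
#
# Default scale is ~20 kb per genome (all algorithms are length-agnostic;
# this keeps a full simulated study under a minute).

# Pectinate clade fragment: (((L1:t,L2:t):i,L3:t):i, ...)
.clade_newick <- function(labels, tip_len, int_len) {
  if (length(labels) == 1L) return(sprintf("%s:%.8f", labels, tip_len))
  frag <- sprintf("(%s:%.8f,%s:%.8f)", labels[1L], tip_len,
                  labels[2L], tip_len)
  for (lab in labels[-(1:2)]) {
    frag <- sprintf("(%s:%.8f,%s:%.8f)", frag, int_len, lab, tip_len)
  }
  frag
}

#' Default simulation parameters
#'
#' Study-like defaults: 25 samples (outgroup `OUT`; species A `spA`, 2
#' samples; species B `spB`, 5; species C split into an eastern lineage
#' `spC_E`, 8, and a western lineage `spC_W`, 8; unstable singleton `HN`),
#' ~20 kb quadripartite genomes (LSC 10,000 / IR 3,630 / SSC 2,800 bp) whose
#' IR length varies by group through deletions in an IR-internal hotspot,
#' low background diversity with a single 20x hotspot, 12 planted diagnostic
#' columns per multi-sample group (6 of them inside the planted barcode
#' core), and fully conserved 30-column flank blocks around the core.
#'
#' @return Named list of generator parameters; edit and pass to
#'   [generate_study_like_dataset()].
#' @export
default_sim_params <- function() {
  groups <- list(spA = paste0("A", 1:2), spB = paste0("B", 1:5),
                 spC_E = paste0("E", 1:8), spC_W = paste0("W", 1:8))
  core <- c(4326L, 5125L)          # grid-aligned 800-bp core in the LSC
  flank_len <- 30L
  # in-core sites: one anchor block per group, spread across the whole core
  # (spA near the left edge, spC_W near the right), so that any window
  # overlapping the core only partially drops a whole group's coverage
  anchors <- c(spA = 4341L, spB = 4581L, spC_E = 4821L, spC_W = 5035L)
  # out-of-core sites are scattered at wide spacing within group-specific
  # regions that sit farther than one scan window from the core and from
  # each other, so they never assemble into a competing candidate
  scatter <- list(spA = 500L + 350L * (0:5),
                  spB = 5900L + 350L * (0:5),
                  spC_W = 10200L + 350L * (0:5),
                  spC_E = 13700L + 350L * (0:5))
  diag <- list()
  for (g in names(groups)) {
    diag[[g]] <- c(anchors[[g]] + 15L * (0:5), scatter[[g]])
  }
  diag[["HN"]] <- 16200L + 40L * (0:2)
  list(
    groups = groups,
    singleton = "HN",
    outgroup = "OUT",
    lsc_len = 10000L, ir_len = 3630L, ssc_len = 2800L,
    hotspot = c(2001L, 2600L),     # IR-relative span, 1-based inclusive
    hotspot_multiplier = 20,
    ir_deletion = c(OUT = 0L, spA = 70L, spB = 210L,
                    spC_E = 0L, spC_W = 0L, HN = 0L),
    rate = 1,
    tip_len = 0.0002, intra_len = 0.00005,
    stem = c(spA = 0.0012, spB = 0.0010, spC = 0.0006,
             spC_E = 0.0003, spC_W = 0.0003, HN = 0.0005,
             node1 = 0.0006, OUT = 0.03),
    barcode_core = core,
    flank_len = flank_len,
    diag_columns = diag
  )
}

#' Guide tree for the simulated study
#'
#' @param params Parameter list from [default_sim_params()].
#' @return Newick string (branch lengths in expected substitutions/site).
#' @export
guide_tree_newick <- function(params = default_sim_params()) {
  p <- params
  stem_of <- function(nm) if (nm %in% names(p$stem)) p$stem[[nm]] else 0.001
  clades <- lapply(p$groups, .clade_newick, tip_len = p$tip_len,
                   int_len = p$intra_len)
  if (all(c("spC_E", "spC_W") %in% names(p$groups))) {
    spC_parts <- sprintf("%s:%.8f,%s:%.8f", clades$spC_E, stem_of("spC_E"),
                         clades$spC_W, stem_of("spC_W"))
    if (!is.null(p$singleton)) {
      spC_parts <- sprintf("%s,%s:%.8f", spC_parts, p$singleton,
                           stem_of("HN"))
    }
    spC <- sprintf("(%s)", spC_parts)
    node1 <- sprintf("(%s:%.8f,%s:%.8f)", clades$spB, stem_of("spB"),
                     spC, stem_of("spC"))
    return(sprintf("(%s:%.8f,%s:%.8f,%s:%.8f);", p$outgroup, stem_of("OUT"),
                   clades$spA, stem_of("spA"), node1, stem_of("node1")))
  }
  # generic case: pectinate chain of whatever clades are configured
  frag <- sprintf("%s:%.8f", clades[[length(clades)]],
                  stem_of(names(clades)[length(clades)]))
  if (!is.null(p$singleton)) {
    frag <- sprintf("(%s,%s:%.8f):%.8f", frag, p$singleton, stem_of("HN"),
                    p$intra_len)
  }
  mid <- if (length(clades) >= 3L) rev(seq(2L, length(clades) - 1L)) else
    integer(0)
  for (k in mid) {
    frag <- sprintf("(%s:%.8f,%s):%.8f", clades[[k]], stem_of(names(clades)[k]),
                    frag, stem_of("node1"))
  }
  sprintf("(%s:%.8f,%s:%.8f,%s);", p$outgroup, stem_of("OUT"),
          clades[[1L]], stem_of(names(clades)[1L]), frag)
}

#' Simulate a gapless alignment along a guide tree
#'
#' Jukes-Cantor substitution along the tree: the root sequence is uniform
#' over A/C/G/T and the expected number of substitutions on an edge is
#' branch length x rate x sequence length. Deterministic given the seed.
#'
#' @param tree `phylo` object or Newick string.
#' @param length Number of sites.
#' @param rate Rate multiplier applied to all branch lengths.
#' @param seed Integer seed.
#' @return List with `aln` (uppercase character matrix, rows = tips) and
#'   `tree` (the `phylo` used).
#' @export
evolve_alignment <- function(tree, length, rate = 1, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(length >= 1L)
  set.seed(as.integer(seed))
  m <- toupper(as.character(phangorn::simSeq(tree, l = length, type = "DNA",
                                             rate = rate)))
  list(aln = m[tree$tip.label, , drop = FALSE], tree = tree)
}

#' Plant diagnostic sites, conserved flanks, and a hotspot
#'
#' Overwrites chosen columns so each group carries a fixed private state
#' (all other samples are set to a shared consensus state), zeroes out
#' variation in flank blocks, and re-simulates hotspot columns at an elevated
#' rate. The returned truth record is sufficient to score every downstream
#' recovery test.
#'
#' @param aln Gapless alignment matrix.
#' @param groups Group table (see [read_groups()]).
#' @param spec List with elements `diag_columns` (named list group ->
#'   columns), `flank_blocks` (list of `c(start, end)` spans),
#'   `hotspot` (absolute `c(start, end)` span or NULL), `hotspot_tree`,
#'   `hotspot_rate`.
#' @param seed Integer seed (used by the hotspot re-simulation).
#' @return List with `aln` and `truth` (`diagnostic_columns` data.frame,
#'   `flank_blocks`, `hotspot`).
#' @export
plant_features <- function(aln, groups, spec, seed = 1L) {
  g <- match_groups(aln, groups)
  claimed <- integer(0)
  hot_cols <- if (is.null(spec$hotspot)) integer(0) else
    spec$hotspot[1L]:spec$hotspot[2L]

  # hotspot first (planted columns must survive the overwrite)
  if (length(hot_cols) > 0L) {
    set.seed(as.integer(seed) + 1L)
    hot <- toupper(as.character(phangorn::simSeq(
      spec$hotspot_tree, l = length(hot_cols), type = "DNA",
      rate = spec$hotspot_rate)))
    aln[, hot_cols] <- hot[rownames(aln), , drop = FALSE]
  }

  diag_rows <- list()
  for (lab in names(spec$diag_columns)) {
    cols <- spec$diag_columns[[lab]]
    if (anyDuplicated(cols) || any(cols %in% claimed)) {
      stop("diagnostic column claimed twice", call. = FALSE)
    }
    claimed <- c(claimed, cols)
    members <- g$sample[g$group == lab & !g$outgroup]
    for (co in cols) {
      others <- setdiff(rownames(aln), members)
      tab <- table(factor(aln[others, co], levels = BASES))
      x <- names(tab)[which.max(tab)]
      b <- setdiff(BASES, x)[1L]
      aln[others, co] <- x
      aln[members, co] <- b
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        column = co, group = lab, state = b, stringsAsFactors = FALSE)
    }
  }

  for (fb in spec$flank_blocks) {
    cols <- fb[1L]:fb[2L]
    if (any(cols %in% claimed)) stop("flank block overlaps a diagnostic column",
                                     call. = FALSE)
    claimed <- c(claimed, cols)
    for (co in cols) {
      tab <- table(factor(aln[, co], levels = BASES))
      aln[, co] <- names(tab)[which.max(tab)]
    }
  }

  list(aln = aln,
       truth = list(
         diagnostic_columns = do.call(rbind, diag_rows),
         flank_blocks = spec$flank_blocks,
         hotspot = spec$hotspot))
}

#' Assemble circular genomes from alignment rows
#'
#' Each row (layout LSC | IR | SSC) becomes a circular genome
#' LSC + IRa + SSC + revcomp(IRa). Per-group IR length is realized by
#' deleting a group-specific block of hotspot columns; a random rotation is
#' applied per genome. The same deletions, as gap characters, yield the true
#' (one-IR-copy) alignment.
#'
#' @param aln Gapless alignment matrix (row length = lsc + ir + ssc).
#' @param groups Group table.
#' @param arch List with `lsc_len`, `ir_len`, `ssc_len`, `hotspot`
#'   (IR-relative span), `ir_deletion` (named per-group bp counts).
#' @param seed Integer seed (rotations).
#' @return List with `genomes` (named list of [circular_genome()]),
#'   `alignment` (the gapped true alignment), and `partitions` (data.frame of
#'   per-genome true LSC/SSC/IR sizes, rotation, and expected canonical
#'   rotation offset).
#' @export
assemble_circular_genomes <- function(aln, groups, arch, seed = 1L) {
  g <- match_groups(aln, groups)
  L <- ncol(aln)
  with_arch <- arch$lsc_len + arch$ir_len + arch$ssc_len
  if (L != with_arch) {
    stop(sprintf("row length %d does not match architecture total %d",
                 L, with_arch), call. = FALSE)
  }
  hot_abs <- arch$lsc_len + (arch$hotspot[1L]:arch$hotspot[2L])
  set.seed(as.integer(seed) + 2L)
  genomes <- list(); rows <- list()
  gapped <- aln
  for (i in seq_len(nrow(aln))) {
    id <- rownames(aln)[i]
    grp <- g$group[g$sample == id]
    del <- arch$ir_deletion[[grp]]
    if (is.null(del) || is.na(del)) del <- 0L
    del_cols <- if (del > 0L) hot_abs[seq_len(del)] else integer(0)
    if (del > 0L) gapped[i, del_cols] <- "-"
    keep <- setdiff(seq_len(L), del_cols)
    s <- paste(aln[i, keep], collapse = "")
    lsc <- substr(s, 1L, arch$lsc_len)
    ira <- substr(s, arch$lsc_len + 1L, arch$lsc_len + arch$ir_len - del)
    ssc <- substr(s, arch$lsc_len + arch$ir_len - del + 1L, nchar(s))
    genome_seq <- paste0(lsc, ira, ssc, revcomp(ira))
    glen <- nchar(genome_seq)
    rot <- sample.int(glen, 1L) - 1L
    genomes[[id]] <- circular_genome(id, rotate_seq(genome_seq, rot))
    rows[[id]] <- data.frame(
      id = id, group = grp, genome_length = glen,
      lsc = arch$lsc_len, ssc = arch$ssc_len, ir = arch$ir_len - del,
      rotation = rot, expected_offset = (glen - rot) %% glen,
      stringsAsFactors = FALSE)
  }
  list(genomes = genomes, alignment = gapped,
       partitions = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Generate a complete study-like dataset
#'
#' One call produces every pipeline input plus the exact truth record:
#' circular genomes (FASTA-ready), the true one-IR-copy alignment, the
#' sample-group table, and the truth (guide tree, planted diagnostic
#' columns, barcode window with flanks, hotspot span, per-genome
#' partitions).
#'
#' @param seed Integer seed; two seeds give different sequences under an
#'   identical architecture.
#' @param params Parameter list, see [default_sim_params()].
#' @return List of class `synthetic_dataset` with elements `genomes`,
#'   `alignment`, `groups`, `truth`.
#' @export
generate_study_like_dataset <- function(seed = 1L,
                                        params = default_sim_params()) {
  p <- params
  L <- p$lsc_len + p$ir_len + p$ssc_len
  nwk <- guide_tree_newick(p)
  ev <- evolve_alignment(nwk, L, rate = p$rate, seed = seed)

  samples <- c(p$outgroup, unlist(p$groups, use.names = FALSE), p$singleton)
  glabels <- c(p$outgroup, rep(names(p$groups), lengths(p$groups)))
  if (!is.null(p$singleton)) glabels <- c(glabels, p$singleton)
  groups <- data.frame(
    sample = samples,
    group = glabels,
    outgroup = samples == p$outgroup,
    stringsAsFactors = FALSE)

  core <- p$barcode_core
  flanks <- list(c(core[1L] - p$flank_len, core[1L] - 1L),
                 c(core[2L] + 1L, core[2L] + p$flank_len))
  hotspot_abs <- p$lsc_len + p$hotspot
  planted <- plant_features(
    ev$aln, groups,
    spec = list(diag_columns = p$diag_columns,
                flank_blocks = flanks,
                hotspot = c(hotspot_abs[1L], hotspot_abs[2L]),
                hotspot_tree = ev$tree,
                hotspot_rate = p$rate * p$hotspot_multiplier),
    seed = seed)

  # guard bases at the single-copy boundaries: a region end must not be the
  # complement of its opposite end, or the detected IR would extend past the
  # true junction by chance
  aln_g <- planted$aln
  aln_g[, c(1L, p$lsc_len, p$lsc_len + p$ir_len + 1L, L)] <- "A"

  asm <- assemble_circular_genomes(
    aln_g, groups,
    arch = list(lsc_len = p$lsc_len, ir_len = p$ir_len, ssc_len = p$ssc_len,
                hotspot = p$hotspot, ir_deletion = p$ir_deletion),
    seed = seed)

  truth <- c(planted$truth, list(
    tree = nwk,
    barcode = list(core = core, flanks = flanks),
    hotspot = c(hotspot_abs[1L], hotspot_abs[2L]),
    partitions = asm$partitions,
    alignment_length = L))

  structure(list(genomes = asm$genomes, alignment = asm$alignment,
                 groups = groups, truth = truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_dataset> %d genomes (~%s bp), alignment ",
                     "%d x %d, %d groups (+%d outgroup)\n"),
              length(x$genomes),
              format(x$truth$partitions$genome_length[1L], big.mark = ","),
              nrow(x$alignment), ncol(x$alignment),
              length(unique(x$groups$group[!x$groups$outgroup])),
              sum(x$groups$outgroup)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `genomes.fasta`, `truth_alignment.fasta`, `groups.tsv`, and
#' `truth.json` into `dir`.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(vapply(ds$genomes, `[[`, "", "seq"),
              file.path(dir, "genomes.fasta"))
  write_fasta(alignment_strings(ds$alignment),
              file.path(dir, "truth_alignment.fasta"))
  write_groups(ds$groups, file.path(dir, "groups.tsv"))
  jsonlite::write_json(ds$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
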