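test_that("site classification follows the missing-data policy", {
  expect_equal(classify_site(c("A", "A", "T", "T")), "parsimony_informative")
  expect_equal(classify_site(c("A", "A", "A", "T")), "singleton")
  expect_equal(classify_site(c("A", "-", "A", "T")), "singleton")
  expect_equal(classify_site(c("A", "A", "A", "A")), "invariant")
  expect_equal(classify_site(c("A", "N", "-", "-")), "excluded")
  expect_equal(classify_site(c("A", "R", "A", "A")), "invariant")  # R = missing
  expect_equal(classify_site(c("A", "A", "T", "T", "G")), "parsimony_informative")
})

test_that("site-class counts satisfy n_variable = n_PI + n_singleton on random data", {
  set.seed(201)
  for (rep in 1:20) {
    aln <- rand_alignment(sample(3:12, 1L), sample(30:120, 1L), miss = 0.1)
    sc <- count_site_classes(aln)
    expect_equal(sc$n_variable, sc$n_parsimony_informative + sc$n_singleton)
    # cross-check against a direct per-column recount
    cls <- apply(aln, 2L, function(co) classify_site(co))
    expect_equal(sc$n_parsimony_informative,
                 sum(cls == "parsimony_informative"))
    expect_equal(sc$n_singleton, sum(cls == "singleton"))
    expect_equal(sc$n_excluded, sum(cls == "excluded"))
  }
  ident <- matrix("A", 4, 10, dimnames = list(paste0("s", 1:4), NULL))
  expect_equal(count_site_classes(ident)$n_variable, 0L)
  expect_error(count_site_classes(ident, c(5L, 2L)), "interval")
})

test_that("nucleotide diversity matches hand-computed and brute-force values", {
  two <- as_alignment(c(a = "AAAAAAAATT", b = "AAAAAAAAAA"))
  expect_equal(nucleotide_diversity(two)$pi, 0.2)
  three <- as_alignment(c(a = "AAA", b = "AAT", c = "ATT"))
  expect_equal(nucleotide_diversity(three)$pi, 4 / 9)
  same <- as_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  expect_equal(nucleotide_diversity(same)$pi, 0)

  set.seed(202)
  for (rep in 1:15) {
    aln <- rand_alignment(sample(3:10, 1L), sample(20:80, 1L), miss = 0.08)
    got <- nucleotide_diversity(aln)
    expect_equal(got$pi, oracle_pi_complete(aln))
  }
  # gapless alignments: complete and pairwise deletion coincide
  for (rep in 1:5) {
    aln <- rand_alignment(sample(3:8, 1L), 50L, miss = 0)
    expect_equal(nucleotide_diversity(aln, deletion = "complete")$pi,
                 nucleotide_diversity(aln, deletion = "pairwise")$pi)
  }
  # pi is invariant under row reordering
  aln <- rand_alignment(6L, 60L, miss = 0.05)
  perm <- aln[sample(nrow(aln)), , drop = FALSE]
  expect_equal(nucleotide_diversity(aln)$pi, nucleotide_diversity(perm)$pi)
  # all-missing interval is flagged undefined
  gap <- matrix("-", 3, 5, dimnames = list(paste0("s", 1:3), NULL))
  expect_true(is.na(nucleotide_diversity(gap)$pi))
})

test_that("sliding windows follow the start/step/truncation scheme", {
  aln <- rand_alignment(4L, 1000L, miss = 0)
  tr <- sliding_window_diversity(aln, 800L, 200L)
  expect_equal(tr$start, c(1L, 201L))
  expect_equal(tr$end, c(800L, 1000L))
  expect_false(any(tr$truncated))

  tr2 <- sliding_window_diversity(rand_alignment(4L, 1100L, miss = 0), 800L, 200L)
  expect_equal(tr2$end[nrow(tr2)], 1100L)
  expect_true(tr2$truncated[nrow(tr2)])

  ident <- matrix("C", 3, 900, dimnames = list(paste0("s", 1:3), NULL))
  tr3 <- sliding_window_diversity(ident, 800L, 200L)
  expect_true(all(tr3$pi == 0))
  expect_warning(sliding_window_diversity(ident[, 1:100], 800L, 200L), "window")
  expect_error(sliding_window_diversity(ident, 100L, 200L), "window_len")
})

test_that("diagnostic sites require fixation inside and absence outside the group", {
  aln <- as_alignment(c(g1a = "AC", g1b = "AC", g2a = "TC", g2b = "CC"))
  groups <- data.frame(sample = rownames(aln),
                       group = c("g1", "g1", "g2", "g2"),
                       outgroup = FALSE)
  d <- find_diagnostic_sites(aln, groups)
  # column 1: A fixed in g1 and absent in g2 -> diagnostic for g1 only
  # (g2 is not fixed there); column 2 invariant
  expect_equal(d$column, 1L)
  expect_equal(d$group, "g1")
  expect_equal(d$state, "A")
  expect_true(d$strict && d$complete)

  aln2 <- as_alignment(c(g1a = "A", g1b = "A", g2a = "T", g2b = "T"))
  d2 <- find_diagnostic_sites(aln2, groups)
  expect_setequal(d2$group, c("g1", "g2"))

  # missing data inside the group clears `complete`; outside clears `strict`
  aln3 <- as_alignment(c(g1a = "AA", g1b = "-A", g2a = "TT", g2b = "T-"))
  d3 <- find_diagnostic_sites(aln3, groups)
  expect_false(d3$complete[d3$column == 1L & d3$group == "g1"])
  expect_false(d3$strict[d3$column == 2L & d3$group == "g1"])

  # outgroup rows are ignored
  aln4 <- as_alignment(c(g1a = "A", g1b = "A", g2a = "T", g2b = "T",
                         out = "A"))
  groups4 <- rbind(groups, data.frame(sample = "out", group = "og",
                                      outgroup = TRUE))
  d4 <- find_diagnostic_sites(aln4, groups4)
  expect_true(all(c("g1", "g2") %in% d4$group))
  expect_error(find_diagnostic_sites(aln4, groups4[c(1, 2, 5), ]), "unlabeled")
})

test_that("planted diagnostic columns are recovered exactly in the noise-free limit", {
  p <- default_sim_params()
  p$rate <- 0  # no background substitution
  ds <- generate_study_like_dataset(seed = 3, params = p)
  d <- find_diagnostic_sites(ds$alignment, ds$groups)
  d <- d[d$strict, , drop = FALSE]
  for (g in names(p$diag_columns)) {
    expect_setequal(d$column[d$group == g], p$diag_columns[[g]])
  }
  # post-hoc definition check on every reported site
  g <- ds$groups
  for (i in seq_len(nrow(d))) {
    members <- g$sample[g$group == d$group[i] & !g$outgroup]
    others <- g$sample[g$group != d$group[i] & !g$outgroup]
    col <- ds$alignment[, d$column[i]]
    expect_true(all(col[members] == d$state[i]))
    expect_false(d$state[i] %in% col[others])
  }
})
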