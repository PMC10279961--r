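test_that("distance models match their closed forms", {
  aln <- as_alignment(c(a = "AAAAAAAATT", b = "AAAAAAAAAA", c = "AAAAAAAAAA"))
  dp <- distance_matrix(aln, model = "p")
  expect_equal(dp["a", "b"], 0.2)
  expect_equal(dp["b", "c"], 0)
  dj <- distance_matrix(aln, model = "JC69")
  expect_equal(dj["a", "b"], -0.75 * log(1 - 0.8 / 3), tolerance = 1e-12)

  # K2P on a column set with known transition/transversion split:
  # a vs b has one transition (A<->G) and two transversions (C<->A, G<->T)
  aln2 <- as_alignment(c(a = "AAAACCCCGG", b = "GAAAACCCGT", c = "AAAACCCCGG"))
  dk <- distance_matrix(aln2, model = "K2P")
  P <- 0.1; Q <- 0.2
  expect_equal(dk["a", "b"],
               -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
               tolerance = 1e-12)

  # cross-check against ape's implementations on low-divergence data
  set.seed(401)
  aln3 <- diverged_alignment(6L, 300L, nmut = 12L)
  bin <- ape::as.DNAbin(tolower(aln3))
  ape_model <- c(p = "raw", JC69 = "JC69", K2P = "K80")
  for (mod in c("p", "JC69", "K2P")) {
    ours <- distance_matrix(aln3, model = mod)
    theirs <- as.matrix(ape::dist.dna(bin, model = ape_model[[mod]]))
    expect_equal(unname(ours), unname(theirs[rownames(ours), colnames(ours)]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  # saturation handling replaces non-finite distances
  far <- as_alignment(c(a = strrep("A", 20L), b = strrep("G", 20L),
                        c = strrep("A", 20L)))
  expect_warning(dsat <- distance_matrix(far, model = "JC69"), "saturated")
  expect_true(all(is.finite(dsat)))
})

test_that("neighbor joining solves the three-point case and additive matrices exactly", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3L,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d3)
  len <- setNames(tr$edge.length[match(seq_along(tr$tip.label),
                                       tr$edge[, 2L])], tr$tip.label)
  expect_equal(len[["A"]], 1)
  expect_equal(len[["B"]], 1)
  expect_equal(len[["C"]], 3)

  # 4-taxon additive matrix from ((A:1,B:2):1,(C:3,D:4))
  gen <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  dm <- cophenetic(gen)
  tr4 <- neighbor_joining(dm)
  expect_true(is_group_monophyletic(tr4, c("A", "B"))$monophyletic)
  co <- cophenetic(tr4)
  expect_equal(co[rownames(dm), colnames(dm)], dm, tolerance = 1e-9)

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2L)), "symmetric")
  # degenerate equidistant matrix still yields a valid binary unrooted tree
  deq <- matrix(1, 4L, 4L, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  trd <- neighbor_joining(deq)
  expect_s3_class(trd, "phylo")
  expect_equal(length(trd$tip.label), 4L)
  expect_true(all(trd$edge.length >= 0))
})

test_that("NJ recovers random additive trees and matches ape's implementation", {
  set.seed(402)
  for (rep in 1:10) {
    n <- sample(4:8, 1L)
    gen <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    dm <- cophenetic(gen)
    tr <- neighbor_joining(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen), tr)), 0)
    co <- cophenetic(tr)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(co - dm)), 1e-9)
    # independent route: ape's own NJ finds the same topology
    expect_equal(as.numeric(ape::dist.topo(ape::nj(dm), tr)), 0)
  }
})

test_that("monophyly checks agree with ape on random trees and handle edge cases", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_group_monophyletic(tr, c("A", "B"))$monophyletic)
  expect_false(is_group_monophyletic(tr, c("A", "C"))$monophyletic)
  expect_true(is_group_monophyletic(tr, "A")$monophyletic)
  expect_error(is_group_monophyletic(tr, c("A", "B", "C", "D")), "proper")

  set.seed(403)
  for (rep in 1:15) {
    n <- sample(5:12, 1L)
    tr <- ape::unroot(ape::rtree(n))
    grp <- sample(tr$tip.label, sample(2:(n - 1L), 1L))
    got <- is_group_monophyletic(tr, grp)$monophyletic
    want <- ape::is.monophyletic(tr, grp)
    expect_identical(got, want)
  }
})

test_that("bootstrap supports are seeded, bounded, and strong for clean splits", {
  set.seed(404)
  # two clearly separated 4-taxon groups: 20 fixed differences
  base <- rand_seq(400L)
  rows <- setNames(rep(base, 8L), c(paste0("g", 1:4), paste0("h", 1:4)))
  aln <- as_alignment(rows)
  diff_cols <- seq(10L, 390L, 20L)
  for (co in diff_cols) {
    alt <- setdiff(c("A", "C", "G", "T"), aln[1L, co])[1L]
    aln[5:8, co] <- alt
  }
  st <- bootstrap_support(aln, B = 100L, seed = 1L)
  key <- plastidscan:::.bip_key(paste0("g", 1:4), rownames(aln))
  expect_gte(st$support[[key]], 95)

  # bit-for-bit reproducibility given the seed
  st2 <- bootstrap_support(aln, B = 100L, seed = 1L)
  expect_identical(st$support, st2$support)
  # seed-to-seed Monte-Carlo wobble is modest at B=200
  sa <- bootstrap_support(aln, B = 200L, seed = 5L)$support[[key]]
  sb <- bootstrap_support(aln, B = 200L, seed = 6L)$support[[key]]
  expect_lt(abs(sa - sb), 10)
  # B = 1 gives all-or-nothing supports
  s1 <- bootstrap_support(aln, B = 1L, seed = 2L)
  expect_true(all(s1$support %in% c(0, 100)))
})

test_that("bootstrap support grows with the number of planted diagnostic sites", {
  set.seed(405)
  mean_support <- vapply(c(0L, 2L, 10L), function(k) {
    vals <- vapply(1:3, function(s) {
      base <- rand_seq(300L)
      rows <- setNames(rep(base, 8L), c(paste0("g", 1:4), paste0("h", 1:4)))
      aln <- as_alignment(rows)
      # light noise
      for (i in 1:8) {
        co <- sample(300L, 3L)
        aln[i, co] <- vapply(aln[i, co], function(b)
          setdiff(c("A", "C", "G", "T"), b)[1L], "")
      }
      if (k > 0L) for (co in sample(300L, k)) {
        aln[1:4, co] <- "A"; aln[5:8, co] <- "G"
      }
      st <- bootstrap_support(aln, B = 200L, seed = s)
      key <- plastidscan:::.bip_key(paste0("g", 1:4), rownames(aln))
      v <- st$support[key]
      if (is.na(v)) 0 else unname(v)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_support) >= -1e-9))
  expect_gt(mean_support[3L], mean_support[1L])
})

test_that("discrimination applies the monophyly-plus-support rule with strict threshold", {
  ds <- generate_study_like_dataset(seed = 2)
  reg <- extract_region(ds$alignment, ds$truth$barcode$core)
  res <- evaluate_discrimination(reg, ds$groups, B = 200L, seed = 2L)
  multi <- res[res$n > 1L, ]
  expect_true(all(multi$monophyletic))
  expect_true(all(multi$success))
  # singleton group: trivially monophyletic, indeterminate success
  single <- res[res$n == 1L, ]
  expect_true(all(single$monophyletic))
  expect_true(all(is.na(single$support)))
  expect_true(all(is.na(single$success)))

  # an invariant region cannot discriminate any multi-sample group
  ident <- matrix("T", nrow(reg), 50L,
                  dimnames = list(rownames(reg), NULL))
  res0 <- evaluate_discrimination(ident, ds$groups, B = 50L, seed = 1L)
  expect_true(all(res0$success[res0$n > 1L] == FALSE))

  # permuted labels break at least one group
  set.seed(406)
  resp <- evaluate_discrimination(reg, permute_groups(ds$groups),
                                  B = 200L, seed = 2L)
  expect_true(any(resp$success == FALSE, na.rm = TRUE))
})
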