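test_that("planted inverted repeat is found exactly, at any rotation and on either strand", {
  set.seed(101)
  fx <- planted_ir_genome(lsc = 1000L, ir = 300L, ssc = 200L)
  g <- fx$genome

  ir <- find_maximal_inverted_repeat(g, min_len = 100L)
  expect_equal(ir$length, 300L)
  expect_equal(ir$mismatches, 0L)
  expect_equal(ir$a_start, 1001L)
  expect_equal(ir$b_start, 1501L)
  # exactness: copy A equals reverse complement of copy B
  a <- substr(g$seq, ir$a_start, ir$a_start + ir$length - 1L)
  b <- substr(g$seq, ir$b_start, ir$b_start + ir$length - 1L)
  expect_identical(a, revcomp(b))

  p <- partition_quadripartite(g, ir)
  expect_equal(p$lsc_size, 1000L)
  expect_equal(p$ssc_size, 200L)
  expect_equal(p$ir_size, 300L)
  expect_equal(p$lsc_size + p$ssc_size + 2L * p$ir_size, 1800L)

  # rotation invariance (including the spec's 777 shift)
  for (rot in c(1L, 777L, 1234L)) {
    gr <- circular_genome("rot", plastidscan:::rotate_seq(g$seq, rot))
    irr <- find_maximal_inverted_repeat(gr, min_len = 100L)
    pr <- partition_quadripartite(gr, irr)
    expect_equal(irr$length, 300L)
    expect_equal(c(pr$lsc_size, pr$ssc_size, pr$ir_size), c(1000L, 200L, 300L))
    expect_identical(canonical_sequence(gr, pr), canonical_sequence(g, p))
  }

  # strand invariance
  gs <- circular_genome("rc", revcomp(g$seq))
  ps <- partition_quadripartite(gs, find_maximal_inverted_repeat(gs, 100L))
  expect_equal(c(ps$lsc_size, ps$ssc_size, ps$ir_size), c(1000L, 200L, 300L))
})

test_that("random sequences yield no long inverted repeat; input validation works", {
  set.seed(102)
  g <- circular_genome("rand", rand_seq(5000L))
  expect_null(find_maximal_inverted_repeat(g, min_len = 100L))
  expect_error(find_maximal_inverted_repeat(g, min_len = 50L), "min_len")
  expect_error(find_maximal_inverted_repeat(circular_genome("short", rand_seq(150L)),
                                            min_len = 100L), "twice")
  expect_error(circular_genome("bad", "ACGTXZ"), "non-IUPAC")
})

test_that("seed-and-extend agrees with exhaustive diagonal enumeration", {
  set.seed(103)
  for (rep in 1:6) {
    lsc <- sample(400:900, 1L); ir <- sample(100:250, 1L)
    ssc <- sample(150:350, 1L)
    fx <- planted_ir_genome(lsc, ir, ssc)
    s <- plastidscan:::rotate_seq(fx$genome$seq, sample(nchar(fx$genome$seq), 1L))
    got <- find_maximal_inverted_repeat(circular_genome("x", s), min_len = 100L)
    want <- oracle_find_ir(s, min_len = 100L)
    expect_false(is.null(got))
    expect_equal(got$length, want$length)
    expect_setequal(c(got$a_start, got$b_start), c(want$a_start, want$b_start))
  }
})

test_that("mismatch budget extends the repeat through planted differences", {
  set.seed(104)
  fx <- planted_ir_genome(lsc = 800L, ir = 300L, ssc = 200L)
  s <- fx$genome$seq
  # corrupt one base in the middle of copy A
  pos <- 800L + 150L
  old <- substr(s, pos, pos)
  substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  g <- circular_genome("mm", s)
  exact <- find_maximal_inverted_repeat(g, min_len = 100L, max_mismatch = 0L)
  tol <- find_maximal_inverted_repeat(g, min_len = 100L, max_mismatch = 1L)
  expect_lt(exact$length, 300L)      # split by the mismatch
  expect_equal(tol$length, 300L)
  expect_lte(tol$mismatches, 1L)
})

test_that("gc_content follows its definition and rejects all-ambiguous input", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("ATGCN"), 0.5)
  expect_error(gc_content("NNNN"), "undefined")
})

test_that("removing one IR yields LSC+IRa+SSC and refuses linear input", {
  set.seed(105)
  fx <- planted_ir_genome(1000L, 300L, 200L)
  g <- fx$genome
  p <- partition_quadripartite(g, find_maximal_inverted_repeat(g, 100L))
  lin <- remove_one_ir(g, p)
  expect_equal(nchar(lin), 1800L - 300L)
  expect_identical(lin, substr(canonical_sequence(g, p), 1L, 1500L))
  glin <- circular_genome("lin", lin, circular = FALSE)
  expect_error(remove_one_ir(glin, p), "linear")
})

test_that("equal-length single-copy arcs are labeled deterministically with a warning", {
  set.seed(106)
  guard <- function(n) paste0("A", rand_seq(n - 2L), "A")
  L <- guard(300L); R <- rand_seq(150L); S <- guard(300L)
  g <- circular_genome("eq", paste0(L, R, S, revcomp(R)))
  ir <- find_maximal_inverted_repeat(g, min_len = 100L)
  expect_warning(p1 <- partition_quadripartite(g, ir), "equal")
  expect_warning(p2 <- partition_quadripartite(g, ir), "equal")
  expect_identical(p1$rotation_offset, p2$rotation_offset)
})

test_that("GenBank records parse and gene counts collapse IR duplicates", {
  gb <- read_genbank(system.file("extdata", "synthetic_mini.gb",
                                 package = "plastidscan"))
  expect_length(gb, 1L)
  rec <- gb[[1L]]
  expect_true(rec$circular)
  expect_equal(nchar(rec$seq), 280L)
  sm <- summarize_genbank_record(rec)
  expect_true(sm$genes_available)
  # psbA appears twice (IR duplicate) and counts once; trnH-GUG is a tRNA
  expect_equal(sm$n_gene, 2L)
  expect_equal(sm$n_trna, 1L)
  expect_equal(sm$n_rrna, 1L)
  expect_equal(sm$n_total, 4L)
})

test_that("gene summaries without features flag counts as unavailable", {
  g <- circular_genome("nofeat", rand_seq(500L))
  sm <- summarize_genbank_record(g)
  expect_false(sm$genes_available)
  expect_true(is.na(sm$n_total))
  # toy duplicated-gene record built directly
  f <- data.frame(name = c("a", "b", "b", "t1", "r1"),
                  start = c(1, 101, 301, 401, 421),
                  end = c(90, 200, 400, 420, 460),
                  strand = "+", kind = c("gene", "gene", "gene", "tRNA", "rRNA"))
  g2 <- circular_genome("toy", rand_seq(500L), features = f)
  sm2 <- summarize_genbank_record(g2)
  expect_equal(sm2$n_gene, 2L)  # b duplicated in the repeat counts once
  expect_equal(sm2$n_trna, 1L)
  expect_equal(sm2$n_rrna, 1L)
})
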