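test_that("local alignment matches the worked examples", {
  h <- local_align("CW", "CW")
  expect_equal(h$raw_score, 20)
  expect_equal(h$identity, 1)
  h0 <- local_align("AAAA", "CCCC")
  expect_equal(h0$raw_score, 0)
  expect_equal(h0$q_start, h0$q_end)
  set.seed(2)
  m <- blosum62()
  for (rep in 1:10) {
    p <- random_peptide(sample(4:30, 1))
    hs <- local_align(p, p)
    expect_equal(hs$identity, 1)
    expect_equal(hs$raw_score,
                 sum(diag(m)[match(strsplit(p, "")[[1]], rownames(m))]))
  }
})

test_that("local alignment equals the independent R DP oracle", {
  set.seed(10)
  m <- blosum62()
  for (rep in 1:400) {
    q <- random_peptide(sample(1:8, 1))
    s <- random_peptide(sample(1:8, 1))
    expect_identical(local_align(q, s)$raw_score,
                     as.integer(oracle_sw_score(q, s, m)))
  }
})

test_that("local alignment agrees with Biostrings as a second oracle", {
  skip_if_not_installed("Biostrings")
  set.seed(11)
  # gapOpening 10 / gapExtension 1 reproduces cost open + extend*(g-1)
  # with open = 11, extend = 1
  mat <- blosum62()
  for (rep in 1:60) {
    q <- random_peptide(sample(5:40, 1))
    s <- random_peptide(sample(5:40, 1))
    ours <- local_align(q, s)$raw_score
    ref <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 10, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(ours, max(0, ref))
  }
})

test_that("alignment score is symmetric and monotone under extension", {
  set.seed(12)
  for (rep in 1:30) {
    a <- random_peptide(sample(3:20, 1))
    b <- random_peptide(sample(3:20, 1))
    expect_equal(local_align(a, b)$raw_score, local_align(b, a)$raw_score)
    a2 <- paste0(a, random_peptide(3))
    b2 <- paste0(random_peptide(2), b)
    expect_gte(local_align(a2, b2)$raw_score, local_align(a, b)$raw_score)
  }
})

test_that("Karlin-Altschul statistics follow the closed form", {
  ev <- alignment_evalue(20, 2, 2)
  expect_equal(ev$bit_score, (0.267 * 20 - log(0.041)) / log(2),
               tolerance = 1e-12)
  expect_equal(ev$bit_score, 12.31, tolerance = 1e-3)
  expect_equal(ev$evalue, 7.9e-4, tolerance = 0.01)
  ev0 <- alignment_evalue(0, 5, 7)
  expect_equal(ev0$bit_score, -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(alignment_evalue(30, 10, 2000)$evalue,
               alignment_evalue(30, 10, 1000)$evalue * 2, tolerance = 1e-12)
  bits <- vapply(0:50, function(s) alignment_evalue(s, 10, 100)$bit_score, 1)
  expect_true(all(diff(bits) > 0))             # affine, increasing
  expect_equal(var(diff(bits)), 0, tolerance = 1e-18)
  es <- vapply(0:50, function(s) alignment_evalue(s, 10, 100)$evalue, 1)
  expect_true(all(diff(es) < 0))               # E monotone decreasing
})

test_that("translated search finds planted proteins on both strands", {
  set.seed(20)
  prots <- vapply(1:5, function(i) random_peptide(60), "")
  db <- protein_db(paste0("p", 1:5), prots, toxin_class = "fam")
  target <- prots[3]
  nt <- reverse_translate(target)
  hits <- search_translated(seq_record("q", nt), db)
  expect_gt(nrow(hits), 0)
  expect_equal(hits$subject_id[1], "p3")
  expect_equal(hits$frame[1], 1L)
  expect_equal(hits$identity[1], 1)
  hits_rc <- search_translated(seq_record("qrc", reverse_complement(nt)), db)
  expect_equal(hits_rc$subject_id[1], "p3")
  expect_lt(hits_rc$frame[1], 0L)
  # random contig vs unrelated proteins: nothing at 1e-5
  rand <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(nrow(search_translated(seq_record("r", rand), db)), 0L)
})

test_that("best_hit breaks ties deterministically", {
  expect_null(best_hit(NULL))
  h <- data.frame(query_id = "q", subject_id = c("s1", "s2"),
                  bit_score = c(50, 40), evalue = c(1e-9, 1e-7))
  expect_equal(best_hit(h)$subject_id, "s1")
  h2 <- data.frame(query_id = "q", subject_id = c("b", "a"),
                   bit_score = c(40, 40), evalue = c(1e-7, 1e-7))
  expect_equal(best_hit(h2)$subject_id, "a")
})

test_that("global alignment yields scores and corrected distances", {
  g <- global_align("ACDE", "ACDE")
  expect_equal(g$score, 24)
  expect_equal(g$p_distance, 0)
  expect_equal(g$poisson_distance, 0)
  a <- strrep("A", 9)
  g2 <- global_align(paste0(a, "C"), paste0(a, "D"))
  expect_equal(g2$p_distance, 0.1)
  expect_equal(g2$poisson_distance, -log(0.9), tolerance = 1e-9)
  # saturated distance hits the ceiling, never infinity
  g3 <- global_align("AAAA", "CCCC")
  expect_true(is.finite(g3$poisson_distance))
  expect_equal(global_align("AAAA", "CCCC", dist_ceiling = 7)$poisson_distance
               <= 7, TRUE)
})

test_that("NCBI matrix files load and X scores zero", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test matrix", "   A  C  X", "A  4  0  0", "C  0  9  0",
               "X  0  0  0"), f)
  m <- read_score_matrix(f)
  expect_equal(m["A", "A"], 4L)
  expect_equal(m["C", "C"], 9L)
  sch <- scoring_scheme(matrix = m, gap_open = 2L, gap_extend = 1L)
  expect_equal(local_align("AXA", "ACA", sch)$raw_score, 8L)
  # default scheme: X-containing translation neither rewards nor penalizes
  expect_equal(blosum62()["X", "W"], 0L)
})

test_that("hits export as 12-column outfmt-6 TSV with 1-based coordinates", {
  set.seed(21)
  p <- random_peptide(40)
  db <- protein_db("s", p, toxin_class = "fam")
  hits <- search_translated(seq_record("q", reverse_translate(p)), db)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, f)
  out <- read.delim(f, header = FALSE)
  expect_equal(ncol(out), 12L)
  expect_equal(out$V1[1], "q")
  expect_equal(out$V9[1], hits$s_start[1] + 1L)
  expect_equal(out$V10[1], hits$s_end[1])
})
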