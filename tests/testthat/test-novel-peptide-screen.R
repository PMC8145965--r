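test_that("expression gate keeps high-expression no-hit contigs with ties", {
  set.seed(40)
  n <- 200
  ids <- sprintf("c%03d", 1:n)
  fpkm <- data.frame(contig_id = ids, count = rep(5L, n),
                     fpkm = sort(runif(n, 1, 1000), decreasing = TRUE))
  no_hits <- data.frame(query_id = character(0), evalue = numeric(0))
  top <- no_hit_high_expression(ids, no_hits, fpkm)
  expect_gte(length(top), 5L)                 # ceiling(0.025 * 200)
  expect_setequal(top, ids[1:length(top)])
  # a single significant hit excludes a contig regardless of expression
  hit <- data.frame(query_id = ids[1], evalue = 1e-8)
  expect_false(ids[1] %in% no_hit_high_expression(ids, hit, fpkm))
  # a non-significant hit does not
  weak <- data.frame(query_id = ids[1], evalue = 1e-3)
  expect_true(ids[1] %in% no_hit_high_expression(ids, weak, fpkm))
  # degenerate quantile: everything passes
  expect_setequal(no_hit_high_expression(ids, no_hits, fpkm,
                                         top_fraction = 1), ids)
  # ties at the threshold are included
  fpkm2 <- fpkm
  fpkm2$fpkm <- c(rep(100, 10), rep(1, n - 10))
  expect_setequal(no_hit_high_expression(ids, no_hits, fpkm2), ids[1:10])
})

test_that("signal-peptide heuristic follows the hydropathy rules", {
  p <- paste0("MKT", strrep("L", 8), "AGVSAA", strrep("Q", 30))
  cl <- detect_signal_peptide(p)
  expect_false(is.null(cl))
  expect_true(cl >= 12 && cl <= 35)
  expect_null(detect_signal_peptide(paste0("M", strrep("K", 30))))
  expect_null(detect_signal_peptide(paste0("M", strrep("L", 10))))
  # negative n-region charge rejects
  neg <- paste0("MDE", strrep("L", 8), "AGVSAA", strrep("Q", 30))
  expect_null(detect_signal_peptide(neg))
})

test_that("transmembrane heuristic needs a filled 19-residue window", {
  expect_true(has_tm_helix(paste0(strrep("S", 5), strrep("L", 19))))
  expect_false(has_tm_helix(strrep("S", 40)))
  # a short hydrophobic stretch diluted by polar flanks never fills a window
  expect_false(has_tm_helix(paste0(strrep("L", 9), strrep("D", 30))))
  expect_false(has_tm_helix(strrep("L", 18)))   # shorter than the window
})

test_that("knottin framework requires six correctly spaced cysteines", {
  pad <- function(x) paste0(strrep("S", 6), x, strrep("S", 12))
  five <- pad("CKAKCGGGGCCSKLC")
  expect_false(match_knottin_framework(five)$matched)
  good <- pad("CKAKCGGGGCCSKLCGGGGC")   # gaps 3,4,0,3,4
  fw <- match_knottin_framework(good)
  expect_true(fw$matched)
  expect_equal(diff(fw$cys_positions) - 1L, c(3L, 4L, 0L, 3L, 4L))
  expect_equal(fw$connectivity, "C1-C4,C2-C5,C3-C6")
  tight <- pad("CKCGGGGCCSKLCGGGGCAK")  # C1-C2 gap 1
  expect_false(match_knottin_framework(tight)$matched)
  expect_false(match_knottin_framework(strrep("S", 20))$matched)  # too short
})

test_that("screen gates compose: expression, signal, TM, framework", {
  set.seed(41)
  kp <- venomscreen:::.knottin_protein()
  knot_nt <- paste0("TAA", reverse_translate(kp$peptide), "TAA")
  # a secreted peptide without the six-cysteine framework
  plain <- paste0(kp$signal, strrep("SDGQ", 15))
  plain_nt <- paste0("TAA", reverse_translate(plain), "TAA")
  contigs <- list(knot = seq_record("knot", knot_nt),
                  plain = seq_record("plain", plain_nt),
                  low = seq_record("low", paste0("TAA",
                    reverse_translate(venomscreen:::.knottin_protein()$peptide),
                    "TAA")))
  fpkm <- data.frame(contig_id = c("knot", "plain", "low"),
                     count = c(100L, 100L, 1L),
                     fpkm = c(1000, 900, 0.01))
  hits <- data.frame(query_id = character(0), evalue = numeric(0))
  calls <- screen_novel(contigs, hits, fpkm, top_fraction = 0.5)
  expect_equal(calls$contig_id, "knot")
  expect_equal(calls$signal_cleavage, kp$cleavage)
  expect_equal(calls$mature, kp$mature)
  # raising the expression fraction never removes calls
  calls2 <- screen_novel(contigs, hits, fpkm, top_fraction = 1)
  expect_true(all(calls$contig_id %in% calls2$contig_id))
  expect_true("low" %in% calls2$contig_id)
  # forcing the knottin below the gate removes it
  fpkm3 <- fpkm; fpkm3$fpkm <- c(0.01, 900, 1000); fpkm3$count <- c(1L, 100L, 100L)
  calls3 <- screen_novel(contigs, hits, fpkm3, top_fraction = 0.34)
  expect_false("knot" %in% calls3$contig_id)
})

test_that("every call re-checks against all five gates independently", {
  b <- tiny_bundle()
  # use the full default bundle machinery on a small synthetic set instead:
  set.seed(42)
  contigs <- list()
  for (i in 1:4) {
    kp <- venomscreen:::.knottin_protein()
    id <- paste0("k", i)
    contigs[[id]] <- seq_record(id, paste0("TAA",
      reverse_translate(kp$peptide), "TAA"))
  }
  fpkm <- data.frame(contig_id = names(contigs), count = 10L,
                     fpkm = c(40, 30, 20, 10))
  hits <- data.frame(query_id = character(0), evalue = numeric(0))
  calls <- screen_novel(contigs, hits, fpkm, top_fraction = 1)
  expect_equal(nrow(calls), 4L)
  for (i in seq_len(nrow(calls))) {
    pep <- calls$peptide[i]
    cl <- detect_signal_peptide(pep)
    expect_equal(cl, calls$signal_cleavage[i])
    mature <- substring(pep, cl)
    expect_false(has_tm_helix(mature))
    expect_true(match_knottin_framework(mature)$matched)
    expect_equal(substring(pep, cl), calls$mature[i])
  }
})
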