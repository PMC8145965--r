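degap <- function(x) gsub("-", "", x)

test_that("center-star alignment degenerates correctly and round-trips", {
  set.seed(70)
  a <- random_peptide(30)
  b <- random_peptide(28)
  msa2 <- center_star_align(c(A = a, B = b))
  g <- global_align(a, b)
  expect_setequal(degap(unclass(msa2)), degap(c(g$q_gapped, g$s_gapped)))
  # identical sequences: gap-free alignment
  p <- random_peptide(25)
  msa5 <- center_star_align(setNames(rep(p, 5), paste0("t", 1:5)))
  expect_true(all(!grepl("-", unclass(msa5))))
  expect_equal(unique(nchar(unclass(msa5))), 25L)
  # degapping returns the inputs, including with indels
  seqs <- c(x = paste0(p, "WWWW"), y = p,
            z = paste0(substring(p, 1, 10), "AAA", substring(p, 11)))
  msa <- center_star_align(seqs)
  expect_equal(unique(nchar(unclass(msa))), nchar(unclass(msa)[[1]]))
  expect_equal(degap(unclass(msa))[names(seqs)], seqs)
})

test_that("gappy columns are dropped by threshold", {
  msa <- structure(c(a = "AC-E", b = "AC-E", c = "A--E", d = "ACDE",
                     e = "AC-E"), class = "msa")
  t1 <- drop_gappy_columns(msa, 0.5)
  expect_equal(unclass(t1)[["a"]], "ACE")   # column 3 gapped in 4/5
  expect_equal(unclass(drop_gappy_columns(msa, 1.0))[["a"]], "AC-E")
  allgap <- structure(c(a = "--", b = "--"), class = "msa")
  expect_error(drop_gappy_columns(allgap), "columns")
  gapfree <- structure(c(a = "ACDE", b = "ACDE"), class = "msa")
  expect_identical(unclass(drop_gappy_columns(gapfree)), unclass(gapfree))
})

test_that("neighbor joining solves the three- and four-taxon cases", {
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  dd <- ape::cophenetic.phylo(t3)
  expect_equal(dd[rownames(d3), colnames(d3)], d3, tolerance = 1e-9)
  # direct branch lengths: leaves at 1, 1, 3 from the center
  el <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(el[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  d4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]], d4,
               tolerance = 1e-9)
  # AB|CD topology with internal branch 1
  nwk <- ape::write.tree(t4)
  expect_true(grepl("A:1", nwk) && grepl("B:2", nwk))
  internal <- t4$edge.length[t4$edge[, 2] > 4]
  expect_equal(internal, 1, tolerance = 1e-9)

  # ultrametric star: zero internal branch
  ds <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(ds) <- 0
  ts <- nj_tree(ds)
  expect_equal(ts$edge.length[ts$edge[, 2] > 4], 0, tolerance = 1e-9)
})

test_that("NJ is exact on random additive matrices", {
  set.seed(71)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    d <- random_additive_matrix(n)
    tr <- nj_tree(d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("NJ agrees with the ape reference implementation on topology", {
  set.seed(72)
  for (rep in 1:10) {
    d <- random_additive_matrix(6)
    ours <- nj_tree(d)
    ref <- ape::nj(as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours), ape::unroot(ref))), 0)
  }
})

test_that("bootstrap supports are reproducible and bounded", {
  set.seed(73)
  base <- random_peptide(40)
  seqs <- c(t1 = base, t2 = base,
            t3 = venomscreen:::.mutate_protein(base, 0.5),
            t4 = venomscreen:::.mutate_protein(base, 0.5))
  msa <- center_star_align(seqs)
  b1 <- bootstrap_support(msa, n_reps = 30, seed = 9)
  b2 <- bootstrap_support(msa, n_reps = 30, seed = 9)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  # topology equals the full-alignment NJ tree
  expect_equal(as.numeric(ape::dist.topo(
    ape::unroot(b1), ape::unroot(nj_tree(msa_distances(msa))))), 0)
})

test_that("unanimous alignments give 100% support", {
  # two clearly distinct duplicated blocks: every column supports t1t2|t3t4
  seqs <- c(t1 = strrep("AD", 15), t2 = strrep("AD", 15),
            t3 = strrep("YW", 15), t4 = strrep("YW", 15))
  msa <- center_star_align(seqs)
  tr <- bootstrap_support(msa, n_reps = 40, seed = 4)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})

test_that("midpoint rooting bisects the longest leaf path", {
  d4 <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- nj_tree(d4)
  r <- midpoint_root(t4)
  expect_equal(sum(r$edge.length), sum(t4$edge.length), tolerance = 1e-9)
  # the two ends of the longest path (C and D, length 7) sit 3.5 from root
  dn <- ape::dist.nodes(r)
  root <- ape::Ntip(r) + 1L
  dC <- dn[match("C", r$tip.label), root]
  dD <- dn[match("D", r$tip.label), root]
  expect_equal(dC, 3.5, tolerance = 1e-9)
  expect_equal(dD, 3.5, tolerance = 1e-9)
  skip_if_not_installed("phangorn")
  ref <- phangorn::midpoint(t4)
  dn2 <- ape::dist.nodes(ref)
  expect_equal(dn2[match("C", ref$tip.label), ape::Ntip(ref) + 1L], 3.5,
               tolerance = 1e-9)
})

test_that("Newick serialization round-trips", {
  set.seed(74)
  d <- random_additive_matrix(6)
  tr <- nj_tree(d)
  tr$node.label <- c("", "87.5", "100", "33.1")[seq_len(tr$Nnode)]
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- read_newick(f)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(back), ape::unroot(tr))), 0)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-9)
  expect_setequal(back$node.label, tr$node.label)
})

test_that("distance matrices round-trip through TSV", {
  set.seed(75)
  d <- random_additive_matrix(5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(d, f)
  expect_equal(read_distance_tsv(f), d, tolerance = 1e-12)
})
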