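# Independent oracles and shared fixtures.

# Plain-R affine-gap Smith-Waterman score, written independently of the
# package's C++ kernel (full matrices, different formulation).
oracle_sw_score <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  n <- length(qa); m <- length(sa)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open, F[i - 1, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qa[i - 1], sa[j - 1]],
                     E[i, j], F[i, j])
    }
  }
  max(H)
}

# Upper-tail chi-square probability by numerical integration of the density.
oracle_chisq_upper <- function(x, df) {
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, lower = x, upper = Inf, rel.tol = 1e-12,
                   abs.tol = 1e-14)$value
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")

random_peptide <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

# Random additive distance matrix: random binary-ish tree with positive
# branch lengths; returns the path-length (cophenetic) matrix, the oracle
# for NJ exactness.
random_additive_matrix <- function(n_taxa) {
  labs <- paste0("t", seq_len(n_taxa))
  # grow a tree by attaching leaves to random edges of a 3-leaf star
  nwk <- sprintf("(t1:%.4f,t2:%.4f,t3:%.4f);", runif(1, .5, 2),
                 runif(1, .5, 2), runif(1, .5, 2))
  tr <- ape::read.tree(text = nwk)
  if (n_taxa > 3) for (k in 4:n_taxa) {
    e <- sample(nrow(tr$edge), 1L)
    tr <- ape::bind.tree(tr,
      ape::read.tree(text = sprintf("(%s:%.4f);", labs[k], runif(1, .5, 2))),
      where = tr$edge[e, 2], position = runif(1, 0.1, 0.9) *
        tr$edge.length[e])
  }
  tr$node.label <- NULL
  ape::cophenetic.phylo(ape::unroot(tr))
}

# A deliberately small simulated universe for fast classifier/pipeline
# tests: one kazal-like family with a reciprocal probe, one toxin-like
# housekeeping decoy, no knottins.
tiny_config <- function(seed = 11L) {
  fams <- data.frame(toxin_class = c("kazal", "CAP"),
                     genes_per_species = c(3L, 2L),
                     expansion_factor = c(1L, 1L),
                     protein_len = c(130L, 200L),
                     keyword_text = c("Kazal-type protease inhibitor",
                                      "CAP superfamily allergen"),
                     stringsAsFactors = FALSE)
  sim_config(seed = seed, families = fams,
             n_housekeeping = 4L, n_toxinlike_hk = 1L, n_noise = 3L,
             n_knottins = 0L, n_truncated = c(NTE = 1L, CTE = 1L, NC = 0L),
             n_split_pairs = 1L, n_probe = c(kazal = 1L))
}

.fixture_env <- new.env(parent = emptyenv())

tiny_bundle <- function() {
  if (is.null(.fixture_env$tiny)) .fixture_env$tiny <-
      simulate_bundle(tiny_config())
  .fixture_env$tiny
}

tiny_candidates <- function() {
  if (is.null(.fixture_env$tiny_cand)) {
    b <- tiny_bundle()
    .fixture_env$tiny_cand <- classify_transcriptome(
      b$transcriptome, b$counts, b$annotations, b$toxin_db, b$animal_db)
  }
  .fixture_env$tiny_cand
}
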