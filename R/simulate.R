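# Seeded synthetic transcriptome bundle with planted ground truth.

#' Default simulated toxin-family table
#'
#' Per-family baseline gene counts per comparison species, the focal-species
#' expansion factor, ancestor protein length, and the annotation phrase
#' attached to focal transcripts of the family. The focal gene count of a
#' family is `genes_per_species * expansion_factor`. The family mix mirrors
#' the per-family candidate-count spectrum typical of a lepidopteran
#' venom-gland transcriptome, with a five-fold expanded chymotrypsin-family
#' serine protease (peptidase S1) component.
#'
#' @return Data.frame with columns `toxin_class`, `genes_per_species`,
#'   `expansion_factor`, `protein_len`, `keyword_text`.
#' @export
default_families <- function() {
  data.frame(
    toxin_class = c("peptidase_S1", "trypsin_inhibitor", "kazal",
                    "carboxylesterase6", "antimicrobial_peptide",
                    "c_type_lectin", "peptidase_S10", "serpin",
                    "dipeptidyl_peptidase4", "CAP", "phospholipase_A2",
                    "acid_phosphatase", "kunitz", "lipocalin"),
    genes_per_species = c(12L, 16L, 15L, 14L, 12L, 10L, 8L, 8L, 6L, 5L,
                          5L, 3L, 3L, 3L),
    expansion_factor = c(5L, rep(1L, 13L)),
    protein_len = c(250L, 120L, 130L, 300L, 120L, 160L, 320L, 380L, 400L,
                    220L, 140L, 350L, 120L, 170L),
    keyword_text = c("venom serine protease precursor",
                     "venom trypsin inhibitor precursor",
                     "Kazal-type protease inhibitor",
                     "venom carboxylesterase-6",
                     "venom antimicrobial peptide",
                     "venom C-type lectin",
                     "venom peptidase S10",
                     "serpin B4-like",
                     "venom dipeptidyl peptidase 4",
                     "CAP superfamily allergen",
                     "phospholipase A2",
                     "venom acid phosphatase",
                     "Kunitz-type protease inhibitor",
                     "venom lipocalin"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' @param seed Integer seed driving every random draw.
#' @param n_species Number of species (focal + comparison; default 5).
#' @param families Family table as in [default_families()].
#' @param divergence Per-branch substitution probability (default 0.15,
#'   maximum 0.35).
#' @param paralog_divergence Divergence between gene lineages within a
#'   family (default 0.15).
#' @param n_housekeeping Housekeeping genes (default 50), of which
#'   `n_toxinlike_hk` are serine-protease-like decoys with toxin-keyword
#'   annotations but a near-identical animal-database source (default 6).
#' @param n_noise Dinucleotide-resampled noise contigs (default 50).
#' @param n_knottins Novel secreted knottin contigs (default 8).
#' @param n_truncated Named vector: truncated extra genes per type
#'   (default `c(NTE = 3, CTE = 3, NC = 3)`).
#' @param n_split_pairs Genes split over two overlapping contigs
#'   (default 2).
#' @param count_mu,count_sigma Log-normal parameters of per-contig mean
#'   counts (log scale; defaults 3 and 1.5).
#' @param nb_size Negative-binomial dispersion (default 5).
#' @param knottin_multiplier Knottin mean-count multiplier applied to the
#'   median per-contig mean (default 50).
#' @param top_fraction Expression gate the knottins are planted to clear
#'   (default 0.025).
#' @param n_probe Named integer vector: per-family count of recent-paralog
#'   "probe" genes carrying neutral annotation text (recovered only by the
#'   reciprocal search).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 42L, n_species = 5L,
                       families = default_families(),
                       divergence = 0.15, paralog_divergence = 0.15,
                       n_housekeeping = 50L, n_toxinlike_hk = 6L,
                       n_noise = 50L, n_knottins = 8L,
                       n_truncated = c(NTE = 3L, CTE = 3L, NC = 3L),
                       n_split_pairs = 2L,
                       count_mu = 3, count_sigma = 1.5, nb_size = 5,
                       knottin_multiplier = 50, top_fraction = 0.025,
                       n_probe = c(peptidase_S1 = 2L, kazal = 1L,
                                   c_type_lectin = 1L)) {
  stopifnot(divergence > 0, divergence <= 0.35, n_species >= 2L,
            all(n_truncated >= 0L), n_split_pairs >= 0L, n_knottins >= 0L)
  if (any(families$genes_per_species < 1L & families$expansion_factor > 1L))
    stop("expansion configured on a family with no genes")
  if (!all(names(n_probe) %in% families$toxin_class))
    stop("probe family not in the family table")
  if (any(n_probe > families$genes_per_species[
        match(names(n_probe), families$toxin_class)] *
        families$expansion_factor[match(names(n_probe),
                                        families$toxin_class)]))
    stop("more probes than focal genes in a family")
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 families = families, divergence = divergence,
                 paralog_divergence = paralog_divergence,
                 n_housekeeping = as.integer(n_housekeeping),
                 n_toxinlike_hk = as.integer(n_toxinlike_hk),
                 n_noise = as.integer(n_noise),
                 n_knottins = as.integer(n_knottins),
                 n_truncated = n_truncated,
                 n_split_pairs = as.integer(n_split_pairs),
                 count_mu = count_mu, count_sigma = count_sigma,
                 nb_size = nb_size, knottin_multiplier = knottin_multiplier,
                 top_fraction = top_fraction, n_probe = n_probe),
            class = "sim_config")
}

#' Plant a lineage-specific family expansion
#'
#' Multiplies the focal-species gene count of one family (rounded); other
#' species are unchanged.
#'
#' @param config A [sim_config()].
#' @param family Toxin-class token present in the family table.
#' @param focal_multiplier Multiplier (>= 0).
#' @return The modified config.
#' @export
plant_expansion <- function(config, family, focal_multiplier) {
  i <- match(family, config$families$toxin_class)
  if (is.na(i)) stop("unknown family: ", family)
  config$families$expansion_factor[i] <-
    max(1L, as.integer(round(config$families$expansion_factor[i] *
                             focal_multiplier)))
  config
}

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
           "S","T","W","Y","V")

.random_protein <- function(len, start_met = TRUE) {
  aa <- sample(.AA20, len, replace = TRUE)
  if (start_met) aa[1] <- "M"
  paste(aa, collapse = "")
}

# Point substitution at rate `div`; positions in `invariant` (1-based) and
# position 1 are never touched; cysteines in `keep_cys` stay cysteine.
.mutate_protein <- function(p, div, invariant = integer(0)) {
  aa <- strsplit(p, "")[[1]]
  hit <- which(runif(length(aa)) < div)
  hit <- setdiff(hit, c(1L, invariant))
  for (i in hit) aa[i] <- sample(setdiff(.AA20, aa[i]), 1L)
  paste(aa, collapse = "")
}

.random_utr <- function(min_len = 20L, max_len = 80L) {
  paste(sample(c("A", "C", "G", "T"), sample(min_len:max_len, 1L),
               replace = TRUE), collapse = "")
}

.stop_codon <- function() sample(c("TAA", "TAG", "TGA"), 1L)

# Contig from a (possibly truncated) peptide. `stop_after` appends a stop
# codon (present C terminus). An in-frame stop always precedes the insert
# so the reading frame opens exactly at the planted peptide (upstream UTR
# ATGs cannot extend the gene model).
.make_contig <- function(peptide, stop_after = TRUE) {
  paste0(.random_utr(), .stop_codon(), reverse_translate(peptide),
         if (stop_after) .stop_codon() else "",
         .random_utr())
}

# Guarantee a methionine within the first 5 residues of an N-truncated
# fragment so ORF start-trimming cannot erode the alignable region.
.ensure_early_met <- function(p) {
  head5 <- strsplit(substring(p, 1, 5), "")[[1]]
  if (!"M" %in% head5) substr(p, 3, 3) <- "M"
  p
}

.knottin_protein <- function() {
  small <- c("A", "G", "S", "C", "T", "V")
  polar <- c("D", "E", "G", "S", "T", "N", "Q", "K", "R", "H", "P", "Y")
  mature_polar <- setdiff(polar, small)  # keep position c+1 non-small
  repeat {
    nreg <- paste(sample(c("K", "R"), sample(2:4, 1L), replace = TRUE),
                  collapse = "")
    core <- paste(sample(c("L", "I"), sample(8:10, 1L), replace = TRUE),
                  collapse = "")
    signal <- paste0("M", nreg, core, "SALA")
    pre <- sample(3:5, 1L)
    gaps <- c(sample(5:9, 1L), sample(8:13, 1L), sample(2:6, 1L),
              sample(4:9, 1L), sample(8:16, 1L))
    tail_len <- sample(8:16, 1L)
    mature_len <- pre + 6L + sum(gaps) + tail_len
    if (mature_len < 46L || mature_len > 71L) next
    filler <- function(n) paste(sample(mature_polar, n, replace = TRUE),
                                collapse = "")
    mature <- paste0(filler(pre), "C", filler(gaps[1]), "C",
                     filler(gaps[2]), "C", filler(gaps[3]), "C",
                     filler(gaps[4]), "C", filler(gaps[5]), "C",
                     filler(tail_len))
    return(list(signal = signal, mature = mature,
                peptide = paste0(signal, mature),
                cleavage = nchar(signal) + 1L))
  }
}

.neutral_names <- c("ribosomal protein L3", "elongation factor 1-alpha",
                    "tubulin beta chain", "actin-related protein 2",
                    "heat shock cognate 70", "ATP synthase subunit beta",
                    "cytochrome c oxidase subunit", "histone H2A",
                    "ubiquitin-conjugating enzyme",
                    "glyceraldehyde-3-phosphate dehydrogenase")

# Dinucleotide-preserving noise: a first-order Markov resample of the
# pooled real contigs.
.dinucleotide_noise <- function(pool, len) {
  nts <- c("A", "C", "G", "T")
  trans <- matrix(1, 4, 4, dimnames = list(nts, nts))  # +1 smoothing
  for (s in pool) {
    v <- strsplit(s, "")[[1]]
    v <- v[v %in% nts]
    if (length(v) < 2L) next
    for (k in seq_len(length(v) - 1L))
      trans[v[k], v[k + 1L]] <- trans[v[k], v[k + 1L]] + 1
  }
  trans <- trans / rowSums(trans)
  out <- character(len)
  out[1] <- sample(nts, 1L)
  for (k in 2:len) out[k] <- sample(nts, 1L, prob = trans[out[k - 1L], ])
  paste(out, collapse = "")
}

#' Simulate a labeled venom-gland transcriptome bundle
#'
#' Generates, from a single seed, a toxin protein database (comparison
#' species homologs), a general animal protein database (housekeeping
#' proteins, each toxin's strictly-more-divergent closest relative, and
#' venomous-taxon decoys), a focal-species transcriptome with planted toxin
#' genes (including N/C-truncated and split gene models and
#' neutral-annotation "probe" paralogs), housekeeping and noise contigs and
#' novel secreted knottin peptides, a heavy-tailed fragment-count table,
#' an annotation-keyword table, and per-contig truth labels.
#'
#' Margins are enforced by construction: every pipeline threshold is
#' cleared by at least ~25 percent in planted positives and missed by at
#' least ~25 percent in planted negatives (see the package vignette for
#' the full list of guarantees).
#'
#' @param config A [sim_config()].
#' @return A list (`sim_bundle`) with `toxin_db`, `animal_db`,
#'   `transcriptome` (named list of [seq_record()]s), `counts`,
#'   `annotations`, `truth`, `planted_counts` (family x species matrix
#'   of planted gene counts, focal species first), `knottin_truth`, and
#'   `config`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  fam <- config$families
  n_sp <- config$n_species
  species <- c("Plepida", paste0("sp", LETTERS[seq_len(n_sp - 1L)]))
  focal <- species[1L]
  div <- config$divergence
  pdiv <- config$paralog_divergence

  tox_db <- list(); an_db <- list()
  contigs <- list(); truth <- list(); annotations <- list()
  planted <- matrix(0L, nrow(fam), n_sp,
                    dimnames = list(fam$toxin_class, species))
  ctg_i <- 0L
  next_ctg <- function() { ctg_i <<- ctg_i + 1L; sprintf("ctg%04d", ctg_i) }
  add_tox_entry <- function(id, protein, taxon, class) {
    tox_db[[length(tox_db) + 1L]] <<- data.frame(
      id = id, protein = protein, taxon = taxon, is_venomous = TRUE,
      toxin_class = class, stringsAsFactors = FALSE)
  }
  add_an_entry <- function(id, protein, taxon, venomous = FALSE) {
    an_db[[length(an_db) + 1L]] <<- data.frame(
      id = id, protein = protein, taxon = taxon, is_venomous = venomous,
      toxin_class = NA_character_, stringsAsFactors = FALSE)
  }
  add_truth <- function(contig_id, class, toxin_class = NA_character_,
                        completeness = NA_character_,
                        join_partner = NA_character_,
                        source_protein = NA_character_,
                        expected_provenance = NA_character_) {
    truth[[length(truth) + 1L]] <<- data.frame(
      contig_id = contig_id, class = class, toxin_class = toxin_class,
      completeness = completeness, join_partner = join_partner,
      source_protein = source_protein,
      expected_provenance = expected_provenance, stringsAsFactors = FALSE)
  }
  add_annot <- function(id, text) {
    annotations[[length(annotations) + 1L]] <<- data.frame(
      unigene_id = id, text = text, stringsAsFactors = FALSE)
  }
  add_contig <- function(nt, ...) {
    id <- next_ctg()
    contigs[[id]] <<- seq_record(id, nt, "nucleotide")
    add_truth(id, ...)
    id
  }
  # animal relative of a focal toxin gene: derived from a comparison-species
  # toxin-db copy with extra divergence (strictly farther than the toxin db)
  rel_i <- 0L
  add_far_relative <- function(sp_copy) {
    rel_i <<- rel_i + 1L
    add_an_entry(sprintf("anmrel%04d", rel_i),
                 .mutate_protein(sp_copy, div), "Bmori")
  }

  ## --- toxin families -----------------------------------------------------
  ancestors <- list()
  for (f in seq_len(nrow(fam))) {
    class <- fam$toxin_class[f]
    G <- fam$genes_per_species[f]
    n_focal <- G * fam$expansion_factor[f]
    n_probe <- if (class %in% names(config$n_probe))
      config$n_probe[[class]] else 0L
    ancestor <- .random_protein(fam$protein_len[f])
    ancestors[[class]] <- ancestor
    lineage <- lapply(seq_len(G), function(g)
      .mutate_protein(ancestor, pdiv))
    sp_copies <- list()
    for (g in seq_len(G)) {
      sp_copies[[g]] <- character(n_sp - 1L)
      for (s in seq_len(n_sp - 1L)) {
        cp <- .mutate_protein(lineage[[g]], div)
        sp_copies[[g]][s] <- cp
        add_tox_entry(sprintf("tox%s.g%02d.%s", class, g, species[s + 1L]),
                      cp, species[s + 1L], class)
        planted[class, s + 1L] <- planted[class, s + 1L] + 1L
      }
    }
    n_regular <- n_focal - n_probe
    focal_prot <- character(n_regular)
    for (i in seq_len(n_regular)) {
      g <- ((i - 1L) %% G) + 1L
      focal_prot[i] <- .mutate_protein(lineage[[g]], div)
      id <- add_contig(.make_contig(focal_prot[i]), "toxin", class, "Full",
                       expected_provenance = "keyword")
      add_annot(id, paste0("putative ", fam$keyword_text[f]))
      planted[class, 1L] <- planted[class, 1L] + 1L
      if (class == "CAP") {
        # venomous-taxon decoy: closer than the toxin db, but flagged
        add_an_entry(sprintf("anmvesp%02d", i),
                     .mutate_protein(focal_prot[i], 0.05),
                     "Vespa", venomous = TRUE)
      } else {
        add_far_relative(sp_copies[[g]][1L])
      }
    }
    for (pr in seq_len(n_probe)) {
      p <- .mutate_protein(focal_prot[pr], 0.05)
      id <- add_contig(.make_contig(p), "toxin", class, "Full",
                       expected_provenance = "reciprocal")
      add_annot(id, "hypothetical protein")
      planted[class, 1L] <- planted[class, 1L] + 1L
      add_far_relative(sp_copies[[((pr - 1L) %% G) + 1L]][1L])
    }
  }

  ## --- truncated and split gene models (extra peptidase S1 lineages) -----
  host <- "peptidase_S1"
  if (!host %in% fam$toxin_class) host <- fam$toxin_class[1L]
  host_anc <- ancestors[[host]]   # same ancestor: extras stay in the family
  extra_i <- 0L
  new_extra_gene <- function() {
    extra_i <<- extra_i + 1L
    lin <- .mutate_protein(host_anc, pdiv)
    copies <- character(n_sp - 1L)
    for (s in seq_len(n_sp - 1L)) {
      copies[s] <- .mutate_protein(lin, div)
      add_tox_entry(sprintf("tox%s.x%02d.%s", host, extra_i,
                            species[s + 1L]),
                    copies[s], species[s + 1L], host)
      planted[host, s + 1L] <<- planted[host, s + 1L] + 1L
    }
    planted[host, 1L] <<- planted[host, 1L] + 1L
    list(protein = .mutate_protein(lin, div), copies = copies)
  }
  host_kw <- fam$keyword_text[match(host, fam$toxin_class)]
  for (type in c("NTE", "CTE", "NC")) {
    for (k in seq_len(config$n_truncated[[type]])) {
      gene <- new_extra_gene()
      L <- nchar(gene$protein)
      cut_n <- sample(40:50, 1L)
      cut_c <- sample(40:50, 1L)
      frag <- switch(type,
        NTE = .ensure_early_met(substring(gene$protein, cut_n + 1L)),
        CTE = substring(gene$protein, 1L, L - cut_c),
        NC = .ensure_early_met(substring(gene$protein, cut_n + 1L,
                                         L - cut_c)))
      id <- add_contig(.make_contig(frag, stop_after = type == "NTE"),
                       "toxin", host, type, source_protein = gene$protein,
                       expected_provenance = "keyword")
      add_annot(id, paste0("putative ", host_kw, " fragment"))
      add_far_relative(gene$copies[1L])
    }
  }
  for (k in seq_len(config$n_split_pairs)) {
    gene <- new_extra_gene()
    L <- nchar(gene$protein)
    a_end <- floor(L * 0.56)                 # ~140 of 250
    b_start <- a_end - sample(24:28, 1L)     # 25ish-residue overlap
    fragA <- substring(gene$protein, 1L, a_end)
    fragB <- .ensure_early_met(substring(gene$protein, b_start + 1L))
    # dedicated close sister entry -> both fragments share one best subject
    sister <- .mutate_protein(gene$protein, 0.03)
    add_tox_entry(sprintf("tox%s.sister%02d.%s", host, k, species[2L]),
                  sister, species[2L], host)
    planted[host, 2L] <- planted[host, 2L] + 1L
    # the N-terminal fragment's frame closes at a stop so its gene model is
    # exactly the planted fragment; the CTE tag still comes from the
    # subject-span margin, not from the stop
    idA <- add_contig(.make_contig(fragA, stop_after = TRUE), "toxin",
                      host, "CTE", source_protein = gene$protein,
                      expected_provenance = "keyword")
    idB <- add_contig(.make_contig(fragB), "toxin", host, "NTE",
                      join_partner = idA, source_protein = gene$protein,
                      expected_provenance = "keyword")
    truth[[length(truth) - 1L]]$join_partner <- idB
    add_annot(idA, paste0("putative ", host_kw, " fragment"))
    add_annot(idB, paste0("putative ", host_kw, " fragment"))
    add_far_relative(gene$copies[1L])
  }

  ## --- housekeeping -------------------------------------------------------
  s1_anc_hk <- .random_protein(260L)
  for (h in seq_len(config$n_housekeeping)) {
    toxinlike <- h <= config$n_toxinlike_hk
    if (toxinlike) {
      # related to the serine-protease fold (so it scores against the toxin
      # db and carries a protease keyword) but with a near-identical
      # animal-db source: the dual filter must reject it
      lin <- .mutate_protein(host_anc, 0.25)
      hk_gene <- .mutate_protein(lin, 0.05)
      animal_src <- .mutate_protein(hk_gene, 0.05)
      id <- add_contig(.make_contig(hk_gene), "housekeeping")
      add_annot(id, "digestive serine protease")
      add_an_entry(sprintf("anmhk%03d", h), animal_src, "Dmelanogaster")
    } else {
      hk_gene <- .random_protein(sample(150:400, 1L))
      animal_src <- .mutate_protein(hk_gene, 0.05)
      id <- add_contig(.make_contig(hk_gene), "housekeeping")
      add_annot(id, paste0(.neutral_names[((h - 1L) %% 10L) + 1L], " ",
                           h))
      add_an_entry(sprintf("anmhk%03d", h), animal_src, "Dmelanogaster")
    }
  }

  ## --- knottins ------------------------------------------------------------
  knottin_truth <- list()
  for (k in seq_len(config$n_knottins)) {
    kp <- .knottin_protein()
    id <- add_contig(.make_contig(kp$peptide), "knottin")
    knottin_truth[[length(knottin_truth) + 1L]] <- data.frame(
      contig_id = id, peptide = kp$peptide, signal_cleavage = kp$cleavage,
      mature = kp$mature, stringsAsFactors = FALSE)
  }

  ## --- noise ---------------------------------------------------------------
  pool <- vapply(contigs[seq_len(min(30L, length(contigs)))], `[[`, "",
                 "residues")
  lens <- vapply(contigs, function(x) nchar(x$residues), 1L)
  for (k in seq_len(config$n_noise)) {
    add_contig(.dinucleotide_noise(pool, sample(lens, 1L)), "noise")
  }

  ## --- counts --------------------------------------------------------------
  n_ctg <- length(contigs)
  if (ceiling(config$top_fraction * n_ctg) < config$n_knottins)
    stop("transcriptome too small: the top-", config$top_fraction,
         " set cannot hold ", config$n_knottins, " knottins")
  truth_df <- do.call(rbind, truth)
  lambda <- rlnorm(n_ctg, config$count_mu, config$count_sigma)
  is_knot <- truth_df$class == "knottin"
  lambda[is_knot] <- config$knottin_multiplier * median(lambda)
  cnt <- rnbinom(n_ctg, size = config$nb_size, mu = lambda)
  cnt[cnt < 1L] <- 1L   # an assembled contig has at least one fragment
  len_bp <- unname(vapply(contigs, function(x) nchar(x$residues), 1L))
  # plant the knottins above the top-fraction gate with a >= 30% rate margin
  max_rate <- max(cnt[!is_knot] / len_bp[!is_knot])
  bump <- ceiling(1.3 * max_rate * len_bp[is_knot])
  cnt[is_knot] <- pmax(cnt[is_knot], bump)
  counts <- data.frame(contig_id = names(contigs), length_bp = len_bp,
                       count = cnt, stringsAsFactors = FALSE)

  tox_db_df <- do.call(rbind, tox_db)
  an_db_df <- do.call(rbind, an_db)
  structure(list(
    toxin_db = protein_db(tox_db_df$id, tox_db_df$protein, tox_db_df$taxon,
                          tox_db_df$is_venomous, tox_db_df$toxin_class),
    animal_db = protein_db(an_db_df$id, an_db_df$protein, an_db_df$taxon,
                           an_db_df$is_venomous, an_db_df$toxin_class),
    transcriptome = contigs,
    counts = counts,
    annotations = do.call(rbind, annotations),
    truth = truth_df,
    planted_counts = planted,
    knottin_truth = do.call(rbind, knottin_truth),
    config = config), class = "sim_bundle")
}

#' Write / read a simulated bundle as plain files
#'
#' Writes the same FASTA/TSV formats the pipeline reads: transcriptome
#' FASTA, both databases (FASTA + metadata TSV), counts TSV, annotations
#' TSV, and truth/planted-count tables.
#'
#' @param bundle A `sim_bundle`.
#' @param dir Directory (created if needed).
#' @return `dir`, invisibly (`read_bundle` returns a list).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$transcriptome, p("transcriptome.fasta"))
  write_protein_db(bundle$toxin_db, p("toxin_db.fasta"), p("toxin_db.tsv"))
  write_protein_db(bundle$animal_db, p("animal_db.fasta"),
                   p("animal_db.tsv"))
  write.table(bundle$counts, p("counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$annotations, p("annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_count_table(bundle$planted_counts, p("planted_counts.tsv"))
  invisible(dir)
}

#' @rdname write_bundle
#' @param dir Directory written by `write_bundle`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  need <- c("transcriptome.fasta", "toxin_db.fasta", "toxin_db.tsv",
            "animal_db.fasta", "animal_db.tsv", "counts.tsv")
  for (f in need) if (!file.exists(p(f))) stop("missing bundle file: ", f)
  out <- list(
    transcriptome = read_fasta(p("transcriptome.fasta")),
    toxin_db = read_protein_db(p("toxin_db.fasta"), p("toxin_db.tsv")),
    animal_db = read_protein_db(p("animal_db.fasta"), p("animal_db.tsv")),
    counts = read_counts_tsv(p("counts.tsv")),
    annotations = if (file.exists(p("annotations.tsv")))
      read.delim(p("annotations.tsv"), stringsAsFactors = FALSE) else NULL,
    truth = if (file.exists(p("truth.tsv")))
      read.delim(p("truth.tsv"), stringsAsFactors = FALSE) else NULL,
    planted_counts = if (file.exists(p("planted_counts.tsv")))
      read_count_table(p("planted_counts.tsv")) else NULL)
  out
}
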