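# Orthologous-family counting and the gene-family expansion chi-square test.

#' Cluster proteins into families by single-linkage similarity
#'
#' All-vs-all local alignment; an edge joins two proteins when the hit
#' E-value is at most `evalue_max` and identity over aligned columns is at
#' least `min_identity`. Connected components are families; each family is
#' labeled by the majority `toxin_class` of its members (ties broken
#' lexicographically, unlabeled members ignored; a fully unlabeled family
#' gets `"unassigned"`). Pairs already connected through earlier edges are
#' skipped (exact for single linkage), and the same k-mer prescreen as
#' [db_search_index()] gates candidate pairs.
#'
#' @param proteins Data.frame with columns `id`, `protein`, `species` and
#'   optionally `toxin_class` (NA allowed).
#' @param scheme A [scoring_scheme()].
#' @param evalue_max E-value cutoff for edges (default 1e-5).
#' @param min_identity Identity floor for edges (default 0.4).
#' @param prefilter_k Prescreen word size (0 disables).
#' @return A list with `counts` (integer matrix families x species),
#'   `membership` (data.frame `id`, `species`, `family`) and `families`
#'   (family labels in matrix row order).
#' @export
cluster_families <- function(proteins, scheme = scoring_scheme(),
                             evalue_max = 1e-5, min_identity = 0.4,
                             prefilter_k = 5L) {
  stopifnot(all(c("id", "protein", "species") %in% names(proteins)),
            !anyDuplicated(proteins$id))
  n <- nrow(proteins)
  if (!"toxin_class" %in% names(proteins))
    proteins$toxin_class <- NA_character_
  db_residues <- sum(nchar(proteins$protein))
  ab <- rownames(scheme$matrix)
  enc <- lapply(proteins$protein, .encode_protein, alphabet = ab)

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  # candidate pairs via shared k-mers (or all pairs)
  if (prefilter_k > 0L) {
    kmers <- lapply(proteins$protein, function(s) {
      L <- nchar(s)
      if (L < prefilter_k) return(character(0))
      unique(substring(s, 1:(L - prefilter_k + 1L), prefilter_k:L))
    })
    groups <- split(rep(seq_len(n), lengths(kmers)), unlist(kmers))
    keys <- unlist(lapply(groups, function(ids) {
      m <- length(ids)
      if (m < 2L) return(numeric(0))
      ids <- sort(ids)
      cc <- utils::combn(ids, 2L)
      cc[1L, ] * (n + 1) + cc[2L, ]
    }), use.names = FALSE)
    keys <- sort(unique(keys))
    pairs <- cbind(as.integer(keys %/% (n + 1)),
                   as.integer(keys %% (n + 1)))
  } else {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- cbind(pairs[, 1L], pairs[, 2L])
  }
  if (nrow(pairs)) {
    o <- order(pairs[, 1L], pairs[, 2L])
    pairs <- pairs[o, , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (find(i) == find(j)) next
      a <- .cpp_pair_align(enc[[i]], enc[[j]], scheme$matrix,
                           scheme$gap_open, scheme$gap_extend, TRUE)
      if (a$score <= 0 || a$aligned_cols == 0L) next
      ev <- alignment_evalue(a$score, nchar(proteins$protein[i]),
                             db_residues, scheme)$evalue
      if (ev <= evalue_max && a$matches / a$aligned_cols >= min_identity)
        unite(i, j)
    }
  }

  comp <- vapply(seq_len(n), find, 1L)
  comp_ids <- sort(unique(comp))
  labels <- vapply(comp_ids, function(cid) {
    cls <- proteins$toxin_class[comp == cid]
    cls <- cls[!is.na(cls)]
    if (!length(cls)) return("unassigned")
    tt <- table(cls)
    sort(names(tt)[tt == max(tt)])[1L]
  }, "")
  # disambiguate repeated labels across distinct components
  fam <- labels[match(comp, comp_ids)]
  if (anyDuplicated(labels)) {
    for (lb in unique(labels[duplicated(labels)])) {
      which_comp <- comp_ids[labels == lb]
      for (k in seq_along(which_comp))
        fam[comp == which_comp[k]] <- paste0(lb, ".", k)
    }
  }
  species <- sort(unique(proteins$species))
  fams <- sort(unique(fam))
  counts <- t(vapply(fams, function(f)
    vapply(species, function(s) sum(fam == f & proteins$species == s), 1L),
    integer(length(species))))
  dimnames(counts) <- list(fams, species)
  list(counts = counts,
       membership = data.frame(id = proteins$id, species = proteins$species,
                               family = fam, stringsAsFactors = FALSE),
       families = fams)
}

#' Chi-square goodness-of-fit test against equal category counts
#'
#' Tests whether per-species gene counts of a family deviate from a 1:1
#' ratio: expected counts are the category mean, the statistic is
#' `sum((O - E)^2 / E)` with `df = length(counts) - 1`, and the p-value is
#' the upper-tail chi-square probability. A warning is emitted when any
#' expected cell is below 1 (the asymptotic approximation is then poor).
#'
#' @param counts Integer vector of per-category gene counts (length >= 2).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_gof <- function(counts) {
  stopifnot(length(counts) >= 2L, sum(counts) > 0)
  e <- mean(counts)
  if (e < 1) warning("expected cell count below 1; chi-square approximation unreliable")
  stat <- sum((counts - e)^2 / e)
  df <- length(counts) - 1L
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Gene-family expansion report
#'
#' Applies [chi_square_gof()] to every family whose gene count exceeds
#' `min_genes` in every species; other families are reported untested.
#' Significance is flagged at `alpha` on the raw p-values (no
#' multiple-testing correction, matching how such per-family tests are
#' conventionally reported).
#'
#' @param counts Integer matrix families x species (as from
#'   [cluster_families()]).
#' @param min_genes Gate: test only families with more than this many genes
#'   in all species (default 5).
#' @param alpha Significance level (default 0.05).
#' @return Data.frame: `family`, `statistic`, `df`, `p_value`, `tested`,
#'   `significant`.
#' @export
expansion_report <- function(counts, min_genes = 5L, alpha = 0.05) {
  stopifnot(is.matrix(counts), nrow(counts) >= 1L)
  rows <- lapply(rownames(counts), function(f) {
    v <- counts[f, ]
    if (all(v > min_genes)) {
      r <- chi_square_gof(v)
      data.frame(family = f, statistic = r$statistic, df = r$df,
                 p_value = r$p_value, tested = TRUE,
                 significant = r$p_value < alpha, stringsAsFactors = FALSE)
    } else {
      data.frame(family = f, statistic = NA_real_, df = NA_integer_,
                 p_value = NA_real_, tested = FALSE, significant = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write a family-count table (families x species TSV)
#' @param counts Integer matrix with dimnames.
#' @param path File path.
#' @return `write_count_table`: `path` invisibly; `read_count_table`: matrix.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(family = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
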