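# Translated and protein database search.

#' Build a protein database table
#'
#' @param id,protein Character vectors (same length).
#' @param taxon Taxon token per entry.
#' @param is_venomous Logical flag: does the entry come from a venomous or
#'   poisonous taxon?
#' @param toxin_class Toxin family token (required for toxin databases; may
#'   be `NA` for general animal databases).
#' @return A data.frame of class `protein_db`.
#' @export
protein_db <- function(id, protein, taxon = "unknown", is_venomous = FALSE,
                       toxin_class = NA_character_) {
  stopifnot(!anyDuplicated(id), all(nzchar(protein)))
  structure(data.frame(id = id, protein = toupper(protein), taxon = taxon,
                       is_venomous = is_venomous, toxin_class = toxin_class,
                       stringsAsFactors = FALSE),
            class = c("protein_db", "data.frame"))
}

#' Precompute a search index over a protein database
#'
#' Encodes every subject once and builds an exact k-mer occurrence table
#' used to prescreen query/subject pairs: pairs sharing no identical k-mer
#' are skipped (reported as no-hit) before the exact dynamic-programming
#' alignment. Set `prefilter_k = 0` to disable prescreening and align every
#' pair.
#'
#' @param db A [protein_db()] data.frame.
#' @param scheme A [scoring_scheme()].
#' @param prefilter_k Word size of the prescreen (default 5).
#' @return A `db_index` object.
#' @export
db_search_index <- function(db, scheme = scoring_scheme(), prefilter_k = 5L) {
  stopifnot(inherits(db, "data.frame"), nrow(db) >= 1L)
  ab <- rownames(scheme$matrix)
  enc <- lapply(db$protein, .encode_protein, alphabet = ab)
  idx_env <- NULL
  if (prefilter_k > 0L) {
    kmers <- lapply(seq_len(nrow(db)), function(i) {
      s <- db$protein[i]
      n <- nchar(s)
      if (n < prefilter_k) return(character(0))
      unique(substring(s, 1:(n - prefilter_k + 1L), prefilter_k:n))
    })
    tab <- data.frame(kmer = unlist(kmers),
                      idx = rep(seq_len(nrow(db)), lengths(kmers)))
    idx_env <- list2env(split(tab$idx, tab$kmer), hash = TRUE)
  }
  structure(list(db = db, enc = enc, kmer_env = idx_env,
                 k = as.integer(prefilter_k),
                 db_residues = sum(nchar(db$protein)), scheme = scheme),
            class = "db_index")
}

.candidate_subjects <- function(index, query) {
  if (is.null(index$kmer_env)) return(seq_len(nrow(index$db)))
  n <- nchar(query)
  k <- index$k
  if (n < k) return(integer(0))
  km <- unique(substring(query, 1:(n - k + 1L), k:n))
  hit <- mget(km, envir = index$kmer_env, ifnotfound = list(NULL))
  sort(unique(unlist(hit, use.names = FALSE)))
}

# Align one protein query against prescreened subjects of an index.
# q_offset shifts reported query coordinates (used for translated segments).
.align_to_index <- function(query, query_id, index, evalue_max,
                            frame = 0L, q_offset = 0L) {
  scheme <- index$scheme
  ab <- rownames(scheme$matrix)
  qenc <- .encode_protein(query, ab)
  cand <- .candidate_subjects(index, query)
  if (!length(cand)) return(.empty_hits())
  rows <- vector("list", length(cand))
  n_keep <- 0L
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    r <- .cpp_pair_align(qenc, index$enc[[i]], scheme$matrix,
                         scheme$gap_open, scheme$gap_extend, TRUE)
    if (r$score <= 0) next
    st <- alignment_evalue(r$score, nchar(query), index$db_residues, scheme)
    if (st$evalue > evalue_max) next
    n_keep <- n_keep + 1L
    rows[[n_keep]] <- .new_hit(
      query_id, index$db$id[i], r$score, st$bit_score, st$evalue, frame,
      r$q_start + q_offset, r$q_end + q_offset, r$s_start, r$s_end,
      if (r$aligned_cols > 0) r$matches / r$aligned_cols else 0,
      r$aligned_cols)
  }
  if (!n_keep) return(.empty_hits())
  do.call(rbind, rows[seq_len(n_keep)])
}

.sort_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[order(-hits$bit_score, hits$evalue, hits$subject_id), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Stop-free translated segments (>= min_aa residues) of all six frames.
.frame_segments <- function(contig, min_aa = 10L) {
  segs <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_frame(contig$residues, frame)
    if (!nzchar(pep)) next
    parts <- strsplit(pep, "*", fixed = TRUE)[[1]]
    off <- 0L
    for (p in parts) {
      if (nchar(p) >= min_aa)
        segs[[length(segs) + 1L]] <- list(frame = frame, peptide = p,
                                          offset = off)
      off <- off + nchar(p) + 1L
    }
  }
  segs
}

#' Search a nucleotide contig against a protein database (translated)
#'
#' All six reading frames are translated, split at stop codons into
#' stop-free segments of at least `min_seg_aa` residues, and each segment is
#' locally aligned against the database. Hits with `E <= evalue_max` are
#' returned sorted by descending bit score, ascending E-value, then subject
#' id. Query coordinates refer to the full translation of the recorded
#' frame.
#'
#' @param contig A nucleotide [seq_record()].
#' @param db A [protein_db()] or prebuilt [db_search_index()].
#' @param scheme A [scoring_scheme()] (ignored when `db` is an index).
#' @param evalue_max E-value cutoff (default 1e-5).
#' @param min_seg_aa Minimum translated segment length (default 10).
#' @param prefilter_k Prescreen word size (when `db` is not an index).
#' @return Hit data.frame (possibly empty).
#' @export
search_translated <- function(contig, db, scheme = scoring_scheme(),
                              evalue_max = 1e-5, min_seg_aa = 10L,
                              prefilter_k = 5L) {
  stopifnot(inherits(contig, "seq_record"), contig$alphabet == "nucleotide")
  index <- if (inherits(db, "db_index")) db
           else db_search_index(db, scheme, prefilter_k)
  segs <- .frame_segments(contig, min_seg_aa)
  if (!length(segs)) return(.empty_hits())
  hits <- lapply(segs, function(s)
    .align_to_index(s$peptide, contig$id, index, evalue_max,
                    frame = s$frame, q_offset = s$offset))
  .sort_hits(do.call(rbind, hits))
}

#' Search a protein query against a protein database
#'
#' Protein-vs-protein counterpart of [search_translated()] (frame recorded
#' as 0).
#'
#' @param query Protein string.
#' @param query_id Id recorded in hits.
#' @inheritParams search_translated
#' @return Hit data.frame (possibly empty).
#' @export
search_protein <- function(query, query_id, db, scheme = scoring_scheme(),
                           evalue_max = 1e-5, prefilter_k = 5L) {
  index <- if (inherits(db, "db_index")) db
           else db_search_index(db, scheme, prefilter_k)
  .sort_hits(.align_to_index(query, query_id, index, evalue_max))
}
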