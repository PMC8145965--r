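# Pairwise alignment, Karlin-Altschul statistics, hit handling.

.new_hit <- function(query_id, subject_id, raw_score, bit_score, evalue,
                     frame, q_start, q_end, s_start, s_end, identity,
                     aligned_cols) {
  data.frame(query_id = query_id, subject_id = subject_id,
             raw_score = raw_score, bit_score = bit_score, evalue = evalue,
             frame = frame, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, identity = identity,
             aligned_cols = aligned_cols, stringsAsFactors = FALSE)
}

.empty_hits <- function() {
  .new_hit(character(0), character(0), integer(0), numeric(0), numeric(0),
           integer(0), integer(0), integer(0), integer(0), integer(0),
           numeric(0), integer(0))
}

#' Optimal local alignment of two proteins (Smith-Waterman, affine gaps)
#'
#' Exact affine-gap local alignment under the given scheme. When no
#' positive-scoring alignment exists the raw score is 0 and the aligned span
#' is empty. Identity is computed over aligned columns, excluding gapped
#' columns. Coordinates are 0-based half-open.
#'
#' @param query,subject Non-empty protein strings.
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Ids recorded in the returned hit.
#' @return One-row data.frame (an alignment hit) with attributes
#'   `q_aln`/`s_aln`: 0-based residue indices per alignment column (-1 = gap).
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        query_id = "query", subject_id = "subject") {
  stopifnot(nzchar(query), nzchar(subject))
  ab <- rownames(scheme$matrix)
  r <- .cpp_pair_align(.encode_protein(query, ab),
                       .encode_protein(subject, ab),
                       scheme$matrix, scheme$gap_open, scheme$gap_extend,
                       TRUE)
  identity <- if (r$aligned_cols > 0) r$matches / r$aligned_cols else 0
  hit <- .new_hit(query_id, subject_id, r$score, NA_real_, NA_real_, 0L,
                  r$q_start, r$q_end, r$s_start, r$s_end, identity,
                  r$aligned_cols)
  attr(hit, "q_aln") <- r$q_aln
  attr(hit, "s_aln") <- r$s_aln
  hit
}

#' Global alignment of two proteins (Needleman-Wunsch) and p-distance
#'
#' Global affine-gap alignment under the same scheme as [local_align()].
#' The p-distance is the fraction of mismatched columns among non-gap
#' columns; the Poisson-corrected distance is `-log(1 - p)`, reported as
#' `dist_ceiling` when `p` reaches 1 (or when the correction would exceed
#' the ceiling).
#'
#' @inheritParams local_align
#' @param dist_ceiling Finite distance to report when `p = 1` (default 10).
#' @return A list with `score`, `q_gapped`/`s_gapped` (gapped alignment
#'   strings), `p_distance`, `poisson_distance`.
#' @export
global_align <- function(query, subject, scheme = scoring_scheme(),
                         dist_ceiling = 10) {
  stopifnot(nzchar(query), nzchar(subject))
  ab <- rownames(scheme$matrix)
  r <- .cpp_pair_align(.encode_protein(query, ab),
                       .encode_protein(subject, ab),
                       scheme$matrix, scheme$gap_open, scheme$gap_extend,
                       FALSE)
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  qg <- rep("-", length(r$q_aln))
  qg[r$q_aln >= 0] <- qc[r$q_aln[r$q_aln >= 0] + 1L]
  sg <- rep("-", length(r$s_aln))
  sg[r$s_aln >= 0] <- sc[r$s_aln[r$s_aln >= 0] + 1L]
  nongap <- r$q_aln >= 0 & r$s_aln >= 0
  p <- if (any(nongap)) mean(qg[nongap] != sg[nongap]) else 1
  d <- if (p >= 1) dist_ceiling else min(-log(1 - p), dist_ceiling)
  list(score = r$score,
       q_gapped = paste(qg, collapse = ""),
       s_gapped = paste(sg, collapse = ""),
       p_distance = p, poisson_distance = d)
}

#' Bit score and E-value from a raw alignment score
#'
#' Karlin-Altschul statistics: `bit = (lambda * S - log(K)) / log(2)` and
#' `E = m * n * 2^-bit` for query length `m` and database size `n` residues.
#'
#' @param raw_score Raw alignment score (>= 0).
#' @param query_len Query length in residues.
#' @param db_residues Total residues in the searched database.
#' @param scheme A [scoring_scheme()] supplying `lambda` and `K`.
#' @return List with `bit_score` and `evalue`.
#' @export
alignment_evalue <- function(raw_score, query_len, db_residues,
                             scheme = scoring_scheme()) {
  stopifnot(raw_score >= 0, query_len >= 1, db_residues >= 1)
  bit <- (scheme$lambda * raw_score - log(scheme$K)) / log(2)
  list(bit_score = bit, evalue = query_len * db_residues * 2^(-bit))
}

#' Select the best hit from a hit table
#'
#' Maximal bit score; ties broken by lower E-value, then lexicographically
#' smallest subject id. Returns `NULL` for an empty table.
#'
#' @param hits Hit data.frame (rows from one query).
#' @return One-row data.frame or `NULL`.
#' @export
best_hit <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(-hits$bit_score, hits$evalue, hits$subject_id)
  hits[o[1L], , drop = FALSE]
}

#' Export hits as BLAST outfmt-6-style TSV
#'
#' Twelve columns (qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore), with 1-based inclusive coordinates in this
#' export only.
#'
#' @param hits Hit data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  gaps <- rep(0L, nrow(hits))  # per-column gap counts are not retained
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = round(100 * hits$identity, 2), length = hits$aligned_cols,
    mismatch = round(hits$aligned_cols * (1 - hits$identity)),
    gapopen = gaps,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = signif(hits$evalue, 3), bitscore = round(hits$bit_score, 1))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
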