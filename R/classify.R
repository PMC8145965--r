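# Candidate-toxin identification: keyword selection, dual-database filter,
# completeness tagging, fragment merging, reciprocal expansion.

#' Default toxin-related annotation keywords
#'
#' The nine keyword terms used to preselect candidate toxin transcripts
#' from free-text annotations.
#'
#' @return Character vector.
#' @export
toxin_keywords <- function() {
  c("lopap", "serine protease", "protease inhibitor", "serpin", "venom",
    "toxin", "allergen", "CAP", "phospholipase A2")
}

#' Classification configuration
#'
#' @param ... Overrides of the defaults: `evalue_max` (1e-5), `margin`
#'   (completeness margin in residues, 20), `min_overlap` (15),
#'   `min_overlap_identity` (0.9), `min_subject_coverage` (0.4, the
#'   conserved-region proxy: best-toxin-hit span over subject length),
#'   `orf_min_aa` (30), `min_seg_aa` (10), `prefilter_k` (5),
#'   `score_type` ("bit" or "raw", the score compared by the dual filter),
#'   `keywords`, `max_reciprocal_rounds` (3).
#' @return Named list of settings.
#' @export
classify_config <- function(...) {
  cfg <- list(evalue_max = 1e-5, margin = 20L, min_overlap = 15L,
              min_overlap_identity = 0.9, min_subject_coverage = 0.4,
              orf_min_aa = 30L, min_seg_aa = 10L, prefilter_k = 5L,
              score_type = "bit", keywords = toxin_keywords(),
              max_reciprocal_rounds = 3L)
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  modifyList(cfg, over)
}

#' Select transcripts by toxin-related annotation keywords
#'
#' Case-insensitive substring match of each keyword against the annotation
#' text of each transcript.
#'
#' @param annotations Data.frame with `unigene_id` and `text`.
#' @param keywords Character vector (default [toxin_keywords()]).
#' @return Character vector of matching unigene ids (input order).
#' @export
select_by_keywords <- function(annotations, keywords = toxin_keywords()) {
  stopifnot(length(keywords) >= 1L,
            all(c("unigene_id", "text") %in% names(annotations)))
  txt <- tolower(annotations$text)
  hit <- rep(FALSE, nrow(annotations))
  for (k in tolower(keywords)) hit <- hit | grepl(k, txt, fixed = TRUE)
  unique(annotations$unigene_id[hit])
}

#' Dual-database differential filter
#'
#' A candidate is kept when it has no significant general-animal-protein
#' hit, when its toxin-database score is at least as high as the animal
#' score (removal requires the animal score to be strictly higher), or when
#' the best animal hit comes from a venomous or poisonous taxon.
#'
#' @param toxin_score Score of the best toxin-database hit.
#' @param animal_score Score of the best animal-database hit, or `NA`/`NULL`
#'   when there is none.
#' @param animal_is_venomous Is the best animal hit from a venomous taxon?
#' @return Logical: keep the candidate?
#' @export
dual_db_filter <- function(toxin_score, animal_score = NULL,
                           animal_is_venomous = FALSE) {
  if (is.null(animal_score) || is.na(animal_score)) return(TRUE)
  toxin_score >= animal_score || isTRUE(animal_is_venomous)
}

#' Gene-model completeness tag
#'
#' `Full`, `NTE` (N terminus missing), `CTE` (C terminus missing) or `NC`
#' (both missing). The N terminus is complete when the ORF starts at a
#' methionine and the alignment reaches within `margin` residues of the
#' subject N terminus; the C terminus when the ORF ends at a stop codon and
#' the alignment reaches within `margin` residues of the subject C
#' terminus.
#'
#' @param has_start_met,has_stop ORF properties.
#' @param s_start,s_end Subject-aligned span (0-based half-open).
#' @param subject_len Subject protein length.
#' @param margin Residue margin (default 20).
#' @return One of `"Full"`, `"NTE"`, `"CTE"`, `"NC"`.
#' @export
tag_completeness <- function(has_start_met, has_stop, s_start, s_end,
                             subject_len, margin = 20L) {
  n_ok <- has_start_met && s_start < margin
  c_ok <- has_stop && (subject_len - s_end) < margin
  if (n_ok && c_ok) "Full" else if (!n_ok && c_ok) "NTE"
  else if (n_ok && !c_ok) "CTE" else "NC"
}

.display_name <- function(unigene_id, toxin_class, completeness, joined) {
  paste0(unigene_id, "_", toxin_class, "_", completeness,
         if (joined) "_Join" else "")
}

#' Parse a candidate display name back to its fields
#'
#' Names follow `unigene_class_completeness[_Join]`; unigene ids must not
#' contain underscores (the toxin class may).
#'
#' @param name Display-name string.
#' @return List with `unigene_id`, `toxin_class`, `completeness`, `joined`.
#' @export
parse_display_name <- function(name) {
  joined <- grepl("_Join$", name)
  core <- sub("_Join$", "", name)
  parts <- strsplit(core, "_")[[1]]
  if (length(parts) < 3L) stop("malformed display name: ", name)
  list(unigene_id = parts[1L],
       toxin_class = paste(parts[2:(length(parts) - 1L)], collapse = "_"),
       completeness = parts[length(parts)], joined = joined)
}

# Subject-position -> query-residue-index map from a local alignment.
.subject_map <- function(hit) {
  q <- attr(hit, "q_aln"); s <- attr(hit, "s_aln")
  ok <- q >= 0 & s >= 0
  setNames(q[ok], s[ok])
}

# Classify one contig: translated toxin-db search, ORF choice, animal-db
# search, dual filter, coverage gate, completeness tag.
.classify_contig <- function(contig, tox_index, an_index, cfg, provenance) {
  hits <- search_translated(contig, tox_index, evalue_max = cfg$evalue_max,
                            min_seg_aa = cfg$min_seg_aa)
  bh <- best_hit(hits)
  if (is.null(bh)) return(NULL)
  frame <- bh$frame
  orfs <- find_orfs(contig, min_aa = cfg$orf_min_aa)
  orfs <- orfs[orfs$frame == frame, , drop = FALSE]
  if (!nrow(orfs)) return(NULL)
  sub_row <- match(bh$subject_id, tox_index$db$id)
  subject <- tox_index$db$protein[sub_row]
  # the ORF carrying the homologous region: highest realignment score
  realn <- lapply(seq_len(nrow(orfs)), function(k)
    local_align(orfs$peptide[k], subject, tox_index$scheme,
                query_id = contig$id, subject_id = bh$subject_id))
  scores <- vapply(realn, function(h) h$raw_score, 1)
  k <- order(-scores, -nchar(orfs$peptide), orfs$nt_start)[1L]
  orf <- orfs[k, , drop = FALSE]
  oh <- realn[[k]]
  if (oh$raw_score <= 0) return(NULL)
  subject_len <- nchar(subject)
  if ((oh$s_end - oh$s_start) < cfg$min_subject_coverage * subject_len)
    return(NULL)
  st <- alignment_evalue(oh$raw_score, nchar(orf$peptide),
                         tox_index$db_residues, tox_index$scheme)
  oh$bit_score <- st$bit_score
  oh$evalue <- st$evalue
  if (oh$evalue > cfg$evalue_max) return(NULL)
  ah <- best_hit(search_protein(orf$peptide, contig$id, an_index,
                                evalue_max = cfg$evalue_max))
  an_venom <- FALSE
  if (!is.null(ah))
    an_venom <- isTRUE(an_index$db$is_venomous[match(ah$subject_id,
                                                     an_index$db$id)])
  tox_score <- if (cfg$score_type == "raw") oh$raw_score else oh$bit_score
  an_score <- if (is.null(ah)) NA_real_
              else if (cfg$score_type == "raw") ah$raw_score else ah$bit_score
  if (!dual_db_filter(tox_score, an_score, an_venom)) return(NULL)
  toxin_class <- tox_index$db$toxin_class[sub_row]
  completeness <- tag_completeness(orf$has_start_met, orf$has_stop,
                                   oh$s_start, oh$s_end, subject_len,
                                   cfg$margin)
  cand <- data.frame(
    unigene_id = contig$id, protein = orf$peptide, frame = frame,
    toxin_class = toxin_class, completeness = completeness, joined = FALSE,
    provenance = provenance,
    display_name = .display_name(contig$id, toxin_class, completeness,
                                 FALSE),
    toxin_subject = bh$subject_id, subject_len = subject_len,
    toxin_raw = oh$raw_score, toxin_bit = oh$bit_score,
    toxin_evalue = oh$evalue, toxin_identity = oh$identity,
    s_start = oh$s_start, s_end = oh$s_end,
    has_start_met = orf$has_start_met, has_stop = orf$has_stop,
    animal_subject = if (is.null(ah)) NA_character_ else ah$subject_id,
    animal_bit = if (is.null(ah)) NA_real_ else ah$bit_score,
    animal_raw = if (is.null(ah)) NA_real_ else ah$raw_score,
    animal_is_venomous = an_venom, stringsAsFactors = FALSE)
  cand
}

#' Merge two overlapping candidate fragments
#'
#' Two candidates of the same toxin class sharing the same best-hit subject
#' are merged when their subject-aligned spans overlap by at least
#' `min_overlap` residues and the two query sequences agree on at least
#' `min_overlap_identity` of the overlapping columns. The merged protein is
#' the N-terminal candidate up to the end of the overlap (its own residues)
#' followed by the C-terminal candidate's suffix; completeness is
#' re-evaluated on the merged extent and `"_Join"` is appended to the name.
#'
#' @param c1,c2 One-row candidate data.frames (as produced by
#'   [classify_transcriptome()]); `c1` must cover the more N-terminal
#'   subject span.
#' @param toxin_db The toxin [protein_db()] (for the shared subject).
#' @param scheme A [scoring_scheme()].
#' @param min_overlap Minimum subject-span overlap in residues.
#' @param min_overlap_identity Minimum identity across the overlap.
#' @param margin Completeness margin.
#' @return A merged one-row candidate, or `NULL` when the criteria fail.
#' @export
merge_fragments <- function(c1, c2, toxin_db, scheme = scoring_scheme(),
                            min_overlap = 15L, min_overlap_identity = 0.9,
                            margin = 20L) {
  if (c1$toxin_class != c2$toxin_class) return(NULL)
  if (c1$toxin_subject != c2$toxin_subject) return(NULL)
  if (c1$s_start > c2$s_start) return(NULL)
  # only complementary partial gene models are merged: the N-terminal
  # fragment must lack its C terminus and vice versa (full-length paralogs
  # of the same subject must never be fused)
  if (!(c1$completeness %in% c("CTE", "NC")) ||
      !(c2$completeness %in% c("NTE", "NC"))) return(NULL)
  subject <- toxin_db$protein[match(c1$toxin_subject, toxin_db$id)]
  h1 <- local_align(c1$protein, subject, scheme)
  h2 <- local_align(c2$protein, subject, scheme)
  m1 <- .subject_map(h1); m2 <- .subject_map(h2)
  common <- intersect(names(m1), names(m2))
  if (length(common) < min_overlap) return(NULL)
  a1 <- strsplit(c1$protein, "")[[1]]
  a2 <- strsplit(c2$protein, "")[[1]]
  ident <- mean(a1[m1[common] + 1L] == a2[m2[common] + 1L])
  if (ident < min_overlap_identity) return(NULL)
  ov_last <- max(as.integer(common))          # last shared subject position
  cut1 <- m1[as.character(ov_last)] + 1L      # 1-based in c1
  after2 <- m2[as.character(ov_last)] + 1L
  merged <- paste0(substring(c1$protein, 1L, cut1),
                   substring(c2$protein, after2 + 1L))
  hm <- local_align(merged, subject, scheme)
  completeness <- tag_completeness(c1$has_start_met, c2$has_stop,
                                   hm$s_start, hm$s_end, nchar(subject),
                                   margin)
  out <- c1
  out$unigene_id <- paste0(c1$unigene_id, "+", c2$unigene_id)
  out$protein <- merged
  out$completeness <- completeness
  out$joined <- TRUE
  out$has_stop <- c2$has_stop
  out$s_start <- hm$s_start
  out$s_end <- hm$s_end
  out$toxin_raw <- hm$raw_score
  out$toxin_identity <- hm$identity
  out$display_name <- .display_name(out$unigene_id, out$toxin_class,
                                    completeness, TRUE)
  out
}

.merge_pass <- function(candidates, toxin_db, scheme, cfg) {
  if (is.null(candidates) || nrow(candidates) < 2L) return(candidates)
  repeat {
    merged_any <- FALSE
    key <- paste(candidates$toxin_class, candidates$toxin_subject)
    for (grp in unique(key[duplicated(key)])) {
      idx <- which(key == grp)
      idx <- idx[order(candidates$s_start[idx])]
      done <- FALSE
      for (a in seq_len(length(idx) - 1L)) {
        for (b in (a + 1L):length(idx)) {
          m <- merge_fragments(candidates[idx[a], , drop = FALSE],
                               candidates[idx[b], , drop = FALSE],
                               toxin_db, scheme,
                               cfg$min_overlap, cfg$min_overlap_identity,
                               cfg$margin)
          if (!is.null(m)) {
            candidates <- rbind(candidates[-c(idx[a], idx[b]), , drop = FALSE],
                                m)
            merged_any <- TRUE; done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (done) break
    }
    if (!merged_any) break
  }
  candidates
}

# Index of translated stop-free segments over a set of contigs, used by the
# reciprocal (protein -> transcriptome) search.
.transcriptome_index <- function(contigs, cfg, scheme) {
  segs <- lapply(contigs, function(ct) {
    s <- .frame_segments(ct, cfg$min_seg_aa)
    if (!length(s)) return(NULL)
    data.frame(contig_id = ct$id,
               peptide = vapply(s, `[[`, "", "peptide"),
               stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || !nrow(segs)) return(NULL)
  db <- protein_db(id = sprintf("seg%06d", seq_len(nrow(segs))),
                   protein = segs$peptide)
  idx <- db_search_index(db, scheme, cfg$prefilter_k)
  idx$contig_id <- segs$contig_id
  idx
}

#' Reciprocal expansion of a candidate set
#'
#' Candidate toxin proteins are searched back against the transcriptome
#' (translated search); contigs hit at `E <= evalue_max` that are not yet
#' candidates are run through the full classification path (best hits
#' against both databases, dual filter, coverage, completeness) and added
#' with provenance `"reciprocal"`. Iterates until no new candidate is found
#' or `max_reciprocal_rounds` is reached.
#'
#' @param candidates Candidate data.frame.
#' @param transcriptome Named list of nucleotide [seq_record()]s.
#' @param tox_index,an_index Prebuilt [db_search_index()]s.
#' @param cfg A [classify_config()].
#' @return The expanded candidate data.frame.
#' @export
reciprocal_expand <- function(candidates, transcriptome, tox_index, an_index,
                              cfg = classify_config()) {
  scheme <- tox_index$scheme
  in_cand <- function(df) unlist(strsplit(df$unigene_id, "+", fixed = TRUE))
  queries <- candidates
  for (round in seq_len(cfg$max_reciprocal_rounds)) {
    if (is.null(queries) || nrow(queries) == 0L) break
    covered <- in_cand(candidates)
    remaining <- transcriptome[setdiff(names(transcriptome), covered)]
    if (!length(remaining)) break
    tidx <- .transcriptome_index(remaining, cfg, scheme)
    if (is.null(tidx)) break
    hit_contigs <- character(0)
    for (qi in seq_len(nrow(queries))) {
      h <- .align_to_index(queries$protein[qi], queries$unigene_id[qi],
                           tidx, cfg$evalue_max)
      if (nrow(h))
        hit_contigs <- union(hit_contigs,
                             tidx$contig_id[match(h$subject_id, tidx$db$id)])
    }
    if (!length(hit_contigs)) break
    new_rows <- list()
    for (cid in sort(hit_contigs)) {
      cand <- .classify_contig(transcriptome[[cid]], tox_index, an_index,
                               cfg, provenance = "reciprocal")
      if (!is.null(cand)) new_rows[[length(new_rows) + 1L]] <- cand
    }
    if (!length(new_rows)) break
    queries <- do.call(rbind, new_rows)
    candidates <- rbind(candidates, queries)
  }
  candidates
}

#' Identify candidate toxin genes in a transcriptome
#'
#' The full classification pipeline: keyword preselection from annotations,
#' translated search against the toxin database (frame and ORF chosen from
#' the best hit), protein search against the general animal database, the
#' dual-database differential filter with its venomous-taxon exception, a
#' conserved-region coverage gate, completeness tagging, merging of
#' overlapping same-family fragments, and reciprocal expansion back against
#' the transcriptome. Deterministic: identical inputs give identical
#' output.
#'
#' @param transcriptome Named list of nucleotide [seq_record()]s (as from
#'   [read_fasta()]).
#' @param counts Count data.frame (`contig_id`, `length_bp`, `count`);
#'   every row must name a transcriptome contig.
#' @param annotations Data.frame (`unigene_id`, `text`) or `NULL`.
#' @param toxin_db,animal_db [protein_db()] data.frames; toxin entries must
#'   carry `toxin_class`.
#' @param scheme A [scoring_scheme()].
#' @param cfg A [classify_config()].
#' @return Candidate data.frame sorted by `toxin_class`, then
#'   `display_name`.
#' @export
classify_transcriptome <- function(transcriptome, counts, annotations,
                                   toxin_db, animal_db,
                                   scheme = scoring_scheme(),
                                   cfg = classify_config()) {
  ids <- names(transcriptome)
  missing_ct <- setdiff(counts$contig_id, ids)
  if (length(missing_ct))
    stop("counts reference unknown contig(s): ",
         paste(head(missing_ct, 5), collapse = ", "))
  if (!is.null(annotations)) {
    missing_an <- setdiff(annotations$unigene_id, ids)
    if (length(missing_an))
      stop("annotations reference unknown contig(s): ",
           paste(head(missing_an, 5), collapse = ", "))
  }
  if (any(is.na(toxin_db$toxin_class)))
    stop("every toxin-database entry needs a toxin_class")
  tox_index <- db_search_index(toxin_db, scheme, cfg$prefilter_k)
  an_index <- db_search_index(animal_db, scheme, cfg$prefilter_k)
  selected <- if (is.null(annotations)) character(0)
              else select_by_keywords(annotations, cfg$keywords)
  rows <- list()
  for (cid in selected) {
    cand <- .classify_contig(transcriptome[[cid]], tox_index, an_index, cfg,
                             provenance = "keyword")
    if (!is.null(cand)) rows[[length(rows) + 1L]] <- cand
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else NULL
  candidates <- .merge_pass(candidates, toxin_db, scheme, cfg)
  if (!is.null(candidates) && nrow(candidates))
    candidates <- reciprocal_expand(candidates, transcriptome, tox_index,
                                    an_index, cfg)
  if (is.null(candidates) || !nrow(candidates)) return(.empty_candidates())
  candidates <- candidates[order(candidates$toxin_class,
                                 candidates$display_name), , drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}

.empty_candidates <- function() {
  data.frame(unigene_id = character(), protein = character(),
             frame = integer(), toxin_class = character(),
             completeness = character(), joined = logical(),
             provenance = character(), display_name = character(),
             toxin_subject = character(), subject_len = integer(),
             toxin_raw = numeric(), toxin_bit = numeric(),
             toxin_evalue = numeric(), toxin_identity = numeric(),
             s_start = integer(), s_end = integer(),
             has_start_met = logical(), has_stop = logical(),
             animal_subject = character(), animal_bit = numeric(),
             animal_raw = numeric(), animal_is_venomous = logical(),
             stringsAsFactors = FALSE)
}

#' Read a protein database (FASTA + metadata sidecar TSV)
#'
#' The sidecar has header columns `id`, `taxon`, `is_venomous`,
#' `toxin_class` (empty toxin_class allowed for animal databases).
#'
#' @param fasta_path,meta_path Input paths.
#' @return A [protein_db()].
#' @export
read_protein_db <- function(fasta_path, meta_path) {
  recs <- read_fasta(fasta_path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE,
                     na.strings = c("NA", ""))
  stopifnot(setequal(names(recs), meta$id))
  meta <- meta[match(names(recs), meta$id), ]
  protein_db(id = meta$id,
             protein = vapply(recs, `[[`, "", "residues"),
             taxon = meta$taxon,
             is_venomous = as.logical(meta$is_venomous),
             toxin_class = meta$toxin_class)
}

#' Write a protein database (FASTA + metadata sidecar TSV)
#' @param db A [protein_db()].
#' @param fasta_path,meta_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_protein_db <- function(db, fasta_path, meta_path) {
  write_fasta(setNames(db$protein, db$id), fasta_path)
  write.table(db[, c("id", "taxon", "is_venomous", "toxin_class")],
              meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' Write the candidate table and candidate proteins
#' @param candidates Candidate data.frame.
#' @param tsv_path,fasta_path Output paths (FASTA skipped when `NULL`).
#' @return `tsv_path`, invisibly.
#' @export
write_candidates <- function(candidates, tsv_path, fasta_path = NULL) {
  write.table(candidates, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(fasta_path))
    write_fasta(setNames(candidates$protein, candidates$display_name),
                fasta_path)
  invisible(tsv_path)
}
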