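# End-to-end orchestration, reporting, scorecard, manifest, config files.

#' Read / write a simple INI-style key = value configuration file
#'
#' Lines of the form `key = value`; `#` comments and blank lines ignored.
#' Values are parsed as logical / numeric where possible, comma-separated
#' values become vectors.
#'
#' @param path File path.
#' @return `read_config`: named list; `write_config`: `path` invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!any(is.na(num))) num
              else if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts)
              else parts
    out[[key]] <- parsed
  }
  out
}

#' @rdname read_config
#' @param cfg Named list of scalar / vector settings.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Toxin-class to presentation-group mapping
#'
#' Loaded from an editable data file shipped with the package; groups the
#' toxin classes into the four conventional presentation groups (protease
#' inhibitors, proteolytic enzymes, other toxins, novel peptides).
#'
#' @return Data.frame with `toxin_class` and `group`.
#' @export
toxin_groups <- function() {
  read.delim(system.file("extdata", "toxin_groups.tsv",
                         package = "venomscreen", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

.stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Score pipeline output against planted truth
#'
#' @param candidates Candidate table from [classify_transcriptome()].
#' @param knottin_calls Call table from [screen_novel()].
#' @param truth Truth table from [simulate_bundle()].
#' @return One-row data.frame: `toxin_recall`, `housekeeping_fp_rate`,
#'   `completeness_accuracy`, `join_recovery`, `knottin_recall`,
#'   `noise_false_positives`, `n_candidates`, `n_knottin_calls`.
#' @export
score_pipeline <- function(candidates, knottin_calls, truth) {
  cand_ctg <- unlist(strsplit(candidates$unigene_id, "+", fixed = TRUE))
  tox <- truth[truth$class == "toxin", , drop = FALSE]
  hk <- truth[truth$class == "housekeeping", , drop = FALSE]
  noise <- truth[truth$class == "noise", , drop = FALSE]
  knot <- truth[truth$class == "knottin", , drop = FALSE]
  toxin_recall <- mean(tox$contig_id %in% cand_ctg)
  hk_fp <- mean(hk$contig_id %in% cand_ctg)
  # completeness over unjoined candidates with planted completeness truth
  un <- candidates[!candidates$joined, , drop = FALSE]
  m <- match(un$unigene_id, tox$contig_id)
  ok <- !is.na(m) & !is.na(tox$completeness[m])
  comp_acc <- if (any(ok)) mean(un$completeness[ok] ==
                                tox$completeness[m][ok]) else NA_real_
  # join recovery: each planted split pair present as one Full Join
  pairs <- tox[!is.na(tox$join_partner) & tox$completeness == "CTE", ,
               drop = FALSE]
  if (nrow(pairs)) {
    joined_ids <- candidates$unigene_id[candidates$joined &
                                        candidates$completeness == "Full"]
    got <- vapply(seq_len(nrow(pairs)), function(i) {
      any(vapply(strsplit(joined_ids, "+", fixed = TRUE), function(p)
        all(c(pairs$contig_id[i], pairs$join_partner[i]) %in% p), TRUE))
    }, TRUE)
    join_rec <- mean(got)
  } else join_rec <- NA_real_
  data.frame(
    toxin_recall = toxin_recall,
    housekeeping_fp_rate = hk_fp,
    completeness_accuracy = comp_acc,
    join_recovery = join_rec,
    knottin_recall = mean(knot$contig_id %in% knottin_calls$contig_id),
    noise_false_positives =
      sum(knottin_calls$contig_id %in% noise$contig_id) +
      sum(knottin_calls$contig_id %in% hk$contig_id),
    n_candidates = nrow(candidates),
    n_knottin_calls = nrow(knottin_calls))
}

#' Run the full analysis on an input bundle
#'
#' Executes classification, the novel-peptide screen, expression summaries,
#' family clustering with the expansion test, and per-family trees; writes
#' every stage output, a run manifest, and (when truth labels are present)
#' a scorecard. Fully deterministic for fixed inputs and seed.
#'
#' @param input A bundle directory (as written by [write_bundle()]) or an
#'   in-memory `sim_bundle` / list with the same components.
#' @param out_dir Output directory (created).
#' @param cfg A [classify_config()].
#' @param scheme A [scoring_scheme()].
#' @param seed Seed for the bootstrap stage.
#' @param top_fraction Expression gate for the novel screen.
#' @param boot_reps Bootstrap replicates for per-family trees.
#' @param tree_min_taxa,tree_max_taxa Family-size bounds for tree building.
#' @param quiet Suppress progress messages.
#' @return A list of stage outputs (invisibly also written under
#'   `out_dir`).
#' @export
run_all <- function(input, out_dir, cfg = classify_config(),
                    scheme = scoring_scheme(), seed = 1L,
                    top_fraction = 0.025, boot_reps = 100L,
                    tree_min_taxa = 4L, tree_max_taxa = 40L,
                    quiet = FALSE) {
  bundle <- if (is.character(input)) read_bundle(input) else input
  for (need in c("transcriptome", "toxin_db", "animal_db", "counts"))
    if (is.null(bundle[[need]])) stop("missing required input: ", need)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)

  .stage_log(quiet, "expression: %d contigs", nrow(bundle$counts))
  fpkm <- compute_fpkm(bundle$counts)
  write.table(fpkm, p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  .stage_log(quiet, "classify: E-max %.1g, margin %d, coverage %.2f",
             cfg$evalue_max, cfg$margin, cfg$min_subject_coverage)
  candidates <- classify_transcriptome(bundle$transcriptome, bundle$counts,
                                       bundle$annotations, bundle$toxin_db,
                                       bundle$animal_db, scheme, cfg)
  write_candidates(candidates, p("candidates.tsv"), p("candidates.fasta"))

  .stage_log(quiet, "no-hit scan + novel screen (top %.1f%%)",
             100 * top_fraction)
  tox_index <- db_search_index(bundle$toxin_db, scheme, cfg$prefilter_k)
  an_index <- db_search_index(bundle$animal_db, scheme, cfg$prefilter_k)
  all_hits <- lapply(bundle$transcriptome, function(ct)
    rbind(search_translated(ct, tox_index, evalue_max = cfg$evalue_max,
                            min_seg_aa = cfg$min_seg_aa),
          search_translated(ct, an_index, evalue_max = cfg$evalue_max,
                            min_seg_aa = cfg$min_seg_aa)))
  all_hits <- do.call(rbind, all_hits)
  calls <- screen_novel(bundle$transcriptome, all_hits, fpkm,
                        top_fraction = top_fraction,
                        evalue_max = cfg$evalue_max)
  # candidates are excluded from the novel screen by the no-hit gate, but
  # guard the invariant explicitly
  calls <- calls[!calls$contig_id %in%
                 unlist(strsplit(candidates$unigene_id, "+", fixed = TRUE)), ,
                 drop = FALSE]
  write.table(calls, p("knottins.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (nrow(calls))
    write_fasta(setNames(calls$mature, calls$contig_id),
                p("knottins.fasta"))

  # joined gene models are attributed to their N-terminal contig
  ctg1 <- vapply(strsplit(candidates$unigene_id, "+", fixed = TRUE), `[`,
                 "", 1L)
  fam_sum <- if (nrow(candidates))
    family_summaries(data.frame(unigene_id = ctg1,
                                toxin_class = candidates$toxin_class),
                     data.frame(contig_id = fpkm$contig_id,
                                fpkm = fpkm$fpkm)) else NULL
  if (!is.null(fam_sum))
    write.table(fam_sum, p("family_summaries.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  .stage_log(quiet, "family clustering + expansion test")
  focal_taxon <- "Plepida"
  prot <- rbind(
    data.frame(id = candidates$display_name, protein = candidates$protein,
               species = focal_taxon, toxin_class = candidates$toxin_class,
               stringsAsFactors = FALSE),
    data.frame(id = bundle$toxin_db$id, protein = bundle$toxin_db$protein,
               species = bundle$toxin_db$taxon,
               toxin_class = bundle$toxin_db$toxin_class,
               stringsAsFactors = FALSE))
  clust <- cluster_families(prot, scheme, evalue_max = cfg$evalue_max,
                            prefilter_k = cfg$prefilter_k)
  write_count_table(clust$counts, p("family_counts.tsv"))
  exp_rep <- expansion_report(clust$counts)
  write.table(exp_rep, p("expansion.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  .stage_log(quiet, "per-family trees (%d-%d taxa, %d bootstrap reps)",
             tree_min_taxa, tree_max_taxa, boot_reps)
  dir.create(p("trees"), showWarnings = FALSE)
  trees <- list()
  for (fm in sort(unique(candidates$toxin_class))) {
    sub <- candidates[candidates$toxin_class == fm, , drop = FALSE]
    if (nrow(sub) < tree_min_taxa || nrow(sub) > tree_max_taxa) next
    prots <- setNames(sub$protein, sub$display_name)
    msa <- drop_gappy_columns(center_star_align(prots, scheme))
    tr <- bootstrap_support(msa, n_reps = boot_reps, seed = seed)
    tr <- midpoint_root(tr)
    write_newick(tr, p(file.path("trees", paste0(fm, ".nwk"))))
    trees[[fm]] <- tr
  }

  scorecard <- NULL
  if (!is.null(bundle$truth)) {
    scorecard <- score_pipeline(candidates, calls, bundle$truth)
    write.table(scorecard, p("scorecard.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  manifest <- c(
    sprintf("tool_version = %s",
            as.character(utils::packageVersion("venomscreen"))),
    sprintf("seed = %d", seed),
    sprintf("evalue_max = %g", cfg$evalue_max),
    sprintf("margin = %d", cfg$margin),
    sprintf("min_overlap = %d", cfg$min_overlap),
    sprintf("min_overlap_identity = %g", cfg$min_overlap_identity),
    sprintf("min_subject_coverage = %g", cfg$min_subject_coverage),
    sprintf("prefilter_k = %d", cfg$prefilter_k),
    sprintf("score_type = %s", cfg$score_type),
    sprintf("top_fraction = %g", top_fraction),
    sprintf("boot_reps = %d", boot_reps),
    sprintf("n_contigs = %d", length(bundle$transcriptome)),
    sprintf("n_toxin_db = %d", nrow(bundle$toxin_db)),
    sprintf("n_animal_db = %d", nrow(bundle$animal_db)),
    sprintf("n_candidates = %d", nrow(candidates)),
    sprintf("n_knottin_calls = %d", nrow(calls)),
    if (is.character(input))
      paste0("input_md5_", basename(names(tools::md5sum(
        list.files(input, full.names = TRUE)))), " = ",
        unname(tools::md5sum(list.files(input, full.names = TRUE)))))
  writeLines(manifest, p("manifest.txt"))

  out <- list(fpkm = fpkm, candidates = candidates, knottin_calls = calls,
              family_summaries = fam_sum, family_counts = clust$counts,
              expansion = exp_rep, trees = trees, scorecard = scorecard,
              out_dir = out_dir)
  report_summary(out, p("report.txt"))
  invisible(out)
}

#' Write a human-readable run report
#'
#' Family count table grouped into the four presentation groups, the top-N
#' expressed candidates, the knottin calls with their cysteine frameworks,
#' and the expansion-test table.
#'
#' @param stages Output list from [run_all()].
#' @param path Report path.
#' @param top_n Rows of the expression top table (default 20).
#' @return `path`, invisibly.
#' @export
report_summary <- function(stages, path, top_n = 20L) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  cand <- stages$candidates
  w("== candidate toxin genes ==")
  w("total: %d", nrow(cand))
  if (nrow(cand)) {
    grp <- toxin_groups()
    g <- grp$group[match(cand$toxin_class, grp$toxin_class)]
    g[is.na(g)] <- "other_toxin"
    for (gr in unique(grp$group)) {
      n_gr <- sum(g == gr) + if (gr == "novel_peptide")
        nrow(stages$knottin_calls) else 0L
      w("  %-20s %d", gr, n_gr)
    }
    tab <- sort(table(cand$toxin_class), decreasing = TRUE)
    w("\n== genes per family ==")
    for (i in seq_along(tab)) w("  %-24s %d", names(tab)[i], tab[i])
    w("\n== top %d expressed candidates ==", top_n)
    f <- setNames(stages$fpkm$fpkm, stages$fpkm$contig_id)
    ctg1 <- vapply(strsplit(cand$unigene_id, "+", fixed = TRUE), `[`, "",
                   1L)
    ord <- order(-f[ctg1])
    for (i in head(ord, top_n))
      w("  %-40s %10.2f FPKM", cand$display_name[i], f[ctg1[i]])
  }
  w("\n== novel knottin-like peptides ==")
  calls <- stages$knottin_calls
  w("calls: %d", nrow(calls))
  if (nrow(calls))
    for (i in seq_len(nrow(calls)))
      w("  %-10s cleavage %2d  spacing %-14s  %8.1f FPKM (top %.2f%%)",
        calls$contig_id[i], calls$signal_cleavage[i], calls$spacing[i],
        calls$fpkm[i], calls$fpkm_rank_percentile[i])
  w("\n== family expansion test ==")
  ex <- stages$expansion
  if (!is.null(ex) && nrow(ex)) {
    for (i in seq_len(nrow(ex))) {
      if (ex$tested[i])
        w("  %-24s X2 = %8.3f  df = %d  p = %.4g%s", ex$family[i],
          ex$statistic[i], ex$df[i], ex$p_value[i],
          if (ex$significant[i]) "  *" else "")
      else
        w("  %-24s not tested (<= 5 genes in some species)", ex$family[i])
    }
  }
  invisible(path)
}
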