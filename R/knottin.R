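# Novel-peptide screen: expression-ranked no-hit contigs -> secreted-peptide
# heuristics -> inhibitor-cystine-knot (knottin) framework call.

.kd_env <- new.env(parent = emptyenv())

#' Kyte-Doolittle hydropathy table
#'
#' Loaded from the tab-separated data file shipped with the package.
#' Residues outside the 20 standard amino acids score 0.
#'
#' @return Named numeric vector of per-residue hydropathy values.
#' @export
kyte_doolittle <- function() {
  if (is.null(.kd_env$kd)) {
    path <- system.file("extdata", "kyte_doolittle.tsv",
                        package = "venomscreen", mustWork = TRUE)
    tab <- read.delim(path, stringsAsFactors = FALSE)
    .kd_env$kd <- setNames(tab$hydropathy, tab$residue)
  }
  .kd_env$kd
}

.kd_values <- function(peptide) {
  v <- kyte_doolittle()[strsplit(peptide, "")[[1]]]
  v[is.na(v)] <- 0
  unname(v)
}

.window_means <- function(v, w) {
  if (length(v) < w) return(numeric(0))
  cs <- cumsum(c(0, v))
  (cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]) / w
}

#' Detect a secretory signal peptide (hydropathy heuristic)
#'
#' A simplified von Heijne-style rule. The cleavage position `c` (1-based
#' index of the first mature residue) is the smallest value in
#' `[12, 35]` such that (i) an 8-residue window fully inside positions
#' `2..c-1` has mean Kyte-Doolittle hydropathy of at least `hydro_min`
#' (the hydrophobic h-region), (ii) the residues at `c-3` and `c-1` are
#' small (`A,G,S,C,T,V`), and (iii) the n-region preceding the earliest such
#' window (positions 2 up to the window start minus one) has non-negative
#' net charge (`K,R` = +1, `D,E` = -1).
#'
#' @param peptide Protein string starting with `M`.
#' @param hydro_min Minimum h-region mean hydropathy (default 2.0).
#' @return The cleavage index, or `NULL` when no position qualifies.
#' @export
detect_signal_peptide <- function(peptide, hydro_min = 2.0) {
  stopifnot(startsWith(peptide, "M"))
  len <- nchar(peptide)
  if (len < 12L) return(NULL)
  aa <- strsplit(peptide, "")[[1]]
  kd <- .kd_values(peptide)
  wm <- .window_means(kd, 8L)            # wm[w] = mean over positions w..w+7
  ok_w <- which(wm >= hydro_min)
  ok_w <- ok_w[ok_w >= 2L]
  if (!length(ok_w)) return(NULL)
  w1 <- ok_w[1L]
  small <- c("A", "G", "S", "C", "T", "V")
  charge <- if (w1 > 2L) {
    seg <- aa[2:(w1 - 1L)]
    sum(seg %in% c("K", "R")) - sum(seg %in% c("D", "E"))
  } else 0L
  if (charge < 0L) return(NULL)
  for (c_pos in 12:min(35L, len)) {
    if (w1 + 7L > c_pos - 1L) next      # window must fit inside 2..c-1
    if (aa[c_pos - 3L] %in% small && aa[c_pos - 1L] %in% small)
      return(c_pos)
  }
  NULL
}

#' Transmembrane-helix heuristic
#'
#' `TRUE` when some 19-residue window of the mature peptide has mean
#' Kyte-Doolittle hydropathy of at least `hydro_min` (default 1.8);
#' peptides shorter than 19 residues return `FALSE`.
#'
#' @param mature Protein string.
#' @param hydro_min Window-mean threshold.
#' @return Logical.
#' @export
has_tm_helix <- function(mature, hydro_min = 1.8) {
  stopifnot(nzchar(mature))
  wm <- .window_means(.kd_values(mature), 19L)
  length(wm) > 0 && any(wm >= hydro_min)
}

#' Match the six-cysteine inhibitor-cystine-knot framework
#'
#' A mature peptide matches when its length lies within `bounds`, it
#' contains exactly six cysteines, and the inter-cysteine gaps (residues
#' strictly between consecutive cysteines) fall within the canonical ICK
#' spacing ranges C1-C2 in [2,12], C2-C3 in [3,16], C3-C4 in [0,8]
#' (adjacent "CC" allowed), C4-C5 in [1,12], C5-C6 in [3,20]. The reported
#' connectivity is the knottin disulfide pattern C1-C4, C2-C5, C3-C6.
#'
#' @param mature Protein string.
#' @param bounds Length bounds for the mature peptide (default `c(30, 90)`).
#' @param gap_ranges 5x2 matrix of inclusive gap bounds (rows C1-C2 ..
#'   C5-C6); default the canonical ranges above.
#' @return List with `matched` (logical), `cys_positions` (six 1-based
#'   indices, or `integer(0)`), `connectivity`.
#' @export
match_knottin_framework <- function(mature, bounds = c(30L, 90L),
                                    gap_ranges = NULL) {
  if (is.null(gap_ranges))
    gap_ranges <- matrix(c(2L, 12L, 3L, 16L, 0L, 8L, 1L, 12L, 3L, 20L),
                         ncol = 2L, byrow = TRUE)
  len <- nchar(mature)
  fail <- list(matched = FALSE, cys_positions = integer(0),
               connectivity = "C1-C4,C2-C5,C3-C6")
  if (len < bounds[1] || len > bounds[2]) return(fail)
  cys <- which(strsplit(mature, "")[[1]] == "C")
  if (length(cys) != 6L) return(fail)
  gaps <- diff(cys) - 1L
  if (any(gaps < gap_ranges[, 1L] | gaps > gap_ranges[, 2L])) return(fail)
  list(matched = TRUE, cys_positions = cys,
       connectivity = "C1-C4,C2-C5,C3-C6")
}

#' High-expression contigs without database hits
#'
#' Contigs with no hit at `E <= evalue_max` against any searched database
#' and FPKM within the top `top_fraction` of contigs: the threshold is the
#' FPKM of the `ceiling(top_fraction * n)`-th highest contig and ties at the
#' threshold are included. By default the quantile pool is the contigs with
#' a positive count (`expressed_only = FALSE` uses all contigs).
#'
#' @param contig_ids Character vector of all contig ids.
#' @param hits Combined hit data.frame over all databases (needs `query_id`
#'   and `evalue`).
#' @param fpkm_table Data.frame with `contig_id`, `count`, `fpkm` covering
#'   all contigs.
#' @param top_fraction Fraction in (0, 1] (default 0.025).
#' @param evalue_max Hit-significance cutoff (default 1e-5).
#' @param expressed_only Restrict the quantile pool to count > 0 contigs.
#' @return Character vector of qualifying contig ids.
#' @export
no_hit_high_expression <- function(contig_ids, hits, fpkm_table,
                                   top_fraction = 0.025, evalue_max = 1e-5,
                                   expressed_only = TRUE) {
  stopifnot(all(contig_ids %in% fpkm_table$contig_id))
  with_hit <- unique(hits$query_id[hits$evalue <= evalue_max])
  pool <- fpkm_table
  if (expressed_only) pool <- pool[pool$count > 0, , drop = FALSE]
  thr <- top_fraction_threshold(pool$fpkm, top_fraction)
  f <- setNames(fpkm_table$fpkm, fpkm_table$contig_id)
  keep <- !(contig_ids %in% with_hit) & f[contig_ids] >= thr
  contig_ids[keep]
}

#' Screen for novel secreted knottin-like peptides
#'
#' The deterministic cascade replacing a manual inspection: high-expression
#' no-hit contigs, then Met-initiated ORFs of at least `min_orf_aa`
#' residues, then a signal peptide ([detect_signal_peptide()]), no
#' transmembrane helix in the mature region ([has_tm_helix()]), and the
#' six-cysteine ICK framework ([match_knottin_framework()]). At most one
#' call per contig (the longest qualifying ORF).
#'
#' @param contigs Named list of nucleotide [seq_record()]s.
#' @param hits Combined hit data.frame over all databases.
#' @param fpkm_table Data.frame with `contig_id`, `count`, `fpkm`.
#' @param top_fraction Expression gate fraction (default 0.025).
#' @param min_orf_aa Minimum ORF length (default 40).
#' @param evalue_max Hit-significance cutoff (default 1e-5).
#' @param expressed_only Quantile pool restriction (see
#'   [no_hit_high_expression()]).
#' @param mature_bounds Length bounds passed to
#'   [match_knottin_framework()].
#' @return Data.frame of knottin calls: `contig_id`, `peptide`,
#'   `signal_cleavage`, `mature`, `cys_positions` (comma-separated),
#'   `spacing` (inter-cysteine gaps, dash-separated), `connectivity`,
#'   `fpkm`, `fpkm_rank_percentile`.
#' @export
screen_novel <- function(contigs, hits, fpkm_table, top_fraction = 0.025,
                         min_orf_aa = 40L, evalue_max = 1e-5,
                         expressed_only = TRUE, mature_bounds = c(30L, 90L)) {
  ids <- vapply(contigs, `[[`, "", "id")
  cand <- no_hit_high_expression(ids, hits, fpkm_table, top_fraction,
                                 evalue_max, expressed_only)
  pct <- rank_percentile(fpkm_table)
  f <- setNames(fpkm_table$fpkm, fpkm_table$contig_id)
  rows <- list()
  for (cid in cand) {
    orfs <- find_orfs(contigs[[cid]], min_aa = min_orf_aa)
    orfs <- orfs[orfs$has_start_met, , drop = FALSE]
    if (!nrow(orfs)) next
    for (k in seq_len(nrow(orfs))) {       # longest first (find_orfs order)
      pep <- orfs$peptide[k]
      cl <- detect_signal_peptide(pep)
      if (is.null(cl)) next
      mature <- substring(pep, cl)
      if (has_tm_helix(mature)) next
      fw <- match_knottin_framework(mature, bounds = mature_bounds)
      if (!fw$matched) next
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = cid, peptide = pep, signal_cleavage = cl,
        mature = mature,
        cys_positions = paste(fw$cys_positions, collapse = ","),
        spacing = paste(diff(fw$cys_positions) - 1L, collapse = "-"),
        connectivity = fw$connectivity, fpkm = unname(f[cid]),
        fpkm_rank_percentile = unname(pct[cid]), stringsAsFactors = FALSE)
      break
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(), peptide = character(),
                      signal_cleavage = integer(), mature = character(),
                      cys_positions = character(), spacing = character(),
                      connectivity = character(), fpkm = numeric(),
                      fpkm_rank_percentile = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(-out$fpkm), , drop = FALSE]
}
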