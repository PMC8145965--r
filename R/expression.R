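# FPKM computation, expression ranking, per-family summaries.

#' Compute FPKM from a fragment-count table
#'
#' `fpkm = count * 1e9 / (length_bp * total)` where `total` is the sum of
#' counts over all contigs (Fragments Per Kilobase of transcript per Million
#' mapped fragments).
#'
#' @param counts Data.frame with columns `contig_id`, `length_bp`, `count`.
#' @return The input with an `fpkm` column appended.
#' @export
compute_fpkm <- function(counts) {
  stopifnot(all(c("contig_id", "length_bp", "count") %in% names(counts)))
  if (any(counts$length_bp <= 0)) stop("non-positive contig length")
  if (any(counts$count < 0)) stop("negative count")
  total <- sum(as.numeric(counts$count))
  if (total <= 0) stop("total mapped fragments must be positive")
  counts$fpkm <- counts$count * 1e9 / (counts$length_bp * total)
  counts
}

#' Rank-based expression percentiles
#'
#' Percentile from the top: `100 * rank / n` with 1-based ranks from the
#' highest FPKM down and average ranks for ties, so the most expressed of
#' `n` contigs sits at percentile `100/n` ("top `100/n` percent").
#'
#' @param records Data.frame with `contig_id` and `fpkm`.
#' @return Named numeric vector of percentiles in (0, 100].
#' @export
rank_percentile <- function(records) {
  stopifnot(nrow(records) >= 1L)
  r <- rank(-records$fpkm, ties.method = "average")
  setNames(100 * r / nrow(records), records$contig_id)
}

#' Rank threshold for a "top fraction" expression gate
#'
#' The FPKM of the `ceiling(top_fraction * n)`-th highest contig; values
#' greater than or equal to this threshold (ties included) are "within the
#' top fraction".
#'
#' @param fpkm Numeric vector of FPKM values.
#' @param top_fraction Fraction in (0, 1].
#' @return The threshold FPKM.
#' @export
top_fraction_threshold <- function(fpkm, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction <= 1, length(fpkm) >= 1L)
  k <- ceiling(top_fraction * length(fpkm))
  sort(fpkm, decreasing = TRUE)[k]
}

#' Per-family expression summaries (box-and-whisker statistics)
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7); outliers
#' are member FPKMs beyond 1.5 * IQR from the quartiles. Families with no
#' members are omitted.
#'
#' @param candidates Data.frame with `unigene_id` and `toxin_class`.
#' @param records Data.frame with `contig_id` and `fpkm` covering every
#'   candidate.
#' @return Data.frame, one row per family, sorted by descending median:
#'   `toxin_class`, `n_genes`, `min`, `q1`, `median`, `q3`, `max`,
#'   `outliers` (comma-separated ids, possibly empty).
#' @export
family_summaries <- function(candidates, records) {
  f <- setNames(records$fpkm, records$contig_id)
  if (!all(candidates$unigene_id %in% names(f)))
    stop("candidate without an expression record")
  sp <- split(candidates$unigene_id, candidates$toxin_class)
  rows <- lapply(names(sp), function(cl) {
    v <- f[sp[[cl]]]
    q <- unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
    iqr <- q[3] - q[1]
    out <- names(v)[v < q[1] - 1.5 * iqr | v > q[3] + 1.5 * iqr]
    data.frame(toxin_class = cl, n_genes = length(v), min = min(v),
               q1 = q[1], median = q[2], q3 = q[3], max = max(v),
               outliers = paste(out, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$median, out$toxin_class), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a fragment-count table
#'
#' TSV with header columns `contig_id`, `length_bp`, `count`.
#'
#' @param path Input path.
#' @return Data.frame.
#' @export
read_counts_tsv <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("contig_id", "length_bp", "count") %in% names(x)))
  x
}
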