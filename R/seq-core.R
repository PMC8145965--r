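# Sequence records, FASTA I/O, translation, ORF finding.

#' Create a sequence record
#'
#' A lightweight container for one FASTA entry: a nucleotide contig or a
#' protein. Residues are uppercased; the alphabet is validated.
#'
#' @param id Unique, non-empty identifier.
#' @param residues Sequence string: `ACGTN` for nucleotide, one-letter amino
#'   acids (plus `*` for stop) for protein.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description Free-text description (may be empty).
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `residues`, `alphabet`.
#' @export
seq_record <- function(id, residues, alphabet = c("nucleotide", "protein"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a non-empty string")
  residues <- toupper(gsub("\\s", "", residues))
  if (!nzchar(residues)) stop("empty sequence for record '", id, "'")
  ok <- if (alphabet == "nucleotide") grepl("^[ACGTN]+$", residues)
        else grepl("^[ARNDCQEGHILKMFPSTWYVBZXU*]+$", residues)
  if (!ok) stop("residues of '", id, "' inconsistent with ", alphabet,
                " alphabet")
  structure(list(id = id, description = description, residues = residues,
                 alphabet = alphabet), class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s [%s, %d residues]>\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Read a FASTA file
#'
#' Parses a (multi-line) FASTA file into a list of [seq_record()]s in file
#' order. The alphabet of each record is inferred: sequences composed of at
#' least 90 percent `ACGTN` characters are taken as nucleotide, anything else
#' as protein. Duplicate ids and empty sequences are hard errors.
#'
#' @param path Path to a FASTA file.
#' @return Named list of `seq_record` objects (names = ids).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- unname(toupper(gsub("\\s", "", as.character(set))))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- seqs[i]
    if (!nzchar(s)) stop("empty sequence for record '", ids[i], "'")
    n_nt <- nchar(gsub("[^ACGTN]", "", s))
    alpha <- if (n_nt / nchar(s) >= 0.9) "nucleotide" else "protein"
    out[[i]] <- seq_record(ids[i], s, alpha, desc[i])
  }
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences, or a list of [seq_record()]s.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.list(x) && length(x) && inherits(x[[1]], "seq_record"))
    x <- setNames(vapply(x, `[[`, "", "residues"),
                  vapply(x, `[[`, "", "id"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param nt Nucleotide string over `ACGTN`.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", nt), "")[[1]]), collapse = "")
}

.genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  # data-driven standard code; alternative tables could be swapped in here
  gc
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code. Frames `+1,+2,+3` read the forward strand starting
#' at offsets 0,1,2; negative frames read the reverse complement the same
#' way. A trailing partial codon is dropped; stop codons are rendered `*`;
#' any codon containing `N` translates to `X`.
#'
#' @param nt Nucleotide string.
#' @param frame Integer in `c(1, 2, 3, -1, -2, -3)`.
#' @return Protein string (possibly empty).
#' @export
translate_frame <- function(nt, frame = 1L) {
  stopifnot(frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
  s <- if (frame < 0) reverse_complement(nt) else nt
  off <- abs(frame) - 1L
  L <- nchar(s) - off
  n_codon <- L %/% 3L
  if (n_codon <= 0L) return("")
  starts <- off + 1L + 3L * (seq_len(n_codon) - 1L)
  codons <- substring(s, starts, starts + 2L)
  aa <- .genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Enumerate open reading frames in a contig
#'
#' Every maximal stop-to-stop segment in all six reading frames is reported,
#' trimmed to its first ATG when one exists (`has_start_met` records whether
#' it was). Segments whose peptide is shorter than `min_aa` are dropped.
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param contig A nucleotide [seq_record()].
#' @param min_aa Minimum peptide length in residues (>= 1).
#' @return A data.frame with columns `contig_id`, `frame`, `nt_start`,
#'   `nt_end`, `peptide`, `has_start_met`, `has_stop`, sorted by descending
#'   peptide length (ties: frame order +1,+2,+3,-1,-2,-3 then position).
#' @export
find_orfs <- function(contig, min_aa = 1L) {
  stopifnot(inherits(contig, "seq_record"), contig$alphabet == "nucleotide",
            min_aa >= 1L)
  L <- nchar(contig$residues)
  rows <- list()
  for (frame in c(1L, 2L, 3L, -1L, -2L, -3L)) {
    pep <- translate_frame(contig$residues, frame)
    if (!nzchar(pep)) next
    aa <- strsplit(pep, "")[[1]]
    stops <- which(aa == "*")
    seg_start <- c(1L, stops + 1L)            # aa index, 1-based
    seg_end <- c(stops - 1L, length(aa))      # inclusive
    has_stop <- c(rep(TRUE, length(stops)), FALSE)
    for (k in seq_along(seg_start)) {
      a <- seg_start[k]; b <- seg_end[k]
      if (a > b) next
      seg <- aa[a:b]
      met <- which(seg == "M")
      has_met <- length(met) > 0L
      if (has_met) { a <- a + met[1L] - 1L; seg <- aa[a:b] }
      if (length(seg) < min_aa) next
      # aa positions a..b (+ stop) -> nt coords in the read strand
      off <- abs(frame) - 1L
      nt_a <- off + 3L * (a - 1L)             # 0-based on read strand
      nt_b <- off + 3L * (b + if (has_stop[k]) 1L else 0L)
      if (frame > 0) { s0 <- nt_a; s1 <- nt_b }
      else { s0 <- L - nt_b; s1 <- L - nt_a }
      rows[[length(rows) + 1L]] <- data.frame(
        contig_id = contig$id, frame = frame, nt_start = s0, nt_end = s1,
        peptide = paste(seg, collapse = ""), has_start_met = has_met,
        has_stop = has_stop[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(contig_id = character(), frame = integer(),
                      nt_start = integer(), nt_end = integer(),
                      peptide = character(), has_start_met = logical(),
                      has_stop = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  frame_rank <- match(out$frame, c(1L, 2L, 3L, -1L, -2L, -3L))
  out <- out[order(-nchar(out$peptide), frame_rank, out$nt_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.codon_table_by_aa <- function() {
  gc <- .genetic_code()
  split(names(gc), unname(gc))
}

#' Reverse-translate a protein with random synonymous codons
#'
#' Each residue is replaced by a uniformly chosen synonymous codon, so that
#' `translate_frame(result, 1)` round-trips to the input. Used by the
#' synthetic-transcriptome generator.
#'
#' @param protein Protein string without `*`.
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein) {
  if (grepl("\\*", protein)) stop("protein contains a stop '*'")
  aa <- strsplit(protein, "")[[1]]
  tab <- .codon_table_by_aa()
  bad <- setdiff(aa, names(tab))
  if (length(bad)) stop("unknown residue(s): ", paste(unique(bad), collapse = ""))
  codons <- vapply(aa, function(a) {
    cs <- tab[[a]]
    if (length(cs) == 1L) cs else sample(cs, 1L)
  }, "")
  paste(codons, collapse = "")
}
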