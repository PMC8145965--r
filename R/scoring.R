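# Scoring schemes: substitution matrix, affine gap costs, Karlin-Altschul
# parameters.

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V","B","Z","X","*")

#' Construct an alignment scoring scheme
#'
#' Defaults follow the common protein-search setup: BLOSUM62 with gap open
#' 11 / gap extend 1 and the ungapped Karlin-Altschul constants
#' `lambda = 0.267`, `K = 0.041` applied to gapped scores, as BLAST does for
#' this parameter combination. Any residue outside the matrix alphabet (and
#' the ambiguity code `X`) is scored 0 against everything.
#'
#' @param matrix Integer substitution matrix with residue dimnames; default
#'   BLOSUM62 (from Biostrings) with the `X` row/column zeroed.
#' @param gap_open,gap_extend Affine gap costs: a gap of length g costs
#'   `gap_open + gap_extend * (g - 1)`.
#' @param lambda,K Karlin-Altschul parameters for bit scores and E-values.
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11L, gap_extend = 1L,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 1L, lambda > 0, K > 0)
  if (is.null(matrix)) matrix <- blosum62()
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  structure(list(matrix = matrix, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' BLOSUM62 substitution matrix
#'
#' The BLOSUM62 matrix restricted to the standard alignment alphabet, with
#' the ambiguity residue `X` scored 0 against everything (an `X` arises here
#' only from `N`-containing codons and should neither reward nor penalize).
#'
#' @return Integer matrix with dimnames over the 24-letter alphabet.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[.AA_ALPHABET, .AA_ALPHABET]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text matrix format used by NCBI tools: `#` comment
#' lines, a header row of residue letters, then one labeled row per residue.
#'
#' @param path Path to the matrix file.
#' @return Integer matrix with residue dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no matrix content in ", path)
  cols <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  rows <- vapply(body, `[`, "", 1L)
  vals <- t(vapply(body, function(x) as.integer(x[-1]),
                   integer(length(cols))))
  dimnames(vals) <- list(rows, cols)
  if (!identical(rownames(vals), colnames(vals)))
    stop("matrix rows and columns disagree in ", path)
  vals
}

# Encode a protein string as 0-based indices into the scheme alphabet.
# Residues absent from the alphabet map to X.
.encode_protein <- function(p, alphabet) {
  idx <- match(strsplit(p, "")[[1]], alphabet)
  idx[is.na(idx)] <- match("X", alphabet)
  as.integer(idx - 1L)
}
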