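# Distance phylogenetics: center-star MSA, gappy-column trimming,
# Poisson-corrected distances, neighbor joining, bootstrap, midpoint rooting.

#' Center-star multiple alignment
#'
#' The center sequence minimizes the sum of pairwise global-alignment
#' p-distances (ties broken by lexicographically smallest id); every other
#' sequence is aligned pairwise to the center and the pairwise alignments
#' are merged under the "once a gap, always a gap" rule. A deliberately
#' simple, deterministic stand-in for a progressive aligner, adequate for
#' closely related protein families.
#'
#' @param proteins Named character vector (>= 2 sequences).
#' @param scheme A [scoring_scheme()].
#' @return An `msa` object: named character vector of equal-length gapped
#'   rows, with attribute `center`.
#' @export
center_star_align <- function(proteins, scheme = scoring_scheme()) {
  stopifnot(length(proteins) >= 2L, !is.null(names(proteins)),
            !anyDuplicated(names(proteins)))
  ids <- names(proteins)
  n <- length(proteins)
  dsum <- setNames(numeric(n), ids)
  aln <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    g <- global_align(proteins[[i]], proteins[[j]], scheme)
    dsum[i] <- dsum[i] + g$p_distance
    dsum[j] <- dsum[j] + g$p_distance
  }
  center <- ids[order(dsum, ids)][1L]
  others <- setdiff(ids, center)

  # rows as character vectors; msa columns tagged by center residue index
  # (NA = column where the center is gapped)
  msa_rows <- list()
  msa_rows[[center]] <- strsplit(proteins[[center]], "")[[1]]
  col_idx <- seq_along(msa_rows[[center]])
  for (id in others) {
    g <- global_align(proteins[[center]], proteins[[id]], scheme)
    cg <- strsplit(g$q_gapped, "")[[1]]
    sg <- strsplit(g$s_gapped, "")[[1]]
    new_idx <- cumsum(cg != "-")
    new_idx[cg == "-"] <- NA
    merged_cols <- integer(0)
    take_old <- integer(0); take_new <- integer(0)  # 0 = gap column
    i <- 1L; j <- 1L
    while (i <= length(col_idx) || j <= length(new_idx)) {
      if (i <= length(col_idx) && is.na(col_idx[i])) {
        take_old <- c(take_old, i); take_new <- c(take_new, 0L)
        merged_cols <- c(merged_cols, NA); i <- i + 1L
      } else if (j <= length(new_idx) && is.na(new_idx[j])) {
        take_old <- c(take_old, 0L); take_new <- c(take_new, j)
        merged_cols <- c(merged_cols, NA); j <- j + 1L
      } else {
        take_old <- c(take_old, i); take_new <- c(take_new, j)
        merged_cols <- c(merged_cols, col_idx[i])
        i <- i + 1L; j <- j + 1L
      }
    }
    for (rid in names(msa_rows)) {
      row <- msa_rows[[rid]]
      msa_rows[[rid]] <- ifelse(take_old > 0L, row[pmax(take_old, 1L)], "-")
    }
    msa_rows[[id]] <- ifelse(take_new > 0L, sg[pmax(take_new, 1L)], "-")
    col_idx <- merged_cols
  }
  rows <- vapply(msa_rows[ids], paste, "", collapse = "")
  structure(rows, center = center, class = "msa")
}

#' Remove gap-rich alignment columns
#'
#' Columns whose gap fraction exceeds `max_gap_frac` are dropped; column
#' order is preserved. Removing every column is a hard error.
#'
#' @param msa An `msa` (named character vector of gapped rows).
#' @param max_gap_frac Maximum tolerated gap fraction per column.
#' @return The trimmed `msa`.
#' @export
drop_gappy_columns <- function(msa, max_gap_frac = 0.5) {
  m <- .msa_matrix(msa)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac <= max_gap_frac
  if (!any(keep)) stop("all alignment columns exceed the gap threshold")
  out <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
  structure(out, center = attr(msa, "center"), class = "msa")
}

.msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Pairwise distances from a multiple alignment
#'
#' p-distance with pairwise deletion (columns gapped in either row are
#' ignored for that pair), optionally Poisson-corrected
#' (`d = -log(1 - p)`). Distances where `p` reaches 1 (or pairs with no
#' comparable column) are reported as `dist_ceiling`.
#'
#' @param msa An `msa` or character matrix of rows.
#' @param correction `"poisson"` (default) or `"p"`.
#' @param dist_ceiling Finite ceiling for saturated distances.
#' @return Symmetric distance matrix with taxa dimnames.
#' @export
msa_distances <- function(msa, correction = c("poisson", "p"),
                          dist_ceiling = 10) {
  correction <- match.arg(correction)
  m <- if (is.matrix(msa)) msa else .msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok)) { p <- 1 } else p <- mean(m[i, ok] != m[j, ok])
    v <- if (correction == "p") p
         else if (p >= 1) dist_ceiling else min(-log(1 - p), dist_ceiling)
    d[i, j] <- d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with deterministic tie-breaking (smallest Q,
#' then the lexicographically smallest pair of node labels, an internal
#' node being labeled by its smallest leaf). Negative branch lengths are
#' clamped to zero with the deficit moved to the sister branch. The result
#' is unrooted (trifurcation at the last join).
#'
#' @param d Symmetric distance matrix (zero diagonal, >= 3 taxa) with
#'   dimnames.
#' @return An [ape::read.tree()] "phylo" object.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3L, isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0), !is.null(rownames(d)))
  labs <- rownames(d)
  nwk <- labs                      # growing newick fragment per active node
  key <- labs                      # deterministic tie-break label
  D <- d
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pk <- paste(pmin(key[cand[, 1]], key[cand[, 2]]),
                pmax(key[cand[, 1]], key[cand[, 2]]), sep = "\r")
    pick <- cand[order(pk)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    new_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], li, nwk[j], lj)
    new_key <- min(key[i], key[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nwk <- c(nwk[keep], new_nwk)
    key <- c(key[keep], new_key)
    D <- D2
  }
  # final three nodes: star with three-point branch lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1], la, nwk[2], lb,
                 nwk[3], lc)
  ape::read.tree(text = txt)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; each
#' replicate yields Poisson-corrected distances and an NJ tree. The support
#' of each internal edge of the tree built from the full alignment is the
#' percentage of replicates containing the same leaf bipartition
#' (computed with [ape::prop.clades()] on unrooted topologies). Fully
#' reproducible for a given `seed`.
#'
#' @param msa An `msa` with >= 4 taxa and >= 1 column.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return The original NJ "phylo" with `node.label` set to support
#'   percentages.
#' @export
bootstrap_support <- function(msa, n_reps = 1000L, seed = 1L) {
  m <- .msa_matrix(msa)
  stopifnot(nrow(m) >= 4L, ncol(m) >= 1L)
  main <- nj_tree(msa_distances(m))
  reps <- vector("list", n_reps)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    reps[[b]] <- nj_tree(msa_distances(m[, cols, drop = FALSE]))
  }
  cnt <- ape::prop.clades(main, reps, rooted = FALSE)
  cnt[is.na(cnt)] <- 0L
  main$node.label <- as.character(round(100 * cnt / n_reps, 1))
  main
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. When
#' several paths tie for the maximum, the lexicographically smallest leaf
#' pair is used. If the midpoint falls exactly on an existing node the tree
#' is rooted at that node; otherwise the spanning edge is split by a new
#' degree-two root node. Total tree length is preserved.
#'
#' @param tree An unrooted "phylo" with branch lengths.
#' @return A rooted "phylo".
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  dm <- ape::cophenetic.phylo(tree)
  labs <- rownames(dm)
  mx <- max(dm)
  cand <- which(dm >= mx - 1e-12 * max(1, mx), arr.ind = TRUE)
  cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  pk <- paste(pmin(labs[cand[, 1]], labs[cand[, 2]]),
              pmax(labs[cand[, 1]], labs[cand[, 2]]), sep = "\r")
  pick <- cand[order(pk)[1L], ]
  a <- labs[pick[1L]]; b <- labs[pick[2L]]
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  ta <- match(a, tree$tip.label); tb <- match(b, tree$tip.label)
  path <- ape::nodepath(tree, from = ta, to = tb)
  elen <- numeric(length(path) - 1L)
  eidx <- integer(length(path) - 1L)
  for (k in seq_along(elen)) {
    hit <- which((tree$edge[, 1] == path[k] & tree$edge[, 2] == path[k + 1]) |
                 (tree$edge[, 2] == path[k] & tree$edge[, 1] == path[k + 1]))
    eidx[k] <- hit
    elen[k] <- tree$edge.length[hit]
  }
  half <- sum(elen) / 2
  cum <- cumsum(elen)
  t_edge <- which(cum >= half - 1e-12)[1L]
  x <- half - if (t_edge > 1L) cum[t_edge - 1L] else 0  # from path[t_edge]
  u <- path[t_edge]; v <- path[t_edge + 1L]
  tol <- 1e-12 * max(1, half)
  if (x <= tol && u > ape::Ntip(tree)) {
    rooted <- ape::root(tree, node = u, resolve.root = FALSE)
  } else if (abs(x - elen[t_edge]) <= tol && v > ape::Ntip(tree)) {
    rooted <- ape::root(tree, node = v, resolve.root = FALSE)
  } else {
    e <- eidx[t_edge]
    par <- tree$edge[e, 1]; chi <- tree$edge[e, 2]
    d_par <- if (par == u) x else elen[t_edge] - x
    phy <- tree
    newnode <- ape::Ntip(phy) + phy$Nnode + 1L
    phy$edge[e, ] <- c(par, newnode)
    phy$edge.length[e] <- d_par
    phy$edge <- rbind(phy$edge, c(newnode, chi))
    phy$edge.length <- c(phy$edge.length, elen[t_edge] - d_par)
    phy$Nnode <- phy$Nnode + 1L
    if (!is.null(phy$node.label)) phy$node.label <- c(phy$node.label, "")
    rooted <- ape::root(phy, node = newnode, resolve.root = FALSE)
  }
  rooted$rooted <- TRUE
  rooted
}

#' Write / read Newick
#'
#' Thin wrappers over [ape::write.tree()] / [ape::read.tree()]; bootstrap
#' supports travel as internal node labels.
#'
#' @param tree A "phylo".
#' @param path File path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a "phylo".
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write / read a labeled square distance matrix TSV
#' @param d Symmetric matrix with dimnames.
#' @param path File path.
#' @return `write_distance_tsv`: `path` invisibly; `read_distance_tsv`:
#'   matrix.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write an alignment as gapped FASTA
#' @param msa An `msa`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) write_fasta(unclass(msa), path)
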