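# Distance matrices: the average gene-tree internode distance (AGID), the
# log-det (paralinear) distance from a concatenated alignment, additive
# matrices from edge-weighted trees, and PHYLIP square-matrix I/O.
#
# Matrices are plain labeled base matrices: symmetric, zero diagonal,
# nonnegative. The triangle inequality is NOT assumed anywhere -- estimated
# dissimilarities routinely violate it.

#' Average gene-tree internode distance matrix
#'
#' Entry (i, j) is the mean, over the gene trees containing both taxa, of
#' the number of internal nodes on the i-j path in the (unrooted) gene
#' tree topology. Branch lengths are ignored. Taxa may be missing from
#' individual gene trees; every pair must co-occur in at least one.
#'
#' The internode count is one less than the number of edges on the path,
#' so a uniform +1 convention shift would move all off-diagonal entries by
#' a constant -- which leaves neighbor-joining topologies unchanged.
#'
#' @param gene_trees List or `multiPhylo` of gene trees.
#' @return Labeled symmetric matrix over the sorted taxon union.
#' @export
agid_matrix <- function(gene_trees) {
  trees <- as_tree_list(gene_trees)
  if (!length(trees)) stop("need at least one gene tree")
  labs <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  n <- length(labs)
  acc <- matrix(0, n, n, dimnames = list(labs, labs))
  cnt <- matrix(0L, n, n, dimnames = list(labs, labs))
  for (t in trees) {
    check_phylo(t)
    if (ape::Ntip(t) < 2L) next
    idx <- match(t$tip.label, labs)
    if (ape::Ntip(t) == 2L) {
      d <- matrix(0, 2, 2)  # a single edge: no internal node between them
    } else {
      tu <- as_unrooted(t)
      tu$edge.length <- rep(1, nrow(tu$edge))
      d <- stats::cophenetic(tu)[t$tip.label, t$tip.label] - 1
      diag(d) <- 0
    }
    acc[idx, idx] <- acc[idx, idx] + d
    cnt[idx, idx] <- cnt[idx, idx] + 1L
  }
  miss <- which(cnt == 0L & upper.tri(cnt), arr.ind = TRUE)
  if (nrow(miss))
    stop("taxon pair never co-occurs in any gene tree: ",
         labs[miss[1L, 1L]], ", ", labs[miss[1L, 2L]])
  D <- acc / cnt
  diag(D) <- 0
  check_dist_matrix(D)
}

#' Log-det (paralinear) distance matrix from an alignment
#'
#' For each pair the 4x4 relative divergence matrix F is tallied over the
#' sites where both sequences carry a plain `A`/`C`/`G`/`T`; the distance is
#' \deqn{d = -\frac{1}{4}\left[\ln\det F - \frac{1}{2}\ln\Big(\prod_a f_a \prod_a g_a\Big)\right]}
#' with f and g the row and column marginals of F. Under stationary
#' Jukes-Cantor evolution this recovers the expected number of
#' substitutions per site. Saturated pairs (non-positive determinant or a
#' zero marginal) raise an error naming the pair; nothing is silently
#' capped.
#'
#' @param alignment Named character vector of equal-length sequences.
#' @return Labeled symmetric matrix of pairwise distances.
#' @export
logdet_matrix <- function(alignment) {
  seqs <- as_alignment(alignment)
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences")
  labs <- names(seqs)
  base <- c("A", "C", "G", "T")
  M <- vapply(seqs, function(s) match(strsplit(s, "", fixed = TRUE)[[1L]], base),
              integer(nchar(seqs[[1L]])))
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(M[, i]) & !is.na(M[, j])
      nok <- sum(ok)
      if (nok == 0L)
        stop("no pairwise-complete sites for pair: ", labs[i], ", ", labs[j])
      counts <- tabulate((M[ok, i] - 1L) * 4L + M[ok, j], nbins = 16L)
      F <- matrix(counts / nok, 4, 4, byrow = TRUE)
      f <- rowSums(F); g <- colSums(F)
      if (any(f == 0) || any(g == 0))
        stop("saturated pair (zero base-frequency marginal): ",
             labs[i], ", ", labs[j])
      dt <- det(F)
      if (dt <= 0)
        stop("saturated pair (non-positive divergence determinant): ",
             labs[i], ", ", labs[j])
      d <- -(log(dt) - 0.5 * (sum(log(f)) + sum(log(g)))) / 4
      D[i, j] <- D[j, i] <- max(d, 0)
    }
  }
  check_dist_matrix(D)
}

#' Additive (path-length) matrix of an edge-weighted tree
#'
#' @param tree A binary `phylo` with strictly positive branch lengths.
#' @return Labeled symmetric matrix of pairwise path lengths, rows and
#'   columns in sorted label order.
#' @export
additive_matrix <- function(tree) {
  check_phylo(tree)
  if (!is_binary_tree(tree)) stop("tree must be binary")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length <= 0))
    stop("all branch lengths must be strictly positive")
  labs <- sort(tree$tip.label)
  D <- stats::cophenetic(tree)[labs, labs]
  diag(D) <- 0
  check_dist_matrix(D)
}

#' Read a PHYLIP square distance matrix
#'
#' First line: the number of taxa; then one row per taxon: the label
#' followed by n whitespace-separated values. Asymmetry beyond `1e-6`
#' is an error; the stored matrix is exactly symmetrized.
#'
#' @param path Path to the matrix file.
#' @return Labeled symmetric matrix.
#' @export
read_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("bad taxon count on line 1 of ", path)
  if (length(lines) != n + 1L)
    stop("expected ", n, " matrix rows, found ", length(lines) - 1L)
  labs <- character(n)
  D <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1L]]
    if (length(tok) != n + 1L)
      stop("row ", i, ": expected label plus ", n, " values")
    labs[i] <- tok[1L]
    v <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(v)) stop("row ", i, ": non-numeric entry")
    D[i, ] <- v
  }
  if (anyDuplicated(labs)) stop("duplicate taxon labels in matrix")
  dimnames(D) <- list(labs, labs)
  if (max(abs(D - t(D))) > 1e-6)
    stop("matrix is asymmetric beyond tolerance 1e-6")
  D <- (D + t(D)) / 2
  diag(D) <- 0
  check_dist_matrix(D)
}

#' Write a PHYLIP square distance matrix
#'
#' @param D Labeled symmetric matrix.
#' @param path Output path.
#' @param digits Significant digits.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(D, path, digits = 12) {
  D <- check_dist_matrix(D)
  labs <- rownames(D)
  con <- file(path, "w")
  on.exit(close(con))
  cat(nrow(D), "\n", sep = "", file = con)
  for (i in seq_len(nrow(D)))
    cat(labs[i], formatC(D[i, ], digits = digits, format = "g"), "\n",
        file = con)
  invisible(path)
}

# ---- internal ---------------------------------------------------------

check_dist_matrix <- function(D) {
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D))
    stop("expected a square numeric matrix")
  labs <- rownames(D)
  if (is.null(labs) || is.null(colnames(D)) || !identical(labs, colnames(D)))
    stop("matrix must carry identical row and column labels")
  if (anyDuplicated(labs)) stop("duplicate matrix labels")
  if (any(!is.finite(D))) stop("non-finite matrix entries")
  if (max(abs(D - t(D))) > 1e-8) stop("matrix is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("matrix diagonal must be zero")
  if (any(D < 0)) stop("negative dissimilarities are not allowed")
  D
}
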