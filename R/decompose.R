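# Centroid-edge decomposition of a starting tree into pairwise disjoint
# taxon subsets under a maximum-size bound (the recursive scheme used by
# large-alignment divide-and-conquer methods).

#' Centroid-edge decomposition
#'
#' Recursively splits the tree at the centroid edge -- the edge whose
#' removal minimizes the larger side of the induced leaf bipartition --
#' until every part has at most `max_size` leaves. Each recursion operates
#' on the restricted subtrees (degree-2 nodes suppressed) so centroid
#' choices stay well defined. Ties between edges are broken by the
#' lexicographically smallest leaf on the smaller side, then by the side's
#' full label string, making the decomposition deterministic.
#'
#' @param tree A binary `phylo`.
#' @param max_size Maximum subset size, at least 3 (smaller subsets could
#'   not carry an informative subset tree).
#' @return An object of class `taxon_decomposition`: a list of disjoint
#'   character vectors covering the leaf set, each of length
#'   `<= max_size`.
#' @export
centroid_decompose <- function(tree, max_size) {
  check_phylo(tree)
  if (!is_binary_tree(tree)) stop("tree must be binary")
  max_size <- as.integer(max_size)
  if (is.na(max_size) || max_size < 3L)
    stop("max_size must be at least 3")
  parts <- decompose_rec(tree, max_size)
  structure(parts, class = "taxon_decomposition", max_size = max_size)
}

#' @export
print.taxon_decomposition <- function(x, ...) {
  sizes <- lengths(x)
  cat("Taxon decomposition:", length(x), "subsets over", sum(sizes),
      "taxa (max allowed", attr(x, "max_size"), ")\n")
  cat("  sizes:", paste(sizes, collapse = ", "), "\n")
  invisible(x)
}

# ---- internal ---------------------------------------------------------

decompose_rec <- function(tree, max_size) {
  n <- ape::Ntip(tree)
  if (n <= max_size) return(list(sort(tree$tip.label)))
  sides <- edge_leaf_sides(tree)
  labs <- tree$tip.label
  best <- NULL
  for (side in sides) {
    other <- setdiff(labs, side)
    larger <- max(length(side), length(other))
    smaller <- if (length(side) < length(other)) side
               else if (length(other) < length(side)) other
               else if (min(side) < min(other)) side else other
    key <- list(larger = larger, minleaf = min(smaller),
                id = paste(sort(smaller), collapse = SPLIT_SEP),
                side = side, other = other)
    if (is.null(best) ||
        key$larger < best$larger ||
        (key$larger == best$larger && key$minleaf < best$minleaf) ||
        (key$larger == best$larger && key$minleaf == best$minleaf &&
         key$id < best$id)) {
      best <- key
    }
  }
  c(decompose_rec(restrict_tree(tree, best$side), max_size),
    decompose_rec(restrict_tree(tree, best$other), max_size))
}

# leaf set on the child side of every edge of the unrooted topology
edge_leaf_sides <- function(tree) {
  tr <- as_unrooted(tree)
  n <- ape::Ntip(tr)
  labs <- tr$tip.label
  clade <- vector("list", n + tr$Nnode)
  for (i in seq_len(n)) clade[[i]] <- labs[i]
  post <- ape::reorder.phylo(tr, "postorder")
  for (k in seq_len(nrow(post$edge))) {
    p <- post$edge[k, 1L]; ch <- post$edge[k, 2L]
    clade[[p]] <- c(clade[[p]], clade[[ch]])
  }
  lapply(seq_len(nrow(tr$edge)), function(k) clade[[tr$edge[k, 2L]]])
}
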