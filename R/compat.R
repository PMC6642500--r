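# Agreement testing, compatibility supertrees, rooted compatibility via the
# Aho BUILD algorithm, and the normalized Robinson-Foulds error.

#' Does a small tree agree with a larger one?
#'
#' `small` agrees with `big` when restricting `big` to the leaves of
#' `small` (and suppressing degree-2 nodes) yields a tree with the same
#' unrooted topology as `small`. Trees on at most 3 leaves agree with any
#' tree containing their leaves.
#'
#' @param small A binary `phylo` on a subset of `big`'s leaves.
#' @param big A `phylo` object.
#' @return Logical scalar.
#' @export
agrees_with <- function(small, big) {
  check_phylo(small); check_phylo(big)
  extra <- setdiff(small$tip.label, big$tip.label)
  if (length(extra))
    stop("leaves of the small tree missing from the big tree: ",
         paste(extra, collapse = ", "))
  if (!is_binary_tree(small))
    stop("the small tree must be binary")
  if (ape::Ntip(small) <= 3L) return(TRUE)
  same_topology(small, restrict_tree(big, small$tip.label))
}

#' Is a tree a compatibility supertree of a forest?
#'
#' True when every tree of the forest agrees with the candidate. The
#' constituent trees need not form clades in the candidate.
#'
#' @param candidate A `phylo` whose leaves cover the forest's.
#' @param forest A list (or `multiPhylo`) of binary `phylo` trees.
#' @return Logical scalar.
#' @export
is_compatibility_supertree <- function(candidate, forest) {
  forest <- as_tree_list(forest)
  all(vapply(forest, agrees_with, logical(1), big = candidate))
}

#' Rooted-tree compatibility (BUILD)
#'
#' Decides whether a common rooted supertree displays every input tree,
#' using the cluster-graph formulation of the BUILD algorithm: at each
#' recursion level the leaves are partitioned by the connectivity graph
#' whose edges are cliques over each tree's proper clusters; a level with
#' at least 3 leaves that cannot be split is a witness of incompatibility.
#' Trees with fewer than 3 leaves impose no constraints.
#'
#' @param trees List of rooted `phylo` trees; leaf sets may overlap.
#' @return Logical scalar (`TRUE` for the empty list).
#' @export
rooted_compatible <- function(trees) {
  trees <- as_tree_list(trees)
  systems <- list()
  for (t in trees) {
    check_phylo(t)
    if (ape::Ntip(t) < 3L) next
    systems[[length(systems) + 1L]] <-
      list(tips = t$tip.label, clusters = tree_clusters(t))
  }
  if (!length(systems)) return(TRUE)
  L <- sort(unique(unlist(lapply(systems, `[[`, "tips"))))
  build_rec(L, systems)
}

#' Resolved rooted triplets of a rooted tree
#'
#' @param tree A rooted `phylo`.
#' @return Character vector of codes `"a,b|c"` (pair sorted), one per
#'   resolved triplet the tree displays.
#' @export
rooted_triplets <- function(tree) {
  check_phylo(tree)
  if (ape::Ntip(tree) < 3L) return(character(0))
  labs <- tree$tip.label
  cl <- tree_clusters(tree)
  out <- character(0)
  for (C in cl) {
    rest <- setdiff(labs, C)
    if (!length(rest)) next
    pairs <- utils::combn(sort(C), 2L)
    for (j in seq_len(ncol(pairs)))
      out <- c(out, paste0(pairs[1L, j], ",", pairs[2L, j], "|", rest))
  }
  unique(out)
}

#' Normalized Robinson-Foulds error
#'
#' The proportion of internal edges of the reference tree whose
#' bipartitions are missing from the estimated tree; for two binary trees
#' on the same n leaves this equals the RF symmetric difference divided by
#' 2(n-3).
#'
#' @param true_tree,est_tree Binary `phylo` trees on the same leaf set,
#'   n >= 4.
#' @return A number in `[0, 1]`.
#' @export
rf_error <- function(true_tree, est_tree) {
  check_phylo(true_tree); check_phylo(est_tree)
  if (!setequal(true_tree$tip.label, est_tree$tip.label))
    stop("trees must share an identical leaf set")
  n <- ape::Ntip(true_tree)
  if (n < 4L) stop("RF error undefined for fewer than 4 leaves")
  st <- tree_bipartitions(true_tree)
  se <- tree_bipartitions(est_tree)
  length(setdiff(st, se)) / (n - 3)
}

# ---- internal ---------------------------------------------------------

as_tree_list <- function(forest) {
  if (inherits(forest, "phylo")) return(list(forest))
  if (inherits(forest, "multiPhylo")) return(unclass(forest))
  if (is.list(forest)) return(forest)
  stop("expected a list of 'phylo' trees")
}

# proper clusters (clades of size >= 2, excluding the full leaf set) of a
# rooted tree, as a list of character vectors
tree_clusters <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 3L) return(list())
  pp <- ape::prop.part(tree)
  out <- list()
  if (length(pp) > 1L) {
    for (k in 2:length(pp)) {
      side <- tree$tip.label[pp[[k]]]
      if (length(side) >= 2L && length(side) < n)
        out[[length(out) + 1L]] <- side
    }
  }
  out
}

# BUILD recursion over cluster systems; each system is list(tips, clusters)
build_rec <- function(L, systems) {
  m <- length(L)
  if (m <= 2L) return(TRUE)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (sys in systems) {
    tl <- intersect(sys$tips, L)
    if (length(tl) < 3L) next
    for (C in sys$clusters) {
      Y <- intersect(C, L)
      if (length(Y) < 2L || length(Y) >= length(tl)) next
      idx <- match(Y, L)
      r0 <- find(idx[1L])
      for (i in idx[-1L]) {
        r <- find(i)
        if (r != r0) parent[r] <- r0
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comps <- split(L, roots)
  if (length(comps) == 1L) return(FALSE)
  for (comp in comps) {
    if (length(comp) >= 3L && !build_rec(comp, systems)) return(FALSE)
  }
  TRUE
}
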