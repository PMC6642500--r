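# Hermetic simulators: random topologies, multispecies-coalescent gene
# trees, Jukes-Cantor sequences, nearly additive matrix perturbations, and
# a randomized search for instances that defeat the pairwise screening
# heuristic. All generators are deterministic given a seed.

#' Random unrooted binary tree
#'
#' Topology drawn uniformly over unrooted labeled binary topologies;
#' branch lengths log-uniform on `[min_bl, max_bl]`.
#'
#' @param n Number of leaves, at least 3.
#' @param seed Optional integer seed.
#' @param labels Leaf labels (default `t1 ... tn`).
#' @param min_bl,max_bl Branch-length range (substitutions/site scale).
#' @return An unrooted binary `phylo`.
#' @export
random_binary_tree <- function(n, seed = NULL, labels = paste0("t", seq_len(n)),
                               min_bl = 0.05, max_bl = 1.0) {
  if (n < 3L) stop("need at least 3 leaves")
  if (length(labels) != n || anyDuplicated(labels))
    stop("labels must be ", n, " unique strings")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtopology(n, rooted = FALSE, tip.label = labels)
  tr$edge.length <- exp(stats::runif(nrow(tr$edge), log(min_bl), log(max_bl)))
  tr
}

#' Simulate gene trees under the multispecies coalescent
#'
#' One lineage per species enters at each tip; within every species-tree
#' branch, lineage pairs coalesce at exponential rate k(k-1)/2 per
#' coalescent unit, where a coalescent unit is `branch length in
#' generations / pop_size` (haploid-equivalent population size, constant
#' across the tree); unresolved lineages coalesce freely above the root.
#' Returned gene trees are rooted and binary with branch lengths in
#' coalescent units.
#'
#' @param species_tree Rooted binary `phylo` with branch lengths in
#'   generations.
#' @param count Number of gene trees, at least 1.
#' @param pop_size Effective (haploid-equivalent) population size;
#'   defaults to 200000.
#' @param seed Optional integer seed.
#' @return A `multiPhylo` of `count` rooted gene trees on the species
#'   labels.
#' @export
msc_gene_trees <- function(species_tree, count, pop_size = 2e5, seed = NULL) {
  check_phylo(species_tree)
  if (!ape::is.rooted(species_tree))
    stop("species tree must be rooted")
  if (is.null(species_tree$edge.length) || any(species_tree$edge.length <= 0))
    stop("species tree needs strictly positive branch lengths")
  if (pop_size <= 0) stop("population size must be positive")
  count <- as.integer(count)
  if (count < 1L) stop("count must be at least 1")
  if (!is.null(seed)) set.seed(seed)

  st <- species_tree
  st$edge.length <- st$edge.length / pop_size   # coalescent units
  n <- ape::Ntip(st)
  nn <- n + st$Nnode
  depth <- ape::node.depth.edgelength(st)
  age <- max(depth) - depth                      # time before the youngest tip
  kids <- vector("list", nn)
  for (k in seq_len(nrow(st$edge)))
    kids[[st$edge[k, 1L]]] <- c(kids[[st$edge[k, 1L]]], st$edge[k, 2L])
  root <- n + 1L
  # postorder edge list guarantees every child precedes its parent
  post <- c(ape::reorder.phylo(st, "postorder")$edge[, 2L], root)

  coalesce_interval <- function(lin, t0, t1) {
    tau <- t0
    while (length(lin) >= 2L) {
      k <- length(lin)
      tau <- tau + stats::rexp(1L, k * (k - 1) / 2)
      if (tau >= t1) break
      ij <- sample.int(k, 2L)
      a <- lin[[ij[1L]]]; b <- lin[[ij[2L]]]
      merged <- list(
        s = sprintf("(%s:%.8g,%s:%.8g)", a$s, tau - a$a, b$s, tau - b$a),
        a = tau)
      lin <- c(lin[-ij], list(merged))
    }
    lin
  }

  parent_of <- integer(nn)
  parent_of[st$edge[, 2L]] <- st$edge[, 1L]

  sim_one <- function() {
    pool <- vector("list", nn)
    for (v in post) {
      lin <- if (v <= n) {
        list(list(s = st$tip.label[v], a = age[v]))
      } else {
        do.call(c, pool[kids[[v]]])
      }
      if (v == root) {
        lin <- coalesce_interval(lin, age[v], Inf)
      } else {
        lin <- coalesce_interval(lin, age[v], age[parent_of[v]])
      }
      pool[[v]] <- lin
    }
    paste0(pool[[root]][[1L]]$s, ";")
  }

  nwk <- vapply(seq_len(count), function(i) sim_one(), character(1))
  trees <- ape::read.tree(text = paste(nwk, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  trees
}

#' Simulate Jukes-Cantor sequences along a tree
#'
#' I.i.d. sites evolve under the Jukes-Cantor model down the tree (branch
#' lengths in expected substitutions per site); no insertions or
#' deletions, so the output is an alignment by construction.
#'
#' @param tree A `phylo` with branch lengths.
#' @param length Number of sites, at least 1.
#' @param seed Optional integer seed.
#' @return Named character vector of aligned sequences (A/C/G/T).
#' @export
jc_sequences <- function(tree, length, seed = NULL) {
  check_phylo(tree)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (length < 1L) stop("length must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  sim <- phangorn::simSeq(tree, l = length, type = "DNA")
  m <- toupper(as.character(sim))
  seqs <- apply(m, 1L, paste0, collapse = "")
  as_alignment(stats::setNames(seqs, rownames(m)))
}

#' Nearly additive perturbation of an additive matrix
#'
#' Adds to every off-diagonal entry an independent uniform draw from
#' `(-eps, eps)` with `eps = 0.49 *` (shortest branch length of `tree`),
#' preserving symmetry. Every entry of the result differs from the tree
#' path length by less than half the shortest branch, the margin under
#' which neighbor joining provably recovers the generating topology.
#'
#' @param tree Binary `phylo` with strictly positive branch lengths.
#' @param D Additive matrix of `tree` (computed if omitted).
#' @param seed Optional integer seed.
#' @return Labeled symmetric matrix, certified nearly additive for `tree`.
#' @export
nearly_additive_perturb <- function(tree, D = NULL, seed = NULL) {
  check_phylo(tree)
  A <- additive_matrix(tree)
  if (is.null(D)) D <- A
  D <- check_dist_matrix(D)[rownames(A), rownames(A)]
  if (!is.null(seed)) set.seed(seed)
  eps <- 0.49 * min(tree$edge.length)
  n <- nrow(D)
  P <- matrix(0, n, n)
  P[upper.tri(P)] <- stats::runif(n * (n - 1) / 2, -eps, eps)
  out <- D + P + t(P)
  dimnames(out) <- dimnames(A)
  half <- 0.5 * min(tree$edge.length)
  if (max(abs(out - A)) >= half)
    stop("internal error: perturbation exceeds the nearly-additive bound")
  check_dist_matrix(pmax(out, 0) * (1 - diag(n)))
}

#' Search for an instance on which the pairwise heuristic fails
#'
#' Pairwise screening of siblinghood proposals does not guarantee joint
#' compatibility of the constraint forest, so a greedy run can reach a
#' state where no remaining pair is joinable. This generator hunts for
#' such instances by drawing small disjoint forests whose trees conflict
#' with a random dissimilarity matrix, running the merger, and returning
#' the first instance certified (by that run) to fail.
#'
#' @param seed Optional integer seed.
#' @param n_taxa Total taxon count per attempt (default 12, split into 3
#'   subsets of 4).
#' @param tries Search budget; exhausting it is an error (retry with
#'   another seed).
#' @return List with `forest` (disjoint constraint trees), `D` (the
#'   dissimilarity matrix), and `attempts`.
#' @export
adversarial_forest <- function(seed = NULL, n_taxa = 12L, tries = 500L) {
  if (!is.null(seed)) set.seed(seed)
  if (n_taxa < 12L) stop("need at least 12 taxa (three informative subsets)")
  labels <- paste0("t", seq_len(n_taxa))
  for (att in seq_len(tries)) {
    perm <- sample(labels)
    cuts <- parts_of_three(n_taxa)
    forest <- list()
    start <- 1L
    for (sz in cuts) {
      forest[[length(forest) + 1L]] <-
        random_binary_tree(sz, labels = perm[start:(start + sz - 1L)])
      start <- start + sz
    }
    D <- random_dissimilarity(labels)
    failed <- tryCatch({
      njmerge(forest, D, mode = "pairwise", check_output = FALSE)
      FALSE
    }, njmerge_failure = function(e) TRUE)
    if (failed)
      return(list(forest = forest, D = D, attempts = att))
  }
  stop("no failing instance found within ", tries,
       " attempts; rerun with a different seed")
}

# ---- internal ---------------------------------------------------------

parts_of_three <- function(n) {
  base <- n %/% 3L
  sizes <- rep(base, 3L)
  extra <- n - 3L * base
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

random_dissimilarity <- function(labels) {
  n <- length(labels)
  D <- matrix(0, n, n, dimnames = list(labels, labels))
  v <- stats::runif(n * (n - 1) / 2, 0.1, 1)
  D[upper.tri(D)] <- v
  D + t(D)
}
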