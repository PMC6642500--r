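# The constrained merger. Siblinghood proposals are drawn in ascending-Q
# order and screened against the constraint forest:
#   Property 1 -- if x and y co-occur in a constraint tree they must be a
#                 cherry there;
#   Property 2 -- relabeling x and y as the merged leaf z must not make any
#                 pair of constraint trees incompatible (tested by rooting
#                 the updated trees at z and running BUILD).
# If a full scan finds no acceptable pair the run terminates with the
# documented failure condition; any tree that IS returned is a
# compatibility supertree of the original forest (asserted by default).

#' Merge disjoint constraint trees guided by a distance matrix
#'
#' Runs neighbor joining on `D` but accepts, at each iteration, the first
#' pair in ascending-Q order that passes the cherry screen (Property 1)
#' and the compatibility screen (Property 2). In `pairwise` mode (the
#' default heuristic) Property 2 checks every pair of updated constraint
#' trees containing the merged leaf; `groupwise` mode runs one BUILD test
#' over the whole group, which is strictly more conservative. Pairwise
#' screening does not guarantee joint compatibility, so the run can fail;
#' failure raises a condition of class `njmerge_failure` carrying the join
#' log -- never a malformed tree.
#'
#' @param forest List (or `multiPhylo`) of unrooted binary constraint
#'   trees on pairwise disjoint leaf subsets; trees with at most 2 leaves
#'   are constraint-free and ignored. May be empty, in which case the
#'   result is plain neighbor joining.
#' @param D Labeled symmetric dissimilarity matrix covering every
#'   constraint leaf, n >= 3.
#' @param mode `"pairwise"` (default) or `"groupwise"`.
#' @param check_output Assert the compatibility-supertree guarantee on the
#'   returned tree (default `TRUE`; disable for speed).
#' @return An object of class `njmerge_result`: a list with `tree` (the
#'   unrooted binary `phylo` on the labels of `D`), `join_log` (a data
#'   frame with columns iter, x, y, z, rank -- rank being how far down the
#'   sorted Q list the accepted pair sat), and `mode`.
#' @seealso [nj_tree()], [check_property1()], [check_property2()]
#' @export
njmerge <- function(forest, D, mode = c("pairwise", "groupwise"),
                    check_output = TRUE) {
  mode <- match.arg(mode)
  D <- check_dist_matrix(D)
  labs <- rownames(D)
  if (length(labs) < 3L) stop("need at least 3 taxa")
  original <- as_tree_list(forest)
  work <- list()
  seen <- character(0)
  for (t in original) {
    check_phylo(t)
    if (!is_binary_tree(t)) stop("constraint trees must be binary")
    ov <- intersect(t$tip.label, seen)
    if (length(ov))
      stop("constraint trees must have pairwise disjoint leaf sets; shared: ",
           paste(ov, collapse = ", "))
    seen <- c(seen, t$tip.label)
    missing <- setdiff(t$tip.label, labs)
    if (length(missing))
      stop("constraint leaf absent from the distance matrix: ",
           paste(missing, collapse = ", "))
    if (ape::Ntip(t) >= 3L) work[[length(work) + 1L]] <- as_unrooted(t)
  }

  state <- nj_state(D)
  log_rows <- list()
  used <- labs
  iter <- 0L
  while (length(state$active) > 3L) {
    iter <- iter + 1L
    Q <- q_matrix(state$D)
    ord <- order_proposals(Q)
    accepted <- FALSE
    for (k in seq_len(nrow(ord))) {
      x <- ord$x[k]; y <- ord$y[k]
      if (!length(work)) {
        accepted <- TRUE
      } else {
        if (!check_property1(work, x, y)) next
        if (!check_property2(work, x, y, mode = mode)) next
        accepted <- TRUE
      }
      if (accepted) {
        z <- fresh_label(c(used, names(state$sub)), iter)
        used <- c(used, z)
        work <- relabel_forest(work, x, y, z)
        state <- join_update(state, x, y, z)
        log_rows[[iter]] <- data.frame(iter = iter, x = x, y = y, z = z,
                                       rank = k, stringsAsFactors = FALSE)
        break
      }
    }
    if (!accepted)
      stop_njmerge_failure(iter, do.call(rbind, log_rows))
  }
  tree <- close_three(state)
  join_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(iter = integer(0), x = character(0), y = character(0),
               z = character(0), rank = integer(0))
  if (check_output && length(original) &&
      !is_compatibility_supertree(tree, original))
    stop("internal error: returned tree is not a compatibility supertree")
  structure(list(tree = tree, join_log = join_log, mode = mode),
            class = "njmerge_result")
}

#' @export
print.njmerge_result <- function(x, ...) {
  cat("Constrained NJ merge (", x$mode, " mode)\n", sep = "")
  cat("  taxa:", ape::Ntip(x$tree), "  joins:", nrow(x$join_log), "\n")
  if (nrow(x$join_log)) {
    r <- x$join_log$rank
    cat("  proposal ranks: median", stats::median(r), " max", max(r), "\n")
  }
  invisible(x)
}

#' Cherry screen for a siblinghood proposal
#'
#' True iff in every constraint tree containing both `x` and `y` the two
#' leaves are attached to a common node (vacuously true when no tree
#' contains both). Trees on 3 leaves impose nothing: every leaf pair of an
#' unrooted 3-leaf tree shares its single internal node.
#'
#' @param forest List of unrooted `phylo` constraint trees.
#' @param x,y Active node labels.
#' @return Logical scalar.
#' @export
check_property1 <- function(forest, x, y) {
  for (t in as_tree_list(forest)) {
    tl <- t$tip.label
    if (x %in% tl && y %in% tl && !is_cherry(t, x, y)) return(FALSE)
  }
  TRUE
}

#' Compatibility screen for a siblinghood proposal
#'
#' Simulates the relabeling of `x` and `y` as the merged leaf `z` on the
#' constraint trees containing either, roots each updated tree at `z`, and
#' tests rooted compatibility with BUILD -- every pair of updated trees in
#' `pairwise` mode, the whole group at once in `groupwise` mode. Only
#' trees containing `x` or `y` need examining; all other pairs are
#' untouched by the proposal. The forest itself is not modified.
#'
#' @inheritParams check_property1
#' @param mode `"pairwise"` or `"groupwise"`.
#' @return Logical scalar.
#' @export
check_property2 <- function(forest, x, y, mode = c("pairwise", "groupwise")) {
  mode <- match.arg(mode)
  forest <- as_tree_list(forest)
  touched <- Filter(function(t) x %in% t$tip.label || y %in% t$tip.label,
                    forest)
  if (length(touched) <= 1L) return(TRUE)
  z <- fresh_label(unique(unlist(lapply(forest, `[[`, "tip.label"))))
  G <- relabel_forest(touched, x, y, z)
  G <- Filter(function(t) z %in% t$tip.label && ape::Ntip(t) >= 4L, G)
  if (length(G) <= 1L) return(TRUE)
  systems <- lapply(G, function(t) clusters_from_leaf(t, z))
  if (mode == "groupwise") {
    L <- sort(unique(unlist(lapply(systems, `[[`, "tips"))))
    return(build_rec(L, systems))
  }
  for (i in seq_len(length(systems) - 1L)) {
    for (j in (i + 1L):length(systems)) {
      pairsys <- systems[c(i, j)]
      L <- sort(unique(c(pairsys[[1L]]$tips, pairsys[[2L]]$tips)))
      if (!build_rec(L, pairsys)) return(FALSE)
    }
  }
  TRUE
}

#' Apply a siblinghood relabeling to a constraint forest
#'
#' In every tree containing exactly one of `x`, `y` that leaf is renamed
#' `z`; in every tree containing both (necessarily as a cherry) the cherry
#' is contracted to the single leaf `z` with degree-2 nodes suppressed.
#' Trees falling to 2 or fewer leaves are dropped -- they constrain
#' nothing. After relabeling, constraint trees may share leaves.
#'
#' @inheritParams check_property1
#' @param z The merged leaf label.
#' @return The updated list of trees.
#' @export
relabel_forest <- function(forest, x, y, z) {
  out <- list()
  for (t in as_tree_list(forest)) {
    tl <- t$tip.label
    hx <- x %in% tl; hy <- y %in% tl
    if (hx && hy) {
      if (!is_cherry(t, x, y))
        stop("internal contract error: relabeling a non-cherry pair")
      t <- ape::drop.tip(t, y, collapse.singles = TRUE)
      t$tip.label[t$tip.label == x] <- z
    } else if (hx) {
      t$tip.label[t$tip.label == x] <- z
    } else if (hy) {
      t$tip.label[t$tip.label == y] <- z
    }
    # cherry contraction can leave a degree-2 anchor; restore the basal
    # trifurcation so adjacency tests see the unrooted topology
    if (ape::Ntip(t) >= 3L) out[[length(out) + 1L]] <- as_unrooted(t)
  }
  out
}

#' Condition raised when no acceptable siblinghood proposal remains
#'
#' @param cond A condition object.
#' @return `is_njmerge_failure` returns a logical scalar.
#' @export
is_njmerge_failure <- function(cond) inherits(cond, "njmerge_failure")

# ---- internal ---------------------------------------------------------

stop_njmerge_failure <- function(iter, join_log) {
  cond <- structure(
    class = c("njmerge_failure", "error", "condition"),
    list(message = paste0(
           "merge failed at iteration ", iter,
           ": none of the remaining pairs can be joined without violating ",
           "the pairwise compatibility of the constraint trees"),
         call = sys.call(-1), iter = iter,
         join_log = join_log %||% data.frame())
  )
  stop(cond)
}

is_cherry <- function(tree, x, y) {
  ix <- match(x, tree$tip.label)
  iy <- match(y, tree$tip.label)
  e2 <- tree$edge[, 2L]
  px <- tree$edge[match(ix, e2), 1L]
  py <- tree$edge[match(iy, e2), 1L]
  px == py
}

# ascending Q with lexicographic tie-break on the sorted label pair
order_proposals <- function(Q) {
  labs <- rownames(Q)
  ut <- which(upper.tri(Q), arr.ind = TRUE)
  a <- labs[ut[, 1L]]
  b <- labs[ut[, 2L]]
  lo <- pmin(a, b); hi <- pmax(a, b)
  o <- order(Q[ut], lo, hi, method = "radix")
  data.frame(x = a[o], y = b[o], q = Q[ut][o], stringsAsFactors = FALSE)
}

# the cluster system of the tree rooted at leaf z (z removed): for each
# nontrivial split, the side away from z is one proper cluster of the
# rooted tree -- equivalent to root_at_leaf() + tree_clusters(), without
# the surgery
clusters_from_leaf <- function(tree, z) {
  labs <- tree$tip.label
  residual <- setdiff(labs, z)
  clusters <- list()
  if (ape::Ntip(tree) >= 4L) {
    tr <- as_unrooted(tree)
    pp <- ape::prop.part(tr)
    n <- length(labs)
    if (length(pp) > 1L) {
      for (k in 2:length(pp)) {
        side <- tr$tip.label[pp[[k]]]
        if (length(side) < 2L || length(side) > n - 2L) next
        if (z %in% side) side <- setdiff(labs, side)
        if (length(side) >= 2L)
          clusters[[length(clusters) + 1L]] <- side
      }
    }
  }
  list(tips = residual, clusters = clusters)
}

close_three <- function(state) {
  act <- state$active
  if (length(act) != 3L)
    stop("internal error: expected exactly 3 active nodes")
  D <- state$D
  a <- act[1L]; b <- act[2L]; c_ <- act[3L]
  la <- max((D[a, b] + D[a, c_] - D[b, c_]) / 2, 0)
  lb <- max(D[a, b] - la, 0)
  lc <- max(D[a, c_] - la, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 state$sub[[a]], la, state$sub[[b]], lb, state$sub[[c_]], lc)
  ape::read.tree(text = txt)
}
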