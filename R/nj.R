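# Classic Neighbor Joining: the Q criterion, the sibling-join matrix
# update, and the full agglomeration. The same Q and update formulas drive
# the constrained merger in njmerge(); only the acceptance rule differs.

#' Neighbor-joining Q matrix
#'
#' Studier-Keppler form: `Q[i,j] = (r-2) D[i,j] - R_i - R_j` with `R_i` the
#' row sum of D over the r active nodes. Adding a constant c to every
#' off-diagonal entry of D shifts Q uniformly by -c r, so the argmin set is
#' unchanged.
#'
#' @param D Labeled symmetric dissimilarity matrix, r >= 3.
#' @return Matrix of the same shape with `NA` on the diagonal.
#' @export
q_matrix <- function(D) {
  D <- check_dist_matrix(D)
  r <- nrow(D)
  if (r < 3L) stop("Q matrix undefined for fewer than 3 active nodes")
  rs <- rowSums(D)
  Q <- (r - 2) * D - outer(rs, rs, `+`)
  diag(Q) <- NA_real_
  Q
}

#' Initialize a neighbor-joining state
#'
#' The state carries the active node labels, the current dissimilarity
#' matrix over them, the partial subtree (Newick fragment) owned by each
#' active node, and the ordered join log.
#'
#' @param D Labeled symmetric dissimilarity matrix.
#' @return An object of class `nj_state`.
#' @export
nj_state <- function(D) {
  D <- check_dist_matrix(D)
  labs <- rownames(D)
  structure(list(
    active = labs,
    D = D,
    sub = stats::setNames(as.list(labs), labs),
    heights = stats::setNames(numeric(length(labs)), labs),
    joins = list()
  ), class = "nj_state")
}

#' Accept a siblinghood join and update the state
#'
#' Replaces active nodes x and y by a fresh node z with
#' `D[z,k] = (D[x,k] + D[y,k] - D[x,y]) / 2`; z's subtree is the cherry of
#' x's and y's subtrees (pendant lengths by the standard NJ formulas,
#' advisory only -- every contract in this package is topological).
#'
#' @param state An `nj_state`.
#' @param x,y Distinct active node labels.
#' @param z Label for the merged node (default: a fresh internal id).
#' @return The updated `nj_state`.
#' @export
join_update <- function(state, x, y, z = NULL) {
  stopifnot(inherits(state, "nj_state"))
  act <- state$active
  if (!x %in% act) stop("inactive node: ", x)
  if (!y %in% act) stop("inactive node: ", y)
  if (x == y) stop("cannot join a node with itself")
  D <- state$D
  r <- length(act)
  z <- z %||% fresh_label(act)
  dxy <- D[x, y]
  others <- setdiff(act, c(x, y))
  if (r > 2L) {
    rsx <- sum(D[x, ]); rsy <- sum(D[y, ])
    lx <- if (r > 2L) dxy / 2 + (rsx - rsy) / (2 * max(r - 2L, 1L)) else dxy / 2
    ly <- dxy - lx
  } else {
    lx <- ly <- dxy / 2
  }
  frag <- sprintf("(%s:%.10g,%s:%.10g)", state$sub[[x]], lx, state$sub[[y]], ly)
  newlabs <- c(others, z)
  D2 <- matrix(0, length(newlabs), length(newlabs),
               dimnames = list(newlabs, newlabs))
  if (length(others)) {
    D2[others, others] <- D[others, others]
    dz <- (D[x, others] + D[y, others] - dxy) / 2
    dz <- pmax(dz, 0)
    D2[z, others] <- dz
    D2[others, z] <- dz
  }
  state$active <- newlabs
  state$D <- D2
  state$sub[[x]] <- NULL
  state$sub[[y]] <- NULL
  state$sub[[z]] <- frag
  state$joins[[length(state$joins) + 1L]] <- c(x = x, y = y, z = z)
  state
}

#' Neighbor joining
#'
#' Iterates argmin-Q sibling joins (ties broken lexicographically on the
#' sorted label pair, for determinism and label-permutation equivariance)
#' until 3 active nodes remain, then closes them through one internal
#' node. On an additive -- or nearly additive -- matrix for a tree T this
#' recovers T's topology.
#'
#' @param D Labeled symmetric dissimilarity matrix, n >= 3.
#' @return An unrooted binary `phylo` on the labels of `D`.
#' @export
nj_tree <- function(D) {
  res <- njmerge(list(), D, check_output = FALSE)
  res$tree
}

# ---- internal ---------------------------------------------------------

fresh_label <- function(taken, i = length(taken)) {
  repeat {
    z <- paste0(".z", i)
    if (!z %in% taken) return(z)
    i <- i + 1L
  }
}
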