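# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: quartets are read off unit-length path
# distances, triplets off MRCA depths, rooted compatibility off exhaustive
# enumeration of rooted supertrees, and the paralinear distance off a
# hand-expanded 4x4 determinant.

# which quartet topology a tree displays for 4 leaves: "ab|cd" with the
# canonical partner of the alphabetically first leaf
oracle_quartet <- function(tree, q) {
  q <- sort(q)
  tu <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  tu$edge.length <- rep(1, nrow(tu$edge))
  d <- stats::cophenetic(tu)
  s1 <- d[q[1], q[2]] + d[q[3], q[4]]
  s2 <- d[q[1], q[3]] + d[q[2], q[4]]
  s3 <- d[q[1], q[4]] + d[q[2], q[3]]
  best <- which.min(c(s1, s2, s3))
  partner <- q[c(2, 3, 4)][best]
  rest <- setdiff(q, c(q[1], partner))
  paste0(q[1], partner, "|", rest[1], rest[2])
}

# resolved rooted triplets via MRCA node depths
oracle_triplets <- function(tree) {
  labs <- sort(tree$tip.label)
  if (length(labs) < 3) return(character(0))
  mr <- ape::mrca(tree)
  depth <- ape::node.depth.edgelength(
    { t2 <- tree; t2$edge.length <- rep(1, nrow(t2$edge)); t2 })
  out <- character(0)
  combs <- utils::combn(labs, 3)
  for (k in seq_len(ncol(combs))) {
    a <- combs[1, k]; b <- combs[2, k]; c_ <- combs[3, k]
    dab <- depth[mr[a, b]]; dac <- depth[mr[a, c_]]; dbc <- depth[mr[b, c_]]
    if (dab > dac && dab > dbc) out <- c(out, paste0(a, ",", b, "|", c_))
    else if (dac > dab && dac > dbc) out <- c(out, paste0(a, ",", c_, "|", b))
    else if (dbc > dab && dbc > dac) out <- c(out, paste0(b, ",", c_, "|", a))
  }
  out
}

# all rooted binary topologies on a label set, as nested lists
enum_rooted_shapes <- function(labs) {
  if (length(labs) == 1L) return(list(labs[[1L]]))
  smaller <- enum_rooted_shapes(labs[-length(labs)])
  x <- labs[[length(labs)]]
  out <- list()
  graft_all <- function(node) {
    # returns all trees obtained by attaching x inside `node`
    res <- list(list(node, x))
    if (is.list(node)) {
      for (i in 1:2) {
        for (sub in graft_all(node[[i]])) {
          nd <- node; nd[[i]] <- sub
          res <- c(res, list(nd))
        }
      }
    }
    res
  }
  for (tr in smaller) out <- c(out, graft_all(tr))
  out
}

shape_leaves <- function(node) {
  if (!is.list(node)) return(node)
  c(shape_leaves(node[[1L]]), shape_leaves(node[[2L]]))
}

shape_triplets <- function(node) {
  # triplets of a nested-list rooted tree, via its cluster list
  clusters <- list()
  walk <- function(nd) {
    if (!is.list(nd)) return(nd)
    lv <- c(walk(nd[[1L]]), walk(nd[[2L]]))
    clusters[[length(clusters) + 1L]] <<- lv
    lv
  }
  all_lv <- walk(node)
  out <- character(0)
  for (C in clusters) {
    if (length(C) >= length(all_lv)) next
    rest <- setdiff(all_lv, C)
    if (length(C) < 2L || !length(rest)) next
    pr <- utils::combn(sort(C), 2L)
    for (j in seq_len(ncol(pr)))
      for (r in rest) out <- c(out, paste0(pr[1L, j], ",", pr[2L, j], "|", r))
  }
  unique(out)
}

# cached triplet sets of every rooted binary supertree on n canonical labels
.supertree_cache <- new.env(parent = emptyenv())
canonical_supertree_triplets <- function(n) {
  key <- as.character(n)
  if (!is.null(.supertree_cache[[key]])) return(.supertree_cache[[key]])
  shapes <- enum_rooted_shapes(as.list(paste0("L", seq_len(n))))
  val <- lapply(shapes, shape_triplets)
  .supertree_cache[[key]] <- val
  val
}

# exhaustive-enumeration oracle for rooted compatibility of binary trees
oracle_rooted_compatible <- function(trees) {
  trees <- Filter(function(t) ape::Ntip(t) >= 3L, trees)
  if (!length(trees)) return(TRUE)
  L <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  map <- stats::setNames(paste0("L", seq_along(L)), L)
  want <- unlist(lapply(trees, function(t) {
    tt <- oracle_triplets(t)
    vapply(tt, function(s) {
      m <- regmatches(s, regexec("^(.*),(.*)\\|(.*)$", s))[[1L]]
      pr <- sort(c(map[[m[2L]]], map[[m[3L]]]))
      paste0(pr[1L], ",", pr[2L], "|", map[[m[4L]]])
    }, character(1), USE.NAMES = FALSE)
  }))
  want <- unique(want)
  for (cand in canonical_supertree_triplets(length(L)))
    if (all(want %in% cand)) return(TRUE)
  FALSE
}

# internal nodes on the leaf-to-leaf path, by explicit adjacency walk
oracle_internodes <- function(tree, a, b) {
  n <- ape::Ntip(tree)
  adj <- vector("list", n + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]; ch <- tree$edge[k, 2L]
    adj[[p]] <- c(adj[[p]], ch)
    adj[[ch]] <- c(adj[[ch]], p)
  }
  from <- match(a, tree$tip.label)
  to <- match(b, tree$tip.label)
  prev <- rep(NA_integer_, length(adj))
  queue <- from
  prev[from] <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    if (v == to) break
    for (w in adj[[v]]) if (is.na(prev[w])) { prev[w] <- v; queue <- c(queue, w) }
  }
  path <- to
  while (path[1L] != from) path <- c(prev[path[1L]], path)
  sum(path > n)
}

# paralinear distance by hand: explicit cofactor expansion of det(F)
oracle_logdet_pair <- function(s1, s2) {
  b <- c("A", "C", "G", "T")
  x <- match(strsplit(s1, "")[[1L]], b)
  y <- match(strsplit(s2, "")[[1L]], b)
  ok <- !is.na(x) & !is.na(y)
  F <- matrix(0, 4, 4)
  for (k in which(ok)) F[x[k], y[k]] <- F[x[k], y[k]] + 1
  F <- F / sum(ok)
  det3 <- function(m)
    m[1,1]*(m[2,2]*m[3,3]-m[2,3]*m[3,2]) -
    m[1,2]*(m[2,1]*m[3,3]-m[2,3]*m[3,1]) +
    m[1,3]*(m[2,1]*m[3,2]-m[2,2]*m[3,1])
  d4 <- F[1,1]*det3(F[2:4, 2:4]) - F[1,2]*det3(F[2:4, c(1,3,4)]) +
        F[1,3]*det3(F[2:4, c(1,2,4)]) - F[1,4]*det3(F[2:4, 1:3])
  f <- rowSums(F); g <- colSums(F)
  -(log(d4) - 0.5 * log(prod(f) * prod(g))) / 4
}

# four-point condition check for one quartet of an additive matrix
four_point_ok <- function(D, q, tol = 1e-9) {
  s <- sort(c(D[q[1], q[2]] + D[q[3], q[4]],
              D[q[1], q[3]] + D[q[2], q[4]],
              D[q[1], q[4]] + D[q[2], q[3]]))
  abs(s[2] - s[3]) < tol
}

# a random rooted binary tree on a subset of labels (for BUILD fuzzing)
random_rooted_subtree <- function(labels, k) {
  tips <- sample(labels, k)
  tr <- ape::rtopology(k, rooted = TRUE, tip.label = tips)
  tr$edge.length <- NULL
  tr
}
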