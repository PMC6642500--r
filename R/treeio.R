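# Tree and alignment I/O plus the surgery primitives every other module
# relies on. Trees are plain ape "phylo" objects throughout; unrooted
# topology is always compared through bipartition sets so the arbitrary
# basal anchoring of the stored object never leaks into results.

SPLIT_SEP <- "\x1f"

#' Parse a Newick string into a phylo tree
#'
#' A deliberately small Newick dialect: branch lengths are optional,
#' internal node labels are discarded on read, quoted labels are rejected,
#' and surrounding whitespace is tolerated. Leaf labels must be unique.
#'
#' @param text A Newick string terminated by `";"`.
#' @return An object of class `phylo` (from \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || substr(text, nchar(text), nchar(text)) != ";")
    stop("Newick parse error: string does not end in ';'")
  if (grepl("'", text, fixed = TRUE) || grepl('"', text, fixed = TRUE))
    stop("Newick parse error: quoted labels are not supported")
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop(sprintf("Newick parse error: unbalanced ')' at position %d", i))
    }
  }
  if (depth != 0L)
    stop(sprintf("Newick parse error: %d unclosed '(' at end of string", depth))
  # single leaf, e.g. "A;" -- ape cannot represent this via read.tree
  if (!grepl("[(),]", text)) {
    lab <- sub(";$", "", text)
    lab <- sub(":[^:]*$", "", lab)
    return(single_tip_tree(lab))
  }
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e)),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w))
  )
  if (is.null(tr)) stop("Newick parse error: unreadable string")
  tr$node.label <- NULL
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (any(!nzchar(tr$tip.label)))
    stop("empty leaf label")
  tr
}

#' Read one or more trees from a Newick file
#'
#' @param path Path to a file of `;`-terminated Newick strings.
#' @return A `phylo` object if the file holds one tree, otherwise a
#'   `multiPhylo` list.
#' @export
read_newick <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(trimws(lines), collapse = "")
  if (!nzchar(txt)) stop("empty Newick file: ", path)
  parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
  parts <- parts[nzchar(trimws(parts))]
  trees <- lapply(paste0(parts, ";"), parse_newick)
  if (length(trees) == 1L) trees[[1L]] else structure(trees, class = "multiPhylo")
}

#' Serialize a tree to Newick
#'
#' The output round-trips: re-parsing yields a tree with the identical
#' bipartition set and leaf labels (rotation and anchoring may differ).
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when given the string is written there.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  check_phylo(tree)
  s <- if (ape::Ntip(tree) == 1L) {
    paste0(tree$tip.label, ";")
  } else {
    ape::write.tree(tree, digits = digits)
  }
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Restrict a tree to a subset of its leaves
#'
#' Induces the subtree connecting `subset` and suppresses all degree-2
#' nodes, so every bipartition of the result is the restriction of a
#' bipartition of the input. Subsets of size 1 or 2 yield trivial trees
#' carrying no topology.
#'
#' @param tree A `phylo` object.
#' @param subset Character vector of leaf labels, a subset of the tree's.
#' @return A `phylo` object on exactly `subset`.
#' @export
restrict_tree <- function(tree, subset) {
  check_phylo(tree)
  subset <- unique(as.character(subset))
  missing <- setdiff(subset, tree$tip.label)
  if (length(missing))
    stop("leaves not in tree: ", paste(missing, collapse = ", "))
  if (length(subset) == 0L) stop("empty leaf subset")
  if (length(subset) == ape::Ntip(tree)) return(tree)
  if (length(subset) == 1L) return(single_tip_tree(subset))
  if (length(subset) == 2L) return(two_tip_tree(subset))
  ape::keep.tip(tree, subset)
}

#' Root an unrooted tree at (the attachment node of) a leaf
#'
#' Places the root at the internal node to which `leaf` attaches and
#' removes `leaf`; the result is a rooted tree on the remaining leaves.
#' This is the device by which two constraint trees sharing a merged leaf
#' are converted to rooted trees for compatibility testing.
#'
#' @param tree A `phylo` object with at least 3 leaves.
#' @param leaf The leaf label to root at.
#' @return A rooted `phylo` object on `setdiff(leaves, leaf)`.
#' @export
root_at_leaf <- function(tree, leaf) {
  check_phylo(tree)
  if (ape::Ntip(tree) < 3L)
    stop("cannot root a tree with fewer than 3 leaves")
  if (!leaf %in% tree$tip.label)
    stop("leaf not in tree: ", leaf)
  tr <- if (ape::is.rooted(tree) && ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  tr <- ape::root(tr, outgroup = leaf, resolve.root = TRUE)
  out <- ape::drop.tip(tr, leaf, collapse.singles = TRUE)
  out
}

#' Nontrivial bipartitions of a tree
#'
#' Each internal edge of the unrooted topology contributes one split,
#' encoded canonically as the sorted leaf labels of the side *not*
#' containing the lexicographically smallest leaf. Trees on fewer than 4
#' leaves have no nontrivial splits.
#'
#' @param tree A `phylo` object.
#' @return Character vector of canonical split encodings (possibly empty),
#'   with the full leaf set attached as attribute `"leaves"`.
#' @export
tree_bipartitions <- function(tree) {
  check_phylo(tree)
  n <- ape::Ntip(tree)
  labs <- tree$tip.label
  if (n < 4L)
    return(structure(character(0), leaves = sort(labs)))
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  pp <- ape::prop.part(tr)
  anchor <- min(labs)
  out <- character(0)
  # entry 1 is the basal node (all tips); the rest are one side each of an
  # internal edge of the unrooted tree
  if (length(pp) > 1L) {
    for (k in 2:length(pp)) {
      side <- tr$tip.label[pp[[k]]]
      if (length(side) < 2L || length(side) > n - 2L) next
      if (anchor %in% side) side <- setdiff(labs, side)
      out <- c(out, paste(sort(side), collapse = SPLIT_SEP))
    }
  }
  structure(unique(out), leaves = sort(labs))
}

#' Test two trees for equal unrooted topology
#'
#' True when the leaf sets coincide and the bipartition sets are equal.
#'
#' @param a,b `phylo` objects.
#' @return Logical scalar.
#' @export
same_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  sa <- tree_bipartitions(a)
  sb <- tree_bipartitions(b)
  setequal(sa, sb)
}

#' Read a FASTA alignment
#'
#' Sequences are case-folded to uppercase; all records must have equal
#' length and unique labels. Characters outside `A`, `C`, `G`, `T` are kept
#' but treated as missing by the distance routines.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of equal-length sequence strings.
#' @export
read_alignment <- function(path) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty alignment: ", path)
  seqs <- vapply(as.character(dna), function(x) paste0(toupper(x), collapse = ""),
                 character(1))
  as_alignment(seqs)
}

#' Validate (and normalize) an alignment object
#'
#' @param seqs Named character vector of sequences.
#' @return The validated, uppercased vector.
#' @export
as_alignment <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment sequences must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence labels")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  toupper(seqs)
}

#' Write an alignment to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(seqs, path) {
  seqs <- as_alignment(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    cat(">", names(seqs)[i], "\n", seqs[[i]], "\n", sep = "", file = con)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------

single_tip_tree <- function(label) {
  structure(list(edge = matrix(c(2L, 1L), 1, 2),
                 tip.label = label, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

two_tip_tree <- function(labels) {
  structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 tip.label = labels, Nnode = 1L),
            class = "phylo", order = "cladewise")
}

check_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("expected a 'phylo' object, got ", paste(class(tree), collapse = "/"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label(s) in tree")
  invisible(tree)
}

# binary in the unrooted sense: n >= 4 unrooted trees have n-2 internal
# nodes; a rooted-binary stored tree has n-1 (the extra degree-2 anchor)
is_binary_tree <- function(tree) {
  n <- ape::Ntip(tree)
  if (n <= 3L) return(TRUE)
  tree$Nnode == n - 2L || (ape::is.rooted(tree) && tree$Nnode == n - 1L && ape::is.binary(tree))
}

as_unrooted <- function(tree) {
  if (ape::Ntip(tree) > 2L && ape::is.rooted(tree)) ape::unroot(tree) else tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a
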