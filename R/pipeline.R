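# The divide-and-conquer pipeline: (1) estimate pairwise distances,
# (2) build an NJ starting tree and decompose it into disjoint bounded
# subsets, (3) build a tree on each subset, (4) merge the subset trees
# under the distance matrix. Wall-clock seconds for steps 1, 3 and 4 are
# recorded in a runtime ledger whose serial total is
# t_P = t_D + sum_i t_T(i) + t_M.

#' Run the divide-and-conquer merge pipeline
#'
#' @param gene_trees List or `multiPhylo` of gene trees (required for
#'   `distance = "agid"`).
#' @param alignment Named character vector of equal-length sequences
#'   (required for `distance = "logdet"`).
#' @param distance `"agid"` or `"logdet"`.
#' @param max_size Maximum subset size for the centroid decomposition
#'   (defaults to 30, the bound used at roughly 100 taxa; ~120 suits
#'   1000-taxon problems).
#' @param base Subset-tree method: `"nj"` (neighbor joining on the
#'   restricted distance matrix), `"true"` (restriction of `true_tree`,
#'   for validation), a function `function(taxa) -> phylo`, or a shell
#'   command template containing the placeholders `{taxa}` (path of a file
#'   with one taxon per line) and `{out}` (path the command must write a
#'   Newick tree to).
#' @param true_tree Reference tree for `base = "true"`.
#' @param mode Proposal screening mode passed to [njmerge()].
#' @param iterations Number of decompose/merge rounds; each round after
#'   the first decomposes the previous merged tree. Default 1.
#' @param seed Optional integer seed (only matters for stochastic base
#'   methods; the internal ones are deterministic).
#' @return An object of class `njmerge_pipeline`: list with `tree`,
#'   `ledger` (class `runtime_ledger`), `decomposition`,
#'   `constraint_trees`, `matrix`, and `join_log`.
#' @export
run_pipeline <- function(gene_trees = NULL, alignment = NULL,
                         distance = c("agid", "logdet"), max_size = 30,
                         base = "nj", true_tree = NULL,
                         mode = c("pairwise", "groupwise"),
                         iterations = 1L, seed = NULL) {
  distance <- match.arg(distance)
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)

  t0 <- proc.time()[["elapsed"]]
  D <- switch(distance,
    agid = {
      if (is.null(gene_trees)) stop("distance = 'agid' requires gene trees")
      agid_matrix(gene_trees)
    },
    logdet = {
      if (is.null(alignment)) stop("distance = 'logdet' requires an alignment")
      logdet_matrix(alignment)
    })
  t_D <- proc.time()[["elapsed"]] - t0

  start_tree <- nj_tree(D)
  merged <- NULL
  for (round in seq_len(max(1L, as.integer(iterations)))) {
    guide <- if (round == 1L) start_tree else merged$tree
    decomp <- centroid_decompose(guide, max_size)

    t_T <- numeric(length(decomp))
    constraints <- vector("list", length(decomp))
    for (i in seq_along(decomp)) {
      ti <- proc.time()[["elapsed"]]
      constraints[[i]] <- build_subset_tree(base, decomp[[i]], D, true_tree)
      t_T[i] <- proc.time()[["elapsed"]] - ti
      if (!setequal(constraints[[i]]$tip.label, decomp[[i]]))
        stop("subset tree for subset ", i,
             " does not match the subset's taxa")
    }
    if (identical(base, "true")) {
      ok <- vapply(constraints, agrees_with, logical(1), big = true_tree)
      if (!all(ok))
        stop("internal error: restriction constraint disagrees with the true tree")
    }

    tm0 <- proc.time()[["elapsed"]]
    informative <- Filter(function(t) ape::Ntip(t) >= 3L, constraints)
    merged <- njmerge(informative, D, mode = mode)
    t_M <- proc.time()[["elapsed"]] - tm0
  }

  ledger <- structure(list(t_D = t_D, t_T = t_T, t_M = t_M,
                           k = length(decomp)),
                      class = "runtime_ledger")
  structure(list(tree = merged$tree, ledger = ledger,
                 decomposition = decomp, constraint_trees = constraints,
                 matrix = D, join_log = merged$join_log),
            class = "njmerge_pipeline")
}

#' Serial running time of a pipeline ledger
#'
#' Returns `t_D + sum(t_T) + t_M`: the wall-clock total when the subset
#' trees are computed one after another. Per-subset times are kept
#' separately so a parallel wall-clock estimate (`t_D + max(t_T) + t_M`)
#' can be derived.
#'
#' @param ledger A `runtime_ledger`.
#' @return Total seconds.
#' @export
aggregate_runtime <- function(ledger) {
  if (!inherits(ledger, "runtime_ledger")) {
    required <- c("t_D", "t_T", "t_M")
    missing <- setdiff(required, names(ledger))
    if (length(missing))
      stop("ledger is missing component(s): ", paste(missing, collapse = ", "))
  }
  for (f in c("t_D", "t_T", "t_M")) {
    v <- ledger[[f]]
    if (is.null(v) || !is.numeric(v) || anyNA(v) || any(v < 0))
      stop("ledger component ", f, " must be nonnegative and complete")
  }
  ledger$t_D + sum(ledger$t_T) + ledger$t_M
}

#' @export
print.runtime_ledger <- function(x, ...) {
  cat(sprintf("Runtime ledger: t_D = %.3fs, t_T = [%s]s, t_M = %.3fs, total = %.3fs\n",
              x$t_D, paste(sprintf("%.3f", x$t_T), collapse = ", "), x$t_M,
              aggregate_runtime(x)))
  invisible(x)
}

#' @export
print.njmerge_pipeline <- function(x, ...) {
  cat("Divide-and-conquer merge pipeline\n")
  cat("  taxa:", ape::Ntip(x$tree), "  subsets:",
      length(x$decomposition), "\n")
  print(x$ledger)
  invisible(x)
}

# ---- internal ---------------------------------------------------------

build_subset_tree <- function(base, taxa, D, true_tree) {
  if (is.function(base)) return(base(taxa))
  if (identical(base, "nj")) {
    if (length(taxa) < 3L) return(trivial_tree(taxa))
    return(nj_tree(D[taxa, taxa, drop = FALSE]))
  }
  if (identical(base, "true")) {
    if (is.null(true_tree)) stop("base = 'true' requires true_tree")
    return(restrict_tree(true_tree, taxa))
  }
  if (is.character(base) && length(base) == 1L)
    return(run_external_base(base, taxa))
  stop("unrecognized base method")
}

trivial_tree <- function(taxa) {
  if (length(taxa) == 1L) single_tip_tree(taxa) else two_tip_tree(taxa)
}

run_external_base <- function(template, taxa) {
  if (!grepl("{taxa}", template, fixed = TRUE) ||
      !grepl("{out}", template, fixed = TRUE))
    stop("command template must contain the {taxa} and {out} placeholders")
  taxa_file <- tempfile("subset_taxa_", fileext = ".txt")
  out_file <- tempfile("subset_tree_", fileext = ".nwk")
  on.exit(unlink(c(taxa_file, out_file)), add = TRUE)
  writeLines(taxa, taxa_file)
  cmd <- gsub("{taxa}", shQuote(taxa_file), template, fixed = TRUE)
  cmd <- gsub("{out}", shQuote(out_file), cmd, fixed = TRUE)
  status <- system(cmd)
  if (!identical(status, 0L))
    stop("subset-tree command failed (exit ", status, ") for taxa: ",
         paste(taxa, collapse = ", "))
  if (!file.exists(out_file))
    stop("subset-tree command produced no output for taxa: ",
         paste(taxa, collapse = ", "))
  tr <- tryCatch(read_newick(out_file), error = function(e)
    stop("unparsable subset-tree output for taxa ",
         paste(taxa, collapse = ", "), ": ", conditionMessage(e)))
  tr
}
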