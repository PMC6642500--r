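test_that("the cherry screen accepts cherries and vacuous pairs only", {
  f <- list(parse_newick("((A,B),(C,D));"))
  expect_true(check_property1(f, "A", "B"))
  expect_true(check_property1(f, "C", "D"))
  expect_false(check_property1(f, "A", "C"))
  expect_true(check_property1(f, "A", "X"))  # no common tree: vacuous
  # a tree where G and H co-occur as non-siblings blocks the (G,H) proposal
  tj <- parse_newick("((G,E),(F,H));")
  expect_false(check_property1(list(tj), "G", "H"))
  expect_true(check_property1(list(tj), "G", "E"))
})

test_that("relabeling renames, contracts cherries, and drops spent trees", {
  ti <- parse_newick("((C,E1),(E2,E3));")
  tj <- parse_newick("((D,F1),(F2,F3));")
  out <- relabel_forest(list(ti, tj), "C", "D", "X")
  expect_true(all(vapply(out, function(t) "X" %in% t$tip.label, logical(1))))
  expect_equal(length(out), 2)

  # contracting a cherry of a quartet leaves a constraint-free 3-leaf tree
  q <- parse_newick("((A,B),(C,D));")
  out2 <- relabel_forest(list(q), "A", "B", "z")
  expect_equal(ape::Ntip(out2[[1]]), 3)
  expect_true(check_property1(out2, "z", "C"))  # 3-leaf trees impose nothing
  expect_true(check_property1(out2, "C", "D"))

  # a tree containing neither label is untouched
  other <- parse_newick("((P,Q),(R,S));")
  out3 <- relabel_forest(list(other), "A", "B", "z")
  expect_true(same_topology(out3[[1]], other))

  # contracting a non-cherry is a contract violation
  expect_error(relabel_forest(list(q), "A", "C", "z"), "non-cherry")

  # contracting a cherry of a 3-leaf tree leaves 2 leaves: dropped
  tri <- parse_newick("(A,B,C);")
  expect_equal(length(relabel_forest(list(tri), "A", "B", "z")), 0)
})

test_that("the compatibility screen mirrors rooted BUILD on updated trees", {
  # single updated tree: nothing to test
  f1 <- list(parse_newick("((A,B),(C,D));"))
  expect_true(check_property2(f1, "A", "X"))

  # two trees whose updated versions share only the merged leaf: disjoint
  # rooted residuals are always compatible
  f2 <- list(parse_newick("((A,B),(C,D));"), parse_newick("((E,F),(G,H));"))
  expect_true(check_property2(f2, "A", "E"))

  # after earlier merges two trees can share several leaves; a clashing
  # triplet must be caught exactly as the exhaustive oracle dictates
  ta <- parse_newick("((m1,P),(m2,Q));")
  tb <- parse_newick("((m1,m2),(R,S));")
  p2 <- check_property2(list(ta, tb), "P", "R")
  sim <- relabel_forest(list(ta, tb), "P", "R", "zz")
  rooted <- lapply(sim, root_at_leaf, leaf = "zz")
  expect_equal(p2, oracle_rooted_compatible(rooted))
  expect_equal(p2, rooted_compatible(rooted))
})

test_that("property screens match a rooted-at-z surgery route on random states", {
  # the screen's internal cluster derivation must agree with literally
  # rooting the relabeled trees at z via tree surgery
  set.seed(91)
  for (i in 1:25) {
    labs <- paste0("t", 1:12)
    perm <- sample(labs)
    f <- list(random_binary_tree(6, labels = perm[1:6]),
              random_binary_tree(6, labels = perm[7:12]))
    x <- sample(f[[1]]$tip.label, 1)
    y <- sample(f[[2]]$tip.label, 1)
    fast <- check_property2(f, x, y)
    sim <- relabel_forest(f, x, y, ".zz")
    G <- Filter(function(t) ".zz" %in% t$tip.label && ape::Ntip(t) >= 4, sim)
    slow <- length(G) <= 1 ||
      rooted_compatible(lapply(G, root_at_leaf, leaf = ".zz"))
    expect_equal(fast, slow, info = paste("case", i))
  }
})

test_that("merging with an empty forest is plain neighbor joining", {
  for (seed in 1:15) {
    tr <- random_binary_tree(sample(6:15, 1), seed = seed)
    D <- nearly_additive_perturb(tr, seed = seed + 500)
    expect_true(same_topology(njmerge(list(), D)$tree, nj_tree(D)))
  }
})

test_that("agreeing constraints and a nearly additive matrix recover the tree", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(c(10, 20, 30), 1)
    tr <- random_binary_tree(n)
    D <- nearly_additive_perturb(tr)
    dec <- centroid_decompose(tr, max(4, ceiling(n / sample(2:5, 1))))
    cons <- Filter(function(t) ape::Ntip(t) >= 3,
                   lapply(dec, function(s) restrict_tree(tr, s)))
    res <- njmerge(cons, D)
    expect_equal(rf_error(tr, res$tree), 0, info = paste("trial", i))
    expect_true(is_compatibility_supertree(res$tree, cons))
  }
})

test_that("constraints overrule the distance matrix but the output stays a supertree", {
  # D additive for a tree with cherry (G,H); a constraint displaying G,H as
  # non-siblings forces a different join, yet the result must agree with it
  anchor <- parse_newick("(((A:1,B:1):1,(C:1,D:1):1):1,E:1,(F:1,(G:1,H:1):1):1);")
  D <- additive_matrix(anchor)
  tj <- parse_newick("((G,E),(F,H));")
  res <- njmerge(list(tj), D)
  expect_true(is_compatibility_supertree(res$tree, list(tj)))
  expect_false(same_topology(res$tree, anchor))
  # G was joined with a neighbor other than H
  gh <- res$join_log[res$join_log$x == "G" | res$join_log$y == "G", ][1, ]
  expect_false(identical(sort(c(gh$x, gh$y)), c("G", "H")))
})

test_that("every returned tree is a compatibility supertree; failures raise the condition", {
  set.seed(31)
  failures <- 0
  returns <- 0
  for (i in 1:120) {
    n <- sample(9:12, 1)
    labs <- paste0("t", 1:n)
    perm <- sample(labs)
    szs <- njmerge:::parts_of_three(n)
    f <- list()
    s <- 1
    for (sz in szs) {
      f[[length(f) + 1]] <- random_binary_tree(sz, labels = perm[s:(s + sz - 1)])
      s <- s + sz
    }
    D <- if (i %% 2) njmerge:::random_dissimilarity(labs) else
      nearly_additive_perturb(random_binary_tree(n, labels = labs))
    res <- tryCatch(njmerge(f, D, check_output = FALSE),
                    njmerge_failure = function(e) e)
    if (is_njmerge_failure(res)) {
      failures <- failures + 1
      expect_s3_class(res$join_log, "data.frame")
    } else {
      returns <- returns + 1
      expect_true(is_compatibility_supertree(res$tree, f))
    }
  }
  expect_gt(returns, 0)
})

test_that("input validation rejects overlap and missing taxa", {
  D <- njmerge:::random_dissimilarity(paste0("t", 1:8))
  f_overlap <- list(parse_newick("((t1,t2),(t3,t4));"),
                    parse_newick("((t4,t5),(t6,t7));"))
  expect_error(njmerge(f_overlap, D), "disjoint")
  f_missing <- list(parse_newick("((t1,t2),(t3,zz));"))
  expect_error(njmerge(f_missing, D), "absent")
})

test_that("groupwise screening is at least as strict as pairwise", {
  # on the frozen pairwise-compatible / jointly-incompatible triple, the
  # groupwise screen must reject a proposal the pairwise screen accepts
  f <- list(parse_newick("((L3,L1),(P1,P2));"),
            parse_newick("((L4,L2),(L1,Q1));"),
            parse_newick("((L2,L3),(L4,R1));"))
  set.seed(41)
  for (i in 1:200) {
    labs <- unique(unlist(lapply(f, `[[`, "tip.label")))
    xy <- sample(labs, 2)
    if (!check_property1(f, xy[1], xy[2])) next  # screen precondition
    pw <- check_property2(f, xy[1], xy[2], mode = "pairwise")
    gw <- check_property2(f, xy[1], xy[2], mode = "groupwise")
    expect_true(!gw || pw, info = paste(xy, collapse = ","))
  }
})
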