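test_that("random topologies are uniform, binary, and seed-deterministic", {
  expect_equal(ape::Ntip(random_binary_tree(3, seed = 1)), 3)
  t30 <- random_binary_tree(30, seed = 2)
  expect_true(njmerge:::is_binary_tree(t30))
  expect_equal(anyDuplicated(t30$tip.label), 0)
  expect_true(all(t30$edge.length > 0))
  expect_identical(write_newick(random_binary_tree(12, seed = 9)),
                   write_newick(random_binary_tree(12, seed = 9)))

  # the three quartet topologies appear uniformly
  set.seed(3)
  tops <- replicate(1200, oracle_quartet(
    random_binary_tree(4, labels = c("A", "B", "C", "D")),
    c("A", "B", "C", "D")))
  counts <- table(factor(tops, levels = c("AB|CD", "AC|BD", "AD|BC")))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("coalescent gene trees match the 3-taxon concordance law", {
  # internal branch of T coalescent units: P(gene tree matches) =
  # 1 - (2/3) exp(-T)
  N <- 2e5
  for (Tcoal in c(0.5, 2)) {
    sp <- parse_newick(sprintf("((A:%d,B:%d):%d,C:%d);",
                               100000L, 100000L, as.integer(Tcoal * N),
                               100000L + as.integer(Tcoal * N)))
    gt <- msc_gene_trees(sp, 4000, pop_size = N, seed = 17)
    match_ab <- vapply(gt, function(t) {
      pa <- t$edge[match(match("A", t$tip.label), t$edge[, 2]), 1]
      pb <- t$edge[match(match("B", t$tip.label), t$edge[, 2]), 1]
      pa == pb
    }, logical(1))
    p_hat <- mean(match_ab)
    p_exp <- 1 - (2 / 3) * exp(-Tcoal)
    se <- sqrt(p_exp * (1 - p_exp) / 4000)
    expect_lt(abs(p_hat - p_exp), 3 * se)
  }
})

test_that("deep species trees silence discordance; shallow ones raise it", {
  set.seed(22)
  sp_deep <- ape::rcoal(20, tip.label = paste0("s", 1:20))
  # clamp away the occasional tiny coalescent branch, then make every
  # branch many times the population size
  sp_deep$edge.length <- pmax(sp_deep$edge.length, 0.05) * 2e7
  sp_shallow <- sp_deep
  sp_shallow$edge.length <- sp_deep$edge.length / 100
  g_deep <- msc_gene_trees(sp_deep, 60, pop_size = 2e5, seed = 23)
  g_shallow <- msc_gene_trees(sp_shallow, 60, pop_size = 2e5, seed = 23)
  rf_deep <- mean(vapply(g_deep, function(g) rf_error(sp_deep, g), numeric(1)))
  rf_shallow <- mean(vapply(g_shallow, function(g) rf_error(sp_shallow, g),
                            numeric(1)))
  expect_lt(rf_deep, 0.02)
  expect_gt(rf_shallow, rf_deep)
  # structural contract: rooted binary trees on the species labels
  expect_true(all(vapply(g_deep, ape::is.rooted, logical(1))))
  expect_true(all(vapply(g_deep, function(g)
    setequal(g$tip.label, sp_deep$tip.label), logical(1))))
})

test_that("Jukes-Cantor simulation honors branch lengths", {
  flat <- parse_newick("(a:0,b:0,c:0);")
  aln0 <- jc_sequences(flat, 500, seed = 5)
  expect_equal(aln0[["a"]], aln0[["b"]])
  expect_equal(aln0[["a"]], aln0[["c"]])

  two <- parse_newick("(x:0.15,y:0.15);")
  aln <- jc_sequences(two, 1e5, seed = 6)
  mm <- mean(strsplit(aln[["x"]], "")[[1]] != strsplit(aln[["y"]], "")[[1]])
  p <- 0.75 * (1 - exp(-4 * 0.3 / 3))
  expect_lt(abs(mm - p), 3 * sqrt(p * (1 - p) / 1e5))
  expect_error(jc_sequences(parse_newick("((A,B),(C,D));"), 10), "branch lengths")
})

test_that("nearly additive perturbations stay within the half-shortest-branch bound", {
  for (seed in 1:20) {
    tr <- random_binary_tree(sample(5:30, 1), seed = seed)
    A <- additive_matrix(tr)
    P <- nearly_additive_perturb(tr, seed = seed + 40)
    bound <- 0.5 * min(tr$edge.length)
    expect_lt(max(abs(P - A)), bound)
    expect_equal(P, t(P))
    expect_true(all(diag(P) == 0))
    expect_equal(rf_error(tr, nj_tree(P)), 0)
  }
})

test_that("the adversarial search returns certified failing instances", {
  adv <- adversarial_forest(seed = 42)
  expect_true(length(adv$forest) >= 3)
  tips <- lapply(adv$forest, `[[`, "tip.label")
  expect_equal(anyDuplicated(unlist(tips)), 0)   # pairwise disjoint
  err <- tryCatch(njmerge(adv$forest, adv$D, check_output = FALSE),
                  njmerge_failure = function(e) e)
  expect_true(is_njmerge_failure(err))
  expect_s3_class(err$join_log, "data.frame")

  # the same taxa under constraints that agree with one tree succeed
  labs <- rownames(adv$D)
  ref <- random_binary_tree(length(labs), seed = 7, labels = labs)
  good <- lapply(tips, function(s) restrict_tree(ref, s))
  res <- njmerge(good, nearly_additive_perturb(ref, seed = 8))
  expect_equal(rf_error(ref, res$tree), 0)
})
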