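---
title: "Constrained neighbor joining: model, guarantees, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained neighbor joining: model, guarantees, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(njmerge)
library(ape)
```

## The estimation problem

Distance-based phylogeny estimation takes a dissimilarity matrix $D$ on
taxa $S$ and returns a tree; Neighbor Joining (NJ) is its classic
polynomial-time representative. In divide-and-conquer analyses of large
datasets one additionally holds a forest $\mathcal{T} = \{T_1, \dots,
T_k\}$ of unrooted binary trees on **pairwise disjoint** subsets of $S$,
each estimated by a (usually more accurate, more expensive) method on its
subset. The task this package solves is the constrained variant: return a
tree on all of $S$ that *agrees with* every $T_i$, i.e. whose restriction
to the leaves of $T_i$ (after suppressing degree-2 nodes) is isomorphic
to $T_i$. A tree with that property is a *compatibility supertree* of
$\mathcal{T}$; because the $T_i$ are leaf-disjoint, one always exists
(join them arbitrarily as clades), and the constraint trees need not form
clades in a valid answer. $D$ is used to pick a *good* compatibility
supertree. We call $D$ a dissimilarity matrix deliberately: estimated
distances may violate the triangle inequality, and nothing here assumes
it.

## The merge algorithm

The merger inherits NJ's agglomerative skeleton unchanged. With $r$
active nodes and row sums $R_i = \sum_k D[i,k]$,

$$Q[i,j] = (r-2)\,D[i,j] - R_i - R_j,$$

and an accepted join $(x, y) \mapsto z$ updates
$D[z,k] = \tfrac12\left(D[x,k] + D[y,k] - D[x,y]\right)$. Where plain NJ
takes the argmin of $Q$, the constrained merger sorts the strict upper
triangle of $Q$ ascending and accepts the first pair passing:

* **Property 1 (cherry screen).** If $x$ and $y$ co-occur in some $T_i$,
  they must form a cherry there. Trees on three leaves impose nothing: an
  unrooted 3-leaf tree has a single internal node, so every leaf pair is
  a cherry.
* **Property 2 (compatibility screen).** Simulate the relabeling: in
  trees containing one of $x, y$, rename that leaf $z$; in trees
  containing both, contract the cherry to $z$. Every pair of updated
  trees containing $z$ is rooted at $z$ and tested for rooted
  compatibility. Only trees containing $x$ or $y$ change, so only those
  pairs need testing; all other pairs remain compatible by induction.

Relabeling makes constraint trees overlap as the run proceeds, which is
precisely why compatibility testing becomes possible (rooting at the
shared leaf $z$) and why it becomes necessary. Deciding compatibility of
*unrooted* trees is NP-complete, so the pairwise rooted test is a
heuristic: pairwise compatibility does not imply joint compatibility (the
test suite carries a 4-taxon triple witnessing this). A run can therefore
paint itself into a corner; when a full scan of the remaining pairs finds
no acceptable proposal, the merger raises an `njmerge_failure` condition
carrying the join log. It never returns a malformed tree, and any tree it
does return is verified (by default) to be a compatibility supertree of
the original forest.

A `groupwise` mode replaces the pairwise screen with one BUILD test over
*all* updated trees containing $z$; it is strictly more conservative and
is offered because the whole-group test is also polynomial. The default
is the pairwise heuristic.

**Rooted compatibility (BUILD).** We use the cluster-graph formulation of
Aho's algorithm: at each recursion level over leaf set $L$, connect two
leaves whenever some input tree has a proper cluster (restricted to $L$)
containing both; if the graph on $|L| \ge 3$ leaves is connected the
inputs are incompatible, otherwise recurse into each component.
Connected components are computed by union-find, and leaves are processed
in sorted order so traces are reproducible. Internally the screen never
performs tree surgery: the clusters of a tree rooted at leaf $z$ are
exactly the away-from-$z$ sides of the tree's nontrivial splits, so they
are read off the split set directly (a property test cross-checks this
against literal root-and-prune surgery).

## Correctness guarantee and its premises

Call $M$ *nearly additive* for an edge-weighted tree $T^*$ when every
entry differs from the corresponding $T^*$ path length by less than half
the shortest branch length of $T^*$. NJ applied to a nearly additive
matrix for $T^*$ returns $T^*$; consequently, if additionally every
constraint tree agrees with $T^*$, the constrained merger accepts exactly
NJ's proposals (the screens never fire against proposals consistent with
$T^*$) and returns $T^*$. The acceptance suite exercises this at scale:
200 random trees with $n \in \{10, 20, 30\}$, centroid decompositions
into 2–5 subsets, constraints taken as true-tree restrictions, and
uniform perturbations at 0.49 of the shortest branch — 200/200 exact
recoveries. The same mechanism transfers statistical consistency from the
distance estimator and the subset-tree method to the whole pipeline: with
probability tending to 1 the matrix becomes nearly additive and the
constraints agree with the true tree, and the merger then cannot fail.

## Distances

**AGID.** The average gene-tree internode distance between taxa $i$ and
$j$ is the mean, over gene trees containing both, of the number of
internal nodes on the $i$–$j$ path in the unrooted gene-tree topology.
This matrix converges, as genes accumulate under the multispecies
coalescent, to a matrix additive for the species tree, which is what
makes NJ on it (NJst) and the constrained pipeline consistent. Two
documented conventions: (a) we count internal *nodes*, not edges — the
two differ by a uniform off-diagonal $+1$, which shifts $Q$ uniformly and
cannot change the first join, and for zero discordance the node count is
itself exactly additive (unit internal edges, half-unit pendants), a
stronger statement verified in the tests; (b) taxa missing from a gene
tree simply drop out of that gene's average, and a pair co-occurring
nowhere is an error naming the pair.

**Log-det.** For each pair we tally the $4 \times 4$ relative divergence
matrix $F$ over sites where both sequences hold a plain `A/C/G/T`
(anything else is excluded pairwise) and report the paralinear form

$$d = -\tfrac14\!\left[\ln \det F - \tfrac12 \ln\!\Big(\textstyle\prod_a f_a \prod_a g_a\Big)\right]$$

with $f$, $g$ the row and column marginals. Under stationary Jukes-Cantor
evolution this equals the expected substitutions per site (the tests
check a 0.3-substitutions pair at $10^5$ sites to within 1%), and it
remains consistent under general Markov substitution — the reason it is a
sound species-tree input when a relaxed clock holds across genes.
Saturated pairs ($\det F \le 0$ or a zero marginal) raise an error naming
the pair; we never cap silently, because a capped entry poisons the merge
order invisibly.

## Decomposition

The centroid decomposition deletes the edge minimizing the larger side of
its leaf bipartition and recurses on the two restricted subtrees until
every part has at most `max_size` leaves (default 30, the bound suited to
~100-taxon problems; ~120 suits ~1000 taxa). Ties are broken by the
lexicographically smallest leaf on the smaller side, then by the side's
label string — published descriptions of the scheme leave tie handling
open, so we pin a deterministic variant and document it as ours. No
minimum subset size is enforced; subsets of 1–2 taxa produce trivial,
constraint-free subset trees, which the merger ignores (their taxa are
still placed by the matrix). `max_size < 3` is rejected since such
subsets could never carry an informative constraint.

## Simulators: what they emulate, what they do not

* `random_binary_tree` draws topologies uniformly and branch lengths
  log-uniform on $[0.05, 1]$ substitutions/site — wide enough to give
  short interior branches without degenerate zero-length edges.
* `msc_gene_trees` runs the standard multispecies coalescent: one lineage
  per species, within-branch coalescence at rate $\binom{k}{2}$ per
  coalescent unit (generations divided by the haploid-equivalent
  population size, default 200,000, held constant across the tree), free
  coalescence above the root. Its statistical anchor is the 3-taxon law
  $P(\text{gene tree matches}) = 1 - \tfrac23 e^{-T}$ for an internal
  branch of $T$ coalescent units, checked at $10^4$ genes.
* `jc_sequences` evolves i.i.d. sites under Jukes-Cantor (no indels), via
  `phangorn::simSeq`. Real phylogenomic data involve rate heterogeneity,
  model misspecification across genes, and alignment error; passing tests
  under JC therefore demonstrates the machinery's correctness on its
  stated model, not robustness to those violations.
* `nearly_additive_perturb` adds independent uniform noise at 0.49 of the
  shortest branch — just inside the recovery margin, which is the point:
  the guarantee is exercised at its boundary, and the bound is asserted
  on every output.
* `adversarial_forest` searches (certified by actually running the
  merger) for small instances — three 4-taxon constraint trees drawn
  independently of a random dissimilarity matrix — on which the pairwise
  heuristic fails, so failure semantics are testable deterministically
  from a seed.

## Numerical and design notes

* Ties in $Q$ are broken lexicographically on the sorted label pair; this
  makes runs deterministic and label-permutation equivariant, and the
  proposal scan re-evaluates all pairs fresh each iteration (the state
  has changed, so earlier rejections are not cached).
* Branch lengths on output trees come from the standard NJ pendant
  formulas and are advisory; every contract in the package is
  topological, and unrooted topology is always compared through
  bipartition sets so the arbitrary storage anchoring never leaks.
  Negative pendant estimates are clamped to zero.
* Merged nodes get fresh `.z<i>` identifiers guaranteed not to collide
  with taxon labels; the join log maps each to its pair.
* Constraint trees shrunk to 3 leaves are retained (harmlessly — they
  constrain nothing); shrunk to 2, they are dropped.
* The post-return supertree assertion costs one agreement test per
  constraint tree and is on by default (`check_output = FALSE` disables
  it for throughput work such as the adversarial search).
* Newick dialect: optional branch lengths, internal labels discarded,
  quoted labels rejected, single-leaf `A;` supported. Distance matrices
  use the PHYLIP square dialect; asymmetry beyond $10^{-6}$ is an error
  and the parse symmetrizes exactly.

## Problem sizes used in the checks

The shipped verification runs use 200 recovery trials at up to 30 taxa,
1000 soundness runs at 9–12 taxa, 500 BUILD fuzz cases over 6-leaf
universes against exhaustive supertree enumeration, $10^4$ genes per
concordance point, 20 pipeline replicates of 1000 ten-taxon gene trees,
and $10^5$-site alignments — sizes chosen so the full battery completes
in minutes on one core while leaving each statistical check at least
three standard errors of resolution. The method itself has no such
limits; the merger's own cost is a few polynomial passes per join.

## Known limitations

The pairwise screen is a heuristic: failure is possible (and surfaced as
a typed condition) even when a compatibility supertree exists. Exact
unrooted-forest compatibility is NP-complete and out of scope, as are
overlapping (padded) decompositions, quartet-based supertree
optimization, and bootstrap support propagation. External subset-tree
methods are invoked through a command template and never reimplemented;
the iterative variant of the pipeline (re-decomposing from the merged
tree) is exposed via `iterations` but carries no accuracy claims here.
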