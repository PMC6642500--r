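Package: njmerge
Title: Constrained Neighbor Joining for Merging Disjoint Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles unrooted binary trees on pairwise disjoint taxon
    subsets into a single tree on the full taxon set, guided by a distance
    matrix, using a constrained extension of Neighbor Joining. Siblinghood
    proposals are screened against the constraint trees (cherry membership
    and pairwise rooted compatibility via the Aho BUILD algorithm) so that
    any returned tree is a compatibility supertree of the input forest.
    Includes the surrounding divide-and-conquer pipeline: average gene-tree
    internode distances, log-det (paralinear) distances from concatenated
    alignments, centroid-edge decomposition of a starting tree into
    bounded-size subsets, and pluggable subset-tree construction. Also
    ships hermetic simulators (random topologies, multispecies-coalescent
    gene trees, Jukes-Cantor sequences, nearly additive matrix
    perturbations) used to exercise the method's guarantees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
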