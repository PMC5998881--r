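Package: treedag
Title: Constrained Exact Optimization over All Optimal Supertrees and Species Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Supertree and summary-method species-tree estimation by constrained
    exact optimization. Given source trees (or gene trees) and a set of allowed
    bipartitions derived from complete constraint trees, a dynamic program over
    the lattice of allowed clades finds the exact optimum of either the
    Robinson-Foulds supertree criterion or the shared-quartet criterion, and
    records every optimal split, yielding a directed acyclic graph that
    compactly represents all optimal trees. The DAG supports exact counting of
    optima with arbitrary-precision integers, exact bipartition frequencies,
    strict/majority/greedy/alpha consensus trees, uniform sampling and full
    enumeration of optima, frequency-corrected branch support, and a greedy
    maximum clade credibility tree. Includes brute-force oracles and a seeded
    synthetic fixture generator for validation, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
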