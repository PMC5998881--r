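---
title: "Constrained exact optimization over all optimal supertrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained exact optimization over all optimal supertrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Supertree estimation and summary-method species-tree estimation both combine
trees on subsets of a species set S into one tree on all of S, optimizing an
NP-hard criterion.  A practical route to exact solutions is to constrain the
search space: a set X of *allowed bipartitions* is harvested from complete
trees produced by other methods, and the optimal tree among those drawing all
their bipartitions from X can then be found in polynomial time by dynamic
programming over the *allowed clades* (the halves of the bipartitions in X,
the singletons, and S itself).

A dynamic program that returns a single backpointer per clade returns a
single optimum — but these criteria are integer-valued counts, and exact ties
are common; real supertree datasets can have astronomically many co-optimal
trees.  `treedag` keeps, for every clade, the *set* of all score-attaining
splits.  The resulting table is a directed acyclic graph whose root-to-leaf
trees are exactly the optimal rooted trees, and that DAG supports exact
counting, exact per-bipartition frequencies, full enumeration, uniform
sampling, consensus construction, and frequency-corrected branch support.

## Criteria and the tripartition decomposition

Two criteria are built in, both maximized, both integer-valued:

* **Robinson–Foulds supertree criterion** (`rfs_scorer`): the number of
  non-trivial bipartitions shared between the candidate tree restricted to
  each source tree's leaf set and that source tree, summed over source trees.
  Maximizing it is equivalent to minimizing the total RF distance to the
  source trees; `rfs_total_rf()` reports that companion value.
* **Shared-quartet criterion** (`quartet_scorer`): the number of 4-taxon
  subsets on which the candidate tree and a gene tree induce the same
  unrooted quartet topology, summed over gene trees.  This is the criterion
  optimized by quartet-based coalescent-aware species-tree methods;
  maximizing it is statistically consistent under the multi-species
  coalescent when X is chosen well.

The DP requires a weight w on tripartitions (A, B, C) — the two child clades
of a node of a rooted tree plus the rest of S — such that summing w over the
n − 1 tripartitions of **any** rooting of a complete binary tree T
reproduces the whole-tree score F(T).  That contract, not any particular
closed form, is what the implementation is held to.  The decompositions used
here were derived for this package:

* **Quartets.**  A quartet {i,j,k,l} whose gene-tree topology is ij|kl and
  which is displayed by T is counted at exactly one node of any rooting:
  at the node where the four leaves first split two-and-two across the child
  clades (i, j in A and k, l in B), or — when they split three-and-one — at
  the lower node where the together-pair separates from the third member
  while the fourth is already outside (i, j in A, k in B, l in C).  Each
  anchor pattern implies the quartet is displayed, and exactly one pattern
  fires per displayed quartet, so the sum telescopes to the quartet count
  with no correction factor.
* **Shared bipartitions.**  For a source tree with leaf set L, each shared
  induced bipartition is counted at the minimal clade whose two children
  both intersect L (these minimal clades are in bijection with the clades of
  the restricted tree).  The two restricted root children would count the
  same bipartition twice; the unique node whose C is disjoint from L
  subtracts that duplicate when both its children hold at least two leaves
  of L and their induced split is in the source tree.

Both decompositions are validated, rather than trusted, by the test suite:
exhaustively over all 105 six-taxon topologies under seeded random source
sets, the tripartition sum must equal the independent direct scorer for
every one of the 2n − 3 rootings.

## Why rooting clades are added to the DP table

The allowed-clade set derived from X contains the halves of non-trivial
bipartitions only.  A rooted tree obtained by rooting an optimum on a
*pendant* edge, however, has a clade of size n − 1, which is the half of a
trivial bipartition.  The DP table therefore augments the clade set with the
complement of every singleton.  This changes nothing about which unrooted
trees are representable (a clade is allowed exactly when its bipartition is),
but it makes every unrooted optimum representable under all 2n − 3 of its
rootings.  Two consequences are load-bearing:

* the rooted-optimum count is exactly (2n − 3) times the unrooted count, so
  `count_unrooted_optima()` can divide exactly and treat non-divisibility as
  an internal-consistency error (it would indicate a scorer that is not
  rooting-invariant);
* every bipartition of every optimum appears as a root split, so exact
  frequencies can be read off the root split set alone: the number of
  unrooted optima containing [c | S∖c] is optsubtrees(c) · optsubtrees(S∖c).

`ConstraintSet$clades` itself keeps the conventional definition (bipartition
halves + singletons + S); the rooting clades live only in the split table.

## Frequencies, consensus, counting: exact arithmetic

Optima counts on real supertree datasets reach 10^90 and beyond, far past
what doubles or 64-bit integers hold, and tie detection and consensus
thresholds are meaningless unless exact.  All counts are arbitrary-precision
integers (`bigcount`, base-10^7 limb arithmetic implemented in the package)
and all frequencies are exact rationals compared by cross-multiplication.
The frequency denominator is the **unrooted** optimum count: bipartition
frequency is the fraction of optimal unrooted trees containing the
bipartition, which is what consensus semantics require (the companion
fraction with the rooted-count denominator — the fraction of rooted optima
rooted on that edge — is exposed as `rooted_fraction` in
`bipartition_frequencies()` for inspection only).

Consensus kinds: `strict` keeps frequency = 1; `majority` keeps > 1/2;
`alpha` with α ≥ 0.5 keeps > α (a tree by pairwise compatibility); `alpha`
with α < 0.5 and `greedy` insert bipartitions in descending frequency,
skipping incompatible ones.  Equal frequencies are ordered by the canonical
clade order of the side containing the first taxon — an arbitrary but fixed
choice, consistent with the deterministic extraction order, since a greedy
consensus is not unique under ties.  Thresholds passed as doubles are
converted to exact rationals p / 2^e (every double is such a rational), so
`alpha = 0.5` reproduces the majority consensus exactly.

`sample_optimal_tree()` draws splits with probability proportional to the
product of subtree counts, giving the uniform distribution over rooted
optima; each unrooted optimum has exactly 2n − 3 rooted representatives, so
the induced distribution over unrooted optima is uniform as well.
Uniformity (rather than an unspecified randomness) is this package's choice,
and is what the chi-square test in the suite checks.  Split probabilities
are formed as double ratios of the exact counts; beyond ~2^53 optima per
clade the proportions are approximate at relative error ~1e-16, which is
irrelevant at any testable scale.

Corrected branch support multiplies a branch's raw support (for example a
posterior probability computed elsewhere) by the fraction of optima
containing the branch, because an optimal tree lacking the branch
contributes zero support.  With a single annotated input tree this raw · A
product is the stated approximation to averaging per-tree annotations over
all optima; exact averaging would require annotating every enumerated
optimum and can be done through `enumerate_optimal_trees()` by the user.
Local posterior probabilities themselves are out of scope: `base_support` is
the injection point for externally computed values.  The greedy MCC tree is
the greedy consensus ranked by corrected support instead of raw frequency.

## Interfaces and degenerate inputs

Input trees are standard newick; branch lengths and input support labels are
accepted and discarded (every criterion here is purely topological), and
unifurcations are suppressed.  Polytomies are legal in source/gene trees —
they contribute only their resolved quartets and bipartitions — but
constraint trees must be complete on S, exactly as the upstream pipelines
that produce them (quartet-based, RF-based, or likelihood-based complete
trees) provide.  If no binary constraint tree is supplied, feasibility is
not guaranteed; an infeasible instance is reported with a witness clade that
admits no allowed split, rather than silently repaired, since how a repair
should be done is not well defined.  Output is deterministic: children are
ordered by the smallest taxon index in their subtree, and unrooted trees
serialize rooted at the internal node adjacent to the first taxon.

The `exec/treedag` script exposes the pipeline as subcommands (`search`,
`count`, `enumerate`, `sample`, `consensus`, `annotate`, `mcc`, `score`,
`fixture`); `--save-dag`/`--load-dag` cache the solution DAG as versioned
JSON, with counts as decimal strings so precision survives the round trip.
Exit codes: 0 success, 1 validation/infeasibility, 2 usage.

## The synthetic generator and what validation does (and does not) show

`generate_fixture()` emulates the structure of the inputs this method is
designed for: a uniformly drawn model topology; source trees formed by
retaining a random 75–80% subset of taxa (never fewer than 4) and applying
one NNI move, mimicking taxon subsampling and mild estimation error; and a
constraint set holding the model tree plus two NNI-perturbed complete
copies, whose conflicts create the exact ties the all-optima machinery
exists for.  Those defaults are the package's study conditions: retention
near 3/4 and single NNI moves give instances where roughly half the runs
have multiple optima at n = 6–7, which is the regime worth testing.  The
generator deliberately does **not** simulate sequence evolution, coalescent
gene-tree heterogeneity, or likelihood-based gene-tree estimation error;
passing tests therefore demonstrate the correctness of the optimization and
its analytics on structurally realistic instances, not the statistical
accuracy of any criterion on real data.

Validation sizes, chosen to keep exhaustive oracles exact: brute-force
enumeration over all (2n − 5)!! topologies at n ∈ {5, 6, 7} (51 seeded
instances per criterion, checking score, optimal set, counts, and exact
frequencies against empirical frequencies); the tripartition-sum contract
over all 105 six-taxon topologies, 20 source sets per criterion, all
rootings; consensus refinement laws over 100 instances; 10^4 seeded draws
for sampling uniformity.  The DP itself has no size limit beyond memory and
the O(|clades|^2) split scan; the quartet weight evaluation scans 4-subsets
and is the practical bottleneck for large n in this pure-R implementation.

## Known limitations

* Only the two built-in criteria are provided; the scorer interface (a
  direct tree score plus a tripartition weight satisfying the rooting-sum
  contract) is the extension point for duplication-loss or other criteria.
* Constraint sets must come from complete trees; heuristic search-space
  enrichment from incomplete source trees is not reimplemented.
* `brute_force_optima()` is restricted to n ≤ 8 (10395 topologies) by
  design — it is an oracle, not a method.
* Weighted (length- or support-aware) quartet scores are not implemented.
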