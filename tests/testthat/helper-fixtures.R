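# Shared fixture builders.  Everything is generated in code; no files.

tx4 <- taxon_index(letters[1:4])
tx5 <- taxon_index(letters[1:5])
tx6 <- taxon_index(letters[1:6])

tree_ab_cd <- function() parse_newick("((a,b),(c,d));")
tree_ac_bd <- function() parse_newick("((a,c),(b,d));")

# the two-optimum 4-taxon instance: X and sources both {ab|cd, ac|bd}
tie4 <- function(criterion = c("rfs", "quartet")) {
  criterion <- match.arg(criterion)
  trees <- list(tree_ab_cd(), tree_ac_bd())
  cs <- build_constraint_set(trees, tx4)
  src <- source_tree_set(trees, tx4)
  scorer <- if (criterion == "rfs") rfs_scorer(src) else quartet_scorer(src)
  dag <- run_dp(enumerate_splits(cs), scorer)
  list(cs = cs, src = src, scorer = scorer, dag = dag, taxa = tx4)
}

# DAG + brute-force oracle for a generated fixture
fixture_instance <- function(n, seed, criterion = "rfs", k = 4L, retention = 0.75,
                             nni = 1L, n_extra = 2L, constraint_nni = 2L) {
  fx <- generate_fixture(n, k = k, retention = retention, nni = nni, seed = seed,
                         n_extra_constraints = n_extra, constraint_nni = constraint_nni)
  cs <- build_constraint_set(fx$constraints, fx$taxa)
  src <- source_tree_set(fx$sources, fx$taxa)
  scorer <- if (criterion == "rfs") rfs_scorer(src) else quartet_scorer(src)
  dag <- run_dp(enumerate_splits(cs), scorer)
  c(fx, list(cs = cs, src = src, scorer = scorer, dag = dag))
}

canon_set <- function(trees, taxa) sort(vapply(trees, canonical_form, "", taxa = taxa))

# fresh scorer of the same criterion (for oracle runs, so caches stay separate)
fresh_scorer <- function(name, src) {
  if (name == "rfs") rfs_scorer(src) else quartet_scorer(src)
}

random_source_set <- function(taxa, k = 4L, nni = 1L) {
  n <- n_taxa(taxa)
  trees <- lapply(seq_len(k), function(i) {
    keep <- sort(sample.int(n, sample(4:n, 1L)))
    nni_perturb(restrict_tree(random_topology(taxa), keep, taxa), nni)
  })
  source_tree_set(trees, taxa)
}
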