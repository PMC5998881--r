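# The constrained dynamic program and its solution DAG.

test_that("single-tree constraint set: the DP recovers that tree exactly", {
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  cs <- build_constraint_set(list(t6), tx6)
  src <- source_tree_set(list(t6), tx6)
  for (mk in c(rfs_scorer, quartet_scorer)) {
    sc <- mk(src)
    dag <- run_dp(enumerate_splits(cs), sc)
    expect_equal(optimal_score(dag), score_tree(mk(src), t6))
    expect_identical(as.character(count_rooted_optima(dag)), "9")  # 2n - 3
    expect_identical(as.character(count_unrooted_optima(dag)), "1")
    expect_identical(canonical_form(extract_one_tree(dag), tx6),
                     canonical_form(t6, tx6))
  }
})

test_that("4-taxon tie: f(S) = 1, both root splits recorded, canonical extraction", {
  inst <- tie4("rfs")
  dag <- inst$dag
  expect_equal(optimal_score(dag), 1)
  root_pairs <- dag$splits[[dag$root_key]]
  nontrivial <- Filter(function(p) {
    length(dag$clades[[p$a]]) >= 2 && length(dag$clades[[p$b]]) >= 2
  }, root_pairs)
  got <- vapply(nontrivial, function(p) paste(p$a, p$b, sep = "/"), "")
  expect_setequal(got, c("1 2/3 4", "1 3/2 4"))
  expect_identical(canonical_form(extract_one_tree(dag), tx4),
                   canonical_form(tree_ab_cd(), tx4))
})

test_that("extraction always attains f(S) when re-scored directly", {
  set.seed(17)
  for (seed in 1:10) for (crit in c("rfs", "quartet")) {
    inst <- fixture_instance(6, seed, crit)
    phy <- extract_one_tree(inst$dag)
    expect_equal(score_tree(fresh_scorer(crit, inst$src), phy),
                 optimal_score(inst$dag))
  }
})

test_that("every DAG subtree attains the optimal score of its clade", {
  # optimal-substructure soundness: re-score deterministic sub-extractions
  inst <- fixture_instance(7, 3, "rfs")
  dag <- inst$dag
  sc <- inst$scorer
  S <- seq_len(dag$n)
  subtree_weight_sum <- function(nested) {
    if (!is.list(nested)) return(0)
    A <- treedag:::nested_leaves(nested[[1]])
    B <- treedag:::nested_leaves(nested[[2]])
    sc$weight(A, B, setdiff(S, c(A, B))) +
      subtree_weight_sum(nested[[1]]) + subtree_weight_sum(nested[[2]])
  }
  for (key in names(dag$clades)) {
    fk <- dag$f[[key]]
    if (is.null(fk) || !is.finite(fk) || length(dag$clades[[key]]) < 2) next
    nested <- treedag:::dag_first_nested(dag, key)
    expect_equal(subtree_weight_sum(nested), fk)
  }
})

test_that("infeasible constraint sets raise a witness-naming error", {
  # only a star tree: no binary tree can be assembled from its clades
  expect_warning(cs <- build_constraint_set(list(parse_newick("(a,b,c,d,e);")), tx5),
                 "no binary")
  src <- source_tree_set(list(parse_newick("((a,b),(c,d));")), tx5)
  expect_error(run_dp(enumerate_splits(cs), rfs_scorer(src)), "infeasible")
})

test_that("adding bipartitions to X never worsens the optimum", {
  set.seed(29)
  for (seed in 1:6) {
    fx <- generate_fixture(6, k = 4, retention = 0.75, nni = 1, seed = seed,
                           n_extra_constraints = 2, constraint_nni = 2)
    src <- source_tree_set(fx$sources, fx$taxa)
    cs_small <- build_constraint_set(fx$constraints[1], fx$taxa)
    cs_big <- build_constraint_set(fx$constraints, fx$taxa)
    for (crit in c("rfs", "quartet")) {
      f_small <- optimal_score(run_dp(enumerate_splits(cs_small), fresh_scorer(crit, src)))
      f_big <- optimal_score(run_dp(enumerate_splits(cs_big), fresh_scorer(crit, src)))
      expect_gte(f_big, f_small)
    }
  }
})

test_that("DAG JSON round trip preserves scores, counts, and extraction", {
  inst <- fixture_instance(6, 18, "rfs", n_extra = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_dag(inst$dag, path)
  dag2 <- load_dag(path)
  expect_equal(optimal_score(dag2), optimal_score(inst$dag))
  expect_identical(as.character(count_rooted_optima(dag2)),
                   as.character(count_rooted_optima(inst$dag)))
  expect_identical(canonical_form(extract_one_tree(dag2), inst$taxa),
                   canonical_form(extract_one_tree(inst$dag), inst$taxa))
  expect_identical(canon_set(enumerate_optimal_trees(dag2), inst$taxa),
                   canon_set(enumerate_optimal_trees(inst$dag), inst$taxa))
})
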