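# Counting, frequencies, enumeration, sampling, consensus, support, errors.

test_that("counting identities: single tree and the 4-taxon tie", {
  t5 <- parse_newick("(((a,b),c),(d,e));")
  cs <- build_constraint_set(list(t5), tx5)
  dag <- run_dp(enumerate_splits(cs), rfs_scorer(source_tree_set(list(t5), tx5)))
  expect_identical(as.character(count_rooted_optima(dag)), "7")   # 2n - 3
  expect_identical(as.character(count_unrooted_optima(dag)), "1")

  inst <- tie4("rfs")
  expect_identical(as.character(count_rooted_optima(inst$dag)), "10")
  expect_identical(as.character(count_unrooted_optima(inst$dag)), "2")
})

test_that("frequencies are exact and match enumeration", {
  inst <- tie4("rfs")
  fr <- bipartition_frequencies(inst$dag)
  expect_equal(nrow(fr), 2L)
  expect_setequal(fr$bipartition, c("c,d", "b,d"))
  expect_true(all(fr$frequency_exact == "0.500000"))
  expect_true(all(fr$numerator == "1" & fr$denominator == "2"))

  # single optimum: every bipartition has frequency exactly 1
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  cs <- build_constraint_set(list(t6), tx6)
  dag <- run_dp(enumerate_splits(cs), rfs_scorer(source_tree_set(list(t6), tx6)))
  fr6 <- bipartition_frequencies(dag)
  expect_equal(nrow(fr6), 3L)
  expect_true(all(fr6$frequency_exact == "1.000000"))
})

test_that("optsubtrees conservation: root splits sum to the rooted count", {
  for (seed in c(2, 7, 18)) {
    inst <- fixture_instance(6, seed, "rfs", n_extra = 3)
    dag <- inst$dag
    total <- bigcount(0)
    for (p in dag$splits[[dag$root_key]]) {
      total <- total + treedag:::dag_optsub(dag, p$a) * treedag:::dag_optsub(dag, p$b)
    }
    expect_identical(as.character(total), as.character(count_rooted_optima(dag)))
  }
})

test_that("enumeration yields each optimum once and respects the limit", {
  inst <- tie4("quartet")
  trees <- enumerate_optimal_trees(inst$dag)
  cf <- canon_set(trees, tx4)
  expect_identical(cf, canon_set(list(tree_ab_cd(), tree_ac_bd()), tx4))
  expect_equal(length(enumerate_optimal_trees(inst$dag, limit = 1)), 1L)
})

test_that("sampling is seeded-reproducible and uniform over the optima", {
  inst <- tie4("rfs")
  s1 <- sample_optimal_tree(inst$dag, seed = 11)
  s2 <- sample_optimal_tree(inst$dag, seed = 11)
  expect_identical(canonical_form(s1, tx4), canonical_form(s2, tx4))
  draws <- sample_optimal_tree(inst$dag, seed = 5, reps = 2000, as = "newick")
  counts <- table(draws)
  expect_equal(length(counts), 2L)
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("consensus kinds behave as documented on the tie fixture", {
  inst <- tie4("rfs")
  strict <- consensus_tree(inst$dag, "strict")
  expect_equal(strict$Nnode, 1L)                       # star
  expect_equal(consensus_tree(inst$dag, "majority")$Nnode, 1L)
  greedy <- consensus_tree(inst$dag, "greedy")
  expect_identical(canonical_form(greedy, tx4), canonical_form(tree_ab_cd(), tx4))
  expect_identical(canonical_form(consensus_tree(inst$dag, "alpha", alpha = 0.5), tx4),
                   canonical_form(consensus_tree(inst$dag, "majority"), tx4))
  expect_identical(canonical_form(consensus_tree(inst$dag, "alpha", alpha = 0.25), tx4),
                   canonical_form(greedy, tx4))
  expect_error(consensus_tree(inst$dag, "alpha", alpha = 1), "alpha")
  expect_error(consensus_tree(inst$dag, "alpha"), "alpha")

  # single optimum: all four consensus kinds return that tree
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  cs <- build_constraint_set(list(t6), tx6)
  dag <- run_dp(enumerate_splits(cs), rfs_scorer(source_tree_set(list(t6), tx6)))
  for (kind in c("strict", "majority", "greedy")) {
    expect_identical(canonical_form(consensus_tree(dag, kind), tx6),
                     canonical_form(t6, tx6))
  }
})

test_that("corrected support: absent-from-optima branches are down-weighted", {
  inst <- tie4("rfs")
  # split in exactly one of the two optima: support halves
  cs1 <- corrected_support(tree_ab_cd(), inst$dag)
  expect_equal(cs1$frequency, 0.5)
  cs2 <- corrected_support(tree_ab_cd(), inst$dag, base_support = c("c,d" = 0.9))
  expect_equal(cs2$corrected, 0.45)
  cs3 <- corrected_support(tree_ab_cd(), inst$dag, base_support = c("c,d" = 1))
  expect_lte(cs3$corrected, 0.5)

  # bipartition in every optimal tree with raw 1 stays 1
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  cs <- build_constraint_set(list(t6), tx6)
  dag6 <- run_dp(enumerate_splits(cs), rfs_scorer(source_tree_set(list(t6), tx6)))
  sup <- corrected_support(t6, dag6, base_support = c("d,e,f" = 1, "a,b" = 1, "d,e" = 1))
  expect_true(all(sup$corrected == 1))

  # a tree using a bipartition absent from all optima gets 0 there
  sup0 <- corrected_support(parse_newick("(((a,b),d),((c,e),f));"), dag6)
  expect_true(0 %in% sup0$frequency)
})

test_that("mcc tree: topology, support labels, and base-support reranking", {
  inst <- tie4("rfs")
  m <- mcc_tree(inst$dag)
  expect_identical(canonical_form(m, tx4), canonical_form(tree_ab_cd(), tx4))
  expect_true("0.500000" %in% m$node.label)

  # single optimum: the tree itself with all supports 1
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  cs <- build_constraint_set(list(t6), tx6)
  dag6 <- run_dp(enumerate_splits(cs), rfs_scorer(source_tree_set(list(t6), tx6)))
  m6 <- mcc_tree(dag6)
  expect_identical(canonical_form(m6, tx6), canonical_form(t6, tx6))
  expect_true(all(setdiff(m6$node.label, "") == "1.000000"))

  # constructed base supports flip the greedy ranking between the tied splits
  m_flip <- mcc_tree(inst$dag, base_support = c("c,d" = 0.2, "b,d" = 0.9))
  expect_identical(canonical_form(m_flip, tx4), canonical_form(tree_ac_bd(), tx4))
})

test_that("tree error rates match hand-computed counts", {
  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  er0 <- tree_error_rates(t6, t6)
  expect_equal(c(er0$fn, er0$fp, er0$f1), c(0, 0, 1))

  taxa10 <- taxon_index(paste0("t", 1:10))
  set.seed(2)
  model10 <- random_topology(taxa10)
  star10 <- tree_from_bipartitions(list(), taxa10)
  er1 <- tree_error_rates(star10, model10)
  expect_equal(c(er1$fn, er1$fp, er1$average), c(1, 0, 0.5))

  # one NNI on 6 taxa changes exactly one of the three internal edges:
  # swapping c with (d,e) across the middle edge keeps {a,b} and {d,e}
  t6b <- parse_newick("(((a,b),(d,e)),(c,f));")
  er2 <- tree_error_rates(t6b, t6)
  expect_equal(er2$fn, 1 / 3)
  expect_equal(er2$fp, 1 / 3)

  expect_error(tree_error_rates(t6, tree_ab_cd()), "leaf sets")
  expect_error(tree_error_rates(t6, parse_newick("(a,b,c,(d,(e,f)));")), "binary")
})
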