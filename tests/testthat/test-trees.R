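# Newick I/O and the bipartition/tripartition calculus.

test_that("parse_newick handles standard dialect and rejects bad input", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_s3_class(t1, "phylo")
  expect_equal(length(t1$tip.label), 4L)
  expect_equal(t1$Nnode, 3L)

  star <- parse_newick("(a,b,c,d,e);")
  expect_equal(star$Nnode, 1L)

  # branch lengths and support labels read and discarded
  t2 <- parse_newick("((a:1.2,b:0.1)0.95:0.3,(c:1,d:1):0.5);")
  expect_null(t2$edge.length)
  expect_null(t2$node.label)

  expect_error(parse_newick("((a,b),(a,c));"), "duplicate")
  expect_error(parse_newick("((a,b),(c,d);"), "malformed")
  expect_error(parse_newick("((a,b)),(c,d));"), "offset")
  expect_error(parse_newick("((a,b),(c,x));", tx4), "not in taxon index")
})

test_that("write_newick is deterministic and round-trip stable", {
  w <- write_newick(parse_newick("((d,c),(b,a));"), tx4)
  expect_identical(w, "((a,b),(c,d));")
  # write . parse . write == write . parse, on assorted shapes
  for (txt in c("((a,b),(c,d));", "(a,b,c,d,e);", "(((e,d),c),(a,b));",
                "((a,(b,c)),(d,(e,f)));")) {
    taxa <- taxon_index_from_trees(parse_newick(txt))
    w1 <- write_newick(parse_newick(txt), taxa)
    w2 <- write_newick(parse_newick(w1), taxa)
    expect_identical(w1, w2)
  }
  # support values become internal labels at 6 places
  w3 <- write_newick(tree_ab_cd(), tx4, support = c("c,d" = 1 / 2))
  expect_match(w3, "0.500000", fixed = TRUE)
  expect_error(write_newick(tree_ab_cd(), tx4, support = c("b,d" = 1)),
               "not a bipartition")
})

test_that("bipartitions_of returns one bipartition per internal edge", {
  expect_equal(length(bipartitions_of(unroot_tree(tree_ab_cd()), tx4)), 1L)
  b <- bipartitions_of(unroot_tree(tree_ab_cd()), tx4)[[1]]
  expect_equal(b$side, c(3L, 4L))  # canonical side excludes taxon 1
  expect_equal(length(bipartitions_of(parse_newick("(a,b,c,d,e);"), tx5)), 0L)
  # n - 3 for complete unrooted binary trees, over a range of n
  set.seed(5)
  for (n in 4:9) {
    taxa <- taxon_index(paste0("t", 1:n))
    phy <- random_topology(taxa)
    expect_equal(length(bipartitions_of(phy, taxa)), n - 3L)
  }
})

test_that("tripartitions_of covers every internal node with C empty at the root", {
  tr <- tripartitions_of(tree_ab_cd(), tx4)
  expect_equal(length(tr), 3L)
  got <- vapply(tr, function(t) paste(paste(t$A, collapse = " "), paste(t$B, collapse = " "),
                                      paste(t$C, collapse = " "), sep = ";"), "")
  expect_setequal(got, c("1;2;3 4", "3;4;1 2", "1 2;3 4;"))

  cat5 <- parse_newick("((((a,b),c),d),e);")
  tr5 <- tripartitions_of(cat5, tx5)
  expect_equal(length(tr5), 4L)
  expect_equal(sum(vapply(tr5, function(t) length(t$C) == 0L, logical(1))), 1L)

  # consistency identity: {A union B} plus singletons = clade set of the tree
  clades <- lapply(tr5, function(t) sort(c(t$A, t$B)))
  keys <- vapply(clades, function(cl) paste(cl, collapse = " "), "")
  expect_setequal(c(keys, as.character(1:5)),
                  c("1 2", "1 2 3", "1 2 3 4", "1 2 3 4 5", as.character(1:5)))

  expect_error(tripartitions_of(parse_newick("(a,b,c,d);"), tx4), "binary")
  expect_error(tripartitions_of(tree_ab_cd(), tx5), "complete")
})

test_that("restrict_tree gives the induced subtree", {
  r <- restrict_tree(parse_newick("((a,b),(c,d));"), c("a", "b", "c"))
  expect_equal(length(bipartitions_of(unroot_tree(r), tx4)), 0L)

  r2 <- restrict_tree(parse_newick("((a,b),(c,(d,e)));"), c("a", "c", "d", "e"))
  b2 <- bipartitions_of(unroot_tree(r2), tx5)
  expect_equal(length(b2), 1L)
  expect_equal(b2[[1]]$side, c(4L, 5L))

  full <- parse_newick("((a,b),(c,d));")
  expect_identical(canonical_form(restrict_tree(full, letters[1:4]), tx4),
                   canonical_form(full, tx4))
  expect_error(restrict_tree(full, c("x", "y")), "empty intersection")
})

test_that("rooting: 2n - 3 pairwise distinct rootings, all one topology", {
  u <- unroot_tree(tree_ab_cd())
  roots <- all_rootings(u, tx4)
  expect_equal(length(roots), 5L)
  expect_equal(length(unique(vapply(roots, canonical_form, "", taxa = tx4))), 1L)

  t6 <- parse_newick("(((a,b),c),((d,e),f));")
  r6 <- all_rootings(unroot_tree(t6), tx6)
  expect_equal(length(r6), 9L)
  expect_equal(length(unique(vapply(r6, write_newick, "", taxa = tx6))), 9L)

  # root_at_edge then unroot restores the topology
  rr <- root_at_edge(u, c(3L, 4L), tx4)
  expect_true(ape::is.rooted(rr))
  expect_identical(canonical_form(unroot_tree(rr), tx4), canonical_form(u, tx4))
  expect_error(root_at_edge(u, c(2L, 4L), tx4), "not an edge")
})

test_that("canonical_form equality coincides with zero RF distance", {
  expect_identical(canonical_form(tree_ab_cd(), tx4), "(a,b,(c,d));")
  expect_false(canonical_form(tree_ac_bd(), tx4) == canonical_form(tree_ab_cd(), tx4))
  set.seed(42)
  taxa <- taxon_index(paste0("t", 1:7))
  for (i in 1:300) {
    t1 <- random_topology(taxa)
    t2 <- if (i %% 3 == 0) {
      # re-serialize a scrambled copy of the same topology
      parse_newick(ape::write.tree(ape::root(t1, outgroup = sample(t1$tip.label, 1),
                                             resolve.root = TRUE)))
    } else {
      random_topology(taxa)
    }
    same_canon <- canonical_form(t1, taxa) == canonical_form(t2, taxa)
    rf <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2))
    expect_identical(same_canon, rf == 0)
  }
})
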