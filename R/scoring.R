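# The two optimization criteria.
#
# Each criterion is exposed two ways, deliberately kept independent:
#   * a direct whole-tree scorer computed from first principles (restrictions
#     and exhaustive 4-subset scans) -- the oracle path, and
#   * a tripartition weight w such that for every complete binary tree T whose
#     bipartitions are allowed, and every rooting of T, the sum of w over the
#     rooted tree's tripartitions equals the direct score.
# The dynamic program only ever sees w; the direct scorer is what tests and
# the brute-force oracle use.  All scores and weights are exact integers.
#
# Quartet criterion weight: a shared quartet {i,j,k,l} with topology ij|kl is
# counted exactly once over the nodes of any rooting, anchored at the node
# where the quartet first splits 2+2 across the two child clades, or -- when
# it splits 3+1 -- at the deeper node where the together-pair separates from
# the third member while the fourth is already outside.
#
# RF (shared bipartition) weight: for each source tree with leaf set L, a
# shared induced bipartition is counted at the minimal clade whose two
# children both intersect L; the unique node whose tripartition has C
# disjoint from L (the meet of L) subtracts one when both its children
# collect >= 2 leaves of L and their induced split is in the source tree,
# undoing the complement-side double count.

#' Bundle source trees (or gene trees) for scoring
#'
#' Precomputes, per tree: its leaf set, its bipartition set over that leaf
#' set, and the meet-depth matrix used to resolve induced quartet topologies.
#' Leaf sets may be proper subsets of the taxon set; polytomies are allowed
#' and contribute only their resolved quartets/bipartitions.
#'
#' @param trees a `phylo` or list of `phylo`, each with at least 4 leaves.
#' @param taxa a `taxon_index` covering all leaf labels.
#' @return an object of class `source_tree_set`.
#' @export
source_tree_set <- function(trees, taxa) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n <- n_taxa(taxa)
  info <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    ids <- sort(taxon_id(taxa, tr$tip.label))
    if (length(ids) < 4L) stop("source tree ", i, " has fewer than 4 leaves")
    nested <- phylo_to_nested(tr, taxa)
    D <- matrix(NA_real_, n, n)
    assign_depth <- function(node, depth) {
      if (!is.list(node)) return(invisible(NULL))
      leaf_groups <- lapply(node, nested_leaves)
      for (x in seq_along(leaf_groups)) for (y in seq_along(leaf_groups)) {
        if (x < y) {
          D[leaf_groups[[x]], leaf_groups[[y]]] <<- depth
          D[leaf_groups[[y]], leaf_groups[[x]]] <<- depth
        }
      }
      for (ch in node) assign_depth(ch, depth + 1)
    }
    assign_depth(nested, 1)
    list(L = ids,
         bipkeys = names(bipartitions_of(tr, taxa)),
         nbip = length(bipartitions_of(tr, taxa)),
         D = D,
         qcache = new.env(parent = emptyenv()))
  })
  structure(list(taxa = taxa, trees = trees, k = length(trees), info = info),
            class = "source_tree_set")
}

#' @export
print.source_tree_set <- function(x, ...) {
  cat("source_tree_set: k =", x$k, "trees on up to", n_taxa(x$taxa), "taxa\n")
  invisible(x)
}

# induced quartet "partner of the smallest member" for a sorted 4-subset,
# from a meet-depth matrix; 0 when unresolved.  Four-point condition: the
# pairing whose within-pair meets are strictly deepest is the topology.
quartet_partner <- function(D, q) {
  s1 <- D[q[1L], q[2L]] + D[q[3L], q[4L]]
  s2 <- D[q[1L], q[3L]] + D[q[2L], q[4L]]
  s3 <- D[q[1L], q[4L]] + D[q[2L], q[3L]]
  if (s1 > s2 && s1 > s3) return(q[2L])
  if (s2 > s1 && s2 > s3) return(q[3L])
  if (s3 > s1 && s3 > s2) return(q[4L])
  0L
}

gene_partner <- function(gi, q) {
  key <- paste(q, collapse = " ")
  p <- gi$qcache[[key]]
  if (is.null(p)) {
    p <- quartet_partner(gi$D, q)
    gi$qcache[[key]] <- p
  }
  p
}

# does the gene resolve {i,j,k,l} as ij|kl ?
gene_has_quartet <- function(gi, i, j, k, l) {
  q <- sort(c(i, j, k, l))
  p <- gene_partner(gi, q)
  if (p == 0L) return(FALSE)
  mate <- if (q[1L] == i) j else if (q[1L] == j) i else if (q[1L] == k) l else k
  p == mate
}

check_complete_binary <- function(phy, taxa) {
  n <- n_taxa(taxa)
  if (length(phy$tip.label) != n) stop("tree is not complete on the taxon set")
  u <- ape::unroot(phy)
  if (length(bipartitions_of(u, taxa)) != n - 3L) stop("tree is not binary")
  invisible(TRUE)
}

# ---- quartet criterion ------------------------------------------------------

#' Shared-quartet score of a complete binary tree (direct computation)
#'
#' F(T) = over all gene trees g, the number of 4-subsets of g's leaves on
#' which T and g induce the same unrooted quartet topology.  Unresolved gene
#' quartets contribute 0.  Computed by an exhaustive 4-subset scan; this is
#' the oracle path, independent of the tripartition decomposition.
#'
#' @param phy a complete binary `phylo` on the taxon set.
#' @param genes a `source_tree_set`.
#' @return integer score.
#' @export
quartet_tree_score <- function(phy, genes) {
  stopifnot(inherits(genes, "source_tree_set"))
  taxa <- genes$taxa
  check_complete_binary(phy, taxa)
  n <- n_taxa(taxa)
  nested <- phylo_to_nested(ape::unroot(phy), taxa)
  DT <- matrix(NA_real_, n, n)
  assign_depth <- function(node, depth) {
    if (!is.list(node)) return(invisible(NULL))
    lg <- lapply(node, nested_leaves)
    for (x in seq_along(lg)) for (y in seq_along(lg)) {
      if (x < y) {
        DT[lg[[x]], lg[[y]]] <<- depth
        DT[lg[[y]], lg[[x]]] <<- depth
      }
    }
    for (ch in node) assign_depth(ch, depth + 1)
  }
  assign_depth(nested, 1)

  total <- 0
  for (gi in genes$info) {
    if (length(gi$L) < 4L) next
    qs <- utils::combn(gi$L, 4L)
    for (col in seq_len(ncol(qs))) {
      q <- qs[, col]
      pg <- gene_partner(gi, q)
      if (pg == 0L) next
      if (pg == quartet_partner(DT, q)) total <- total + 1
    }
  }
  total
}

quartet_weight_raw <- function(A, B, C, genes) {
  total <- 0
  for (gi in genes$info) {
    a <- intersect(A, gi$L); b <- intersect(B, gi$L); cc <- intersect(C, gi$L)
    la <- length(a); lb <- length(b); lc <- length(cc)
    if (la >= 2L && lb >= 2L) {
      pa <- utils::combn(a, 2L); pb <- utils::combn(b, 2L)
      for (x in seq_len(ncol(pa))) for (y in seq_len(ncol(pb))) {
        if (gene_has_quartet(gi, pa[1L, x], pa[2L, x], pb[1L, y], pb[2L, y])) total <- total + 1
      }
    }
    if (la >= 2L && lb >= 1L && lc >= 1L) {
      pa <- utils::combn(a, 2L)
      for (x in seq_len(ncol(pa))) for (k in b) for (l in cc) {
        if (gene_has_quartet(gi, pa[1L, x], pa[2L, x], k, l)) total <- total + 1
      }
    }
    if (lb >= 2L && la >= 1L && lc >= 1L) {
      pb <- utils::combn(b, 2L)
      for (x in seq_len(ncol(pb))) for (k in a) for (l in cc) {
        if (gene_has_quartet(gi, pb[1L, x], pb[2L, x], k, l)) total <- total + 1
      }
    }
  }
  total
}

# ---- RF supertree criterion -------------------------------------------------

#' Shared-bipartition score of a complete binary tree (direct computation)
#'
#' SharedBip(T) = over all source trees t_i with leaf set L_i, the number of
#' non-trivial bipartitions shared between T restricted to L_i and t_i.
#' Maximizing SharedBip is equivalent to minimizing the total Robinson-Foulds
#' distance to the source trees over their own leaf sets.  Computed via
#' explicit restriction; this is the oracle path.
#'
#' @param phy a complete binary `phylo` on the taxon set.
#' @param sources a `source_tree_set`.
#' @return integer score.
#' @export
rfs_tree_score <- function(phy, sources) {
  stopifnot(inherits(sources, "source_tree_set"))
  taxa <- sources$taxa
  check_complete_binary(phy, taxa)
  total <- 0
  for (gi in sources$info) {
    rt <- restrict_tree(phy, gi$L, taxa)
    total <- total + length(intersect(names(bipartitions_of(rt, taxa)), gi$bipkeys))
  }
  total
}

#' Total Robinson-Foulds distance to the source trees
#'
#' Sum over source trees of the RF distance between the source tree and the
#' candidate tree restricted to the source tree's leaf set.
#'
#' @inheritParams rfs_tree_score
#' @return integer total RF distance.
#' @export
rfs_total_rf <- function(phy, sources) {
  stopifnot(inherits(sources, "source_tree_set"))
  taxa <- sources$taxa
  check_complete_binary(phy, taxa)
  total <- 0
  for (gi in sources$info) {
    rt <- restrict_tree(phy, gi$L, taxa)
    rb <- names(bipartitions_of(rt, taxa))
    shared <- length(intersect(rb, gi$bipkeys))
    total <- total + gi$nbip + length(rb) - 2 * shared
  }
  total
}

rfs_weight_raw <- function(A, B, C, sources) {
  total <- 0
  for (gi in sources$info) {
    L <- gi$L
    sa <- intersect(A, L); sb <- intersect(B, L)
    if (length(sa) >= 1L && length(sb) >= 1L) {
      s <- c(sa, sb)
      if (length(L) - length(s) >= 2L) {
        b <- make_bip(s, L)
        if (!is.null(b) && b$key %in% gi$bipkeys) total <- total + 1
      }
    }
    if (length(intersect(C, L)) == 0L && length(sa) >= 2L && length(sb) >= 2L) {
      b <- make_bip(sa, L)
      if (!is.null(b) && b$key %in% gi$bipkeys) total <- total - 1
    }
  }
  total
}

# ---- scorer objects ---------------------------------------------------------

new_scorer <- function(name, data, weight_raw, tree_score_fn, direction = "max") {
  cache <- new.env(parent = emptyenv())
  cache$hits <- 0L
  cache$misses <- 0L
  sc <- list(
    name = name,
    direction = direction,
    taxa = data$taxa,
    data = data,
    cache = cache,
    weight = function(A, B, C) {
      if (clade_lt(B, A)) { tmp <- A; A <- B; B <- tmp }
      key <- paste0(ckey(A), "|", ckey(B))
      w <- cache[[key]]
      if (is.null(w)) {
        w <- weight_raw(A, B, C, data)
        cache[[key]] <- w
        cache$misses <- cache$misses + 1L
      } else {
        cache$hits <- cache$hits + 1L
      }
      w
    },
    tree_score = function(phy) tree_score_fn(phy, data)
  )
  structure(sc, class = "tripartition_scorer")
}

#' Scorer for the shared-quartet criterion
#'
#' @param genes a `source_tree_set` of gene trees.
#' @return a `tripartition_scorer` maximizing the shared-quartet count.
#' @export
quartet_scorer <- function(genes) {
  stopifnot(inherits(genes, "source_tree_set"))
  new_scorer("quartet", genes, quartet_weight_raw, quartet_tree_score)
}

#' Scorer for the Robinson-Foulds supertree criterion
#'
#' @param sources a `source_tree_set` of source trees.
#' @return a `tripartition_scorer` maximizing the shared-bipartition count
#'   (equivalently minimizing total RF distance).
#' @export
rfs_scorer <- function(sources) {
  stopifnot(inherits(sources, "source_tree_set"))
  new_scorer("rfs", sources, rfs_weight_raw, rfs_tree_score)
}

#' @export
print.tripartition_scorer <- function(x, ...) {
  cat("tripartition_scorer:", x$name, "(", x$direction, "),",
      x$cache$misses, "cached weights\n")
  invisible(x)
}

#' Tripartition weight under a scorer
#'
#' The weight w((A,B,C)); symmetric in A and B, cached per canonical
#' tripartition.
#'
#' @param scorer a `tripartition_scorer`.
#' @param A,B non-empty disjoint clades (taxon-index vectors).
#' @param C the remaining taxa (possibly empty).
#' @return integer weight.
#' @export
tripartition_weight <- function(scorer, A, B, C) scorer$weight(A, B, C)

#' Direct criterion score of a tree
#' @param scorer a `tripartition_scorer`.
#' @param phy a complete binary `phylo`.
#' @return integer score.
#' @export
score_tree <- function(scorer, phy) scorer$tree_score(phy)

#' Criterion score via the tripartition decomposition
#'
#' Sums w over the tripartitions of one rooting; by the decomposition
#' contract this equals [score_tree()] for every rooting.
#'
#' @param scorer a `tripartition_scorer`.
#' @param phy a rooted binary `phylo`, complete on the scorer's taxa.
#' @return integer score.
#' @export
rooted_score_sum <- function(scorer, phy) {
  trips <- tripartitions_of(phy, scorer$taxa)
  sum(vapply(trips, function(t) scorer$weight(t$A, t$B, t$C), numeric(1)))
}
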