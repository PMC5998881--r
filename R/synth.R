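# Brute-force oracles and seeded synthetic fixtures.
#
# The oracle path never touches the tripartition weights or the DP: feasible
# trees are enumerated exhaustively and scored with the direct whole-tree
# scorers, keeping the two computation routes fully independent.

# enumerate all rooted binary trees (nested form) on a set of taxon ids
rooted_trees_nested <- function(ids) {
  if (length(ids) == 1L) return(list(ids[1L]))
  x <- ids[length(ids)]
  base <- rooted_trees_nested(ids[-length(ids)])
  out <- list()
  for (t in base) {
    for (v in insert_leaf_everywhere(t, x)) out[[length(out) + 1L]] <- v
  }
  out
}

# all ways of attaching leaf x above any node of nested tree t
insert_leaf_everywhere <- function(t, x) {
  out <- list(sort_kids(list(t, x)))
  if (is.list(t)) {
    for (i in seq_along(t)) {
      for (v in insert_leaf_everywhere(t[[i]], x)) {
        t2 <- t
        t2[[i]] <- v
        out[[length(out) + 1L]] <- sort_kids(t2)
      }
    }
  }
  out
}

sort_kids <- function(kids) kids[order(vapply(kids, nested_min, numeric(1)))]

#' All unrooted binary tree topologies on a taxon set
#'
#' Exactly (2n - 5)!! trees, each yielded once.  Unrooted trees on S
#' correspond one-to-one to rooted binary trees on S minus its first taxon,
#' with that taxon re-attached at the root.
#'
#' @param taxa a `taxon_index` with 4 to 10 taxa.
#' @return a list of unrooted `phylo` objects.
#' @export
all_unrooted_binary_trees <- function(taxa) {
  n <- n_taxa(taxa)
  if (n < 4L || n > 10L) stop("n must be between 4 and 10")
  subs <- rooted_trees_nested(2:n)
  lapply(subs, function(sub) {
    nested <- c(list(1L), sub)   # trifurcation at the first taxon's neighbor
    nested_to_phylo(sort_kids(nested), taxa)
  })
}

#' Brute-force optimal feasible trees (oracle)
#'
#' Enumerates every unrooted binary topology, keeps those whose bipartitions
#' are all allowed, scores each with the criterion's direct whole-tree scorer
#' (never the tripartition weights), and returns the optimum and the full
#' optimal set.
#'
#' @param cs a `constraint_set` on at most 8 taxa.
#' @param scorer a `tripartition_scorer`.
#' @return a list with `score` (the optimal direct score, or `-Inf` if no
#'   feasible tree exists), `trees` (the optimal unrooted `phylo` objects),
#'   `n_feasible`, and `feasible_scores` (named by canonical form).
#' @export
brute_force_optima <- function(cs, scorer) {
  stopifnot(inherits(cs, "constraint_set"), inherits(scorer, "tripartition_scorer"))
  taxa <- cs$taxa
  n <- n_taxa(taxa)
  if (n > 8L) stop("brute force is limited to n <= 8")
  xkeys <- names(cs$X)
  sgn <- if (scorer$direction == "max") 1 else -1
  best <- -Inf
  best_trees <- list()
  scores <- numeric(0)
  n_feasible <- 0L
  for (phy in all_unrooted_binary_trees(taxa)) {
    bips <- names(bipartitions_of(phy, taxa))
    if (!all(bips %in% xkeys)) next
    n_feasible <- n_feasible + 1L
    val <- sgn * scorer$tree_score(phy)
    scores[[canonical_form(phy, taxa)]] <- sgn * val
    if (val > best) {
      best <- val
      best_trees <- list(phy)
    } else if (val == best) {
      best_trees[[length(best_trees) + 1L]] <- phy
    }
  }
  list(score = sgn * best, trees = best_trees, n_feasible = n_feasible,
       feasible_scores = scores)
}

# ---- random trees and perturbations -----------------------------------------

#' Random unrooted binary topology, uniform over labeled topologies
#'
#' Built by attaching taxa one at a time to a uniformly chosen edge; with the
#' insertion order fixed this induces the uniform distribution over the
#' (2n - 5)!! labeled topologies.  Uses the current RNG state.
#'
#' @param taxa a `taxon_index` (n >= 4).
#' @return an unrooted `phylo`.
#' @export
random_topology <- function(taxa) {
  n <- n_taxa(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  # rooted binary tree on taxa 2..n by random insertion, then attach taxon 1
  t <- 2L
  for (x in 3:n) {
    positions <- nested_positions(t)
    pick <- positions[[sample.int(length(positions), 1L)]]
    t <- nested_insert_at(t, pick, x)
  }
  nested_to_phylo(sort_kids(c(list(1L), t)), taxa)
}

# list of node addresses (integer vectors; empty = root) in a nested tree
nested_positions <- function(t, prefix = integer(0)) {
  out <- list(prefix)
  if (is.list(t)) {
    for (i in seq_along(t)) {
      out <- c(out, nested_positions(t[[i]], c(prefix, i)))
    }
  }
  out
}

nested_insert_at <- function(t, addr, x) {
  if (length(addr) == 0L) return(sort_kids(list(t, x)))
  t[[addr[1L]]] <- nested_insert_at(t[[addr[1L]]], addr[-1L], x)
  sort_kids(t)
}

#' Random nearest-neighbor-interchange perturbation
#'
#' Applies `moves` NNI moves, each picking one of the tree's NNI neighbors
#' uniformly (equivalently: an internal edge uniformly and one of its two
#' swaps uniformly).  Uses the current RNG state.
#'
#' @param phy an unrooted binary `phylo` with at least 4 tips.
#' @param moves number of moves.
#' @return a perturbed unrooted `phylo`.
#' @export
nni_perturb <- function(phy, moves = 1L) {
  if (moves <= 0L) return(phy)
  if (!requireNamespace("phangorn", quietly = TRUE)) {
    stop("nni_perturb requires the phangorn package")
  }
  for (i in seq_len(moves)) {
    nbrs <- phangorn::nni(phy)
    phy <- nbrs[[sample.int(length(nbrs), 1L)]]
  }
  phy
}

#' Generate a seeded synthetic test instance
#'
#' Emulates the structure of a supertree/phylogenomic input: a model tree,
#' source trees obtained from it by leaf subsampling and NNI perturbation,
#' and a set of complete constraint trees (the model tree plus perturbed
#' copies) whose conflicts create ties.  Fully determined by `seed`.
#'
#' @param n number of taxa (>= 4); labels are t1..tn.
#' @param k number of source trees.
#' @param retention fraction of taxa kept in each source tree (each keeps at
#'   least 4).
#' @param nni number of NNI moves applied to each source tree.
#' @param seed integer seed.
#' @param n_extra_constraints number of perturbed complete trees added to the
#'   constraint set beside the model tree.
#' @param constraint_nni NNI moves applied to each extra constraint tree.
#' @return a list with `taxa`, `model` (unrooted binary `phylo`), `sources`
#'   (list of `phylo`), `constraints` (list of complete `phylo`).
#' @export
generate_fixture <- function(n, k = 5L, retention = 0.8, nni = 1L, seed = 1L,
                             n_extra_constraints = 2L, constraint_nni = 1L) {
  stopifnot(n >= 4L, k >= 1L, retention > 0, retention <= 1)
  if (ceiling(retention * n) < 4L && retention < 1) {
    stop("retention too low: source trees would have fewer than 4 leaves")
  }
  set.seed(seed)
  taxa <- taxon_index(paste0("t", seq_len(n)))
  model <- random_topology(taxa)
  sources <- lapply(seq_len(k), function(i) {
    m <- max(4L, round(retention * n))
    keep <- sort(sample.int(n, m))
    st <- restrict_tree(model, keep, taxa)
    nni_perturb(st, nni)
  })
  constraints <- c(list(model), lapply(seq_len(n_extra_constraints), function(i) {
    nni_perturb(model, constraint_nni)
  }))
  list(taxa = taxa, model = model, sources = sources, constraints = constraints)
}

#' Write a fixture to newick files
#'
#' Writes `model.nwk`, `sources.nwk`, `constraints.nwk` under `dir`, each with
#' one deterministic newick string per line.
#'
#' @param fixture a fixture from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  taxa <- fixture$taxa
  writeLines(write_newick(fixture$model, taxa), file.path(dir, "model.nwk"))
  writeLines(vapply(fixture$sources, write_newick, "", taxa = taxa),
             file.path(dir, "sources.nwk"))
  writeLines(vapply(fixture$constraints, write_newick, "", taxa = taxa),
             file.path(dir, "constraints.nwk"))
  invisible(dir)
}
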