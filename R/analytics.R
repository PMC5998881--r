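# Everything the solution DAG enables: exact counting, exact bipartition
# frequencies, enumeration, uniform sampling, consensus trees, corrected
# branch support, a greedy MCC tree, and topological error metrics.
#
# Counts are arbitrary-precision integers and frequencies are exact rationals
# throughout; decimals appear only at serialization.  All consensus
# thresholds are compared by exact cross-multiplication.

# memoized number of optimal rooted binary subtrees on a clade
dag_optsub <- function(dag, key) {
  v <- dag$optsub[[key]]
  if (!is.null(v)) return(v)
  cl <- dag$clades[[key]]
  if (length(cl) == 1L) {
    v <- bigcount(1)
  } else {
    v <- bigcount(0)
    for (p in dag$splits[[key]]) {
      v <- big_add(v, big_mul(dag_optsub(dag, p$a), dag_optsub(dag, p$b)))
    }
  }
  dag$optsub[[key]] <- v
  v
}

#' Count the optimal rooted trees represented by the DAG
#'
#' The number of distinct optimal rooted binary trees drawing all clades from
#' the allowed set, as an exact arbitrary-precision integer.
#'
#' @param dag a `solution_dag`.
#' @return a `bigcount`.
#' @export
count_rooted_optima <- function(dag) {
  stopifnot(inherits(dag, "solution_dag"))
  dag_optsub(dag, dag$root_key)
}

#' Count the optimal unrooted trees
#'
#' Both built-in criteria are rooting-invariant, so every unrooted optimum has
#' exactly 2n - 3 rooted representatives in the DAG; the rooted count divided
#' by 2n - 3 is therefore exact.  Non-divisibility indicates a scorer that
#' violates rooting invariance and raises an internal-consistency error.
#'
#' @param dag a `solution_dag`.
#' @return a `bigcount`.
#' @export
count_unrooted_optima <- function(dag) {
  rooted <- count_rooted_optima(dag)
  qd <- big_divmod(rooted, bigcount(2 * dag$n - 3))
  if (!big_is_zero(qd$r)) {
    stop("internal consistency error: rooted optimum count ", as.character(rooted),
         " is not divisible by 2n-3 = ", 2 * dag$n - 3,
         "; the scorer is not rooting-invariant")
  }
  qd$q
}

# exact support map over unrooted optima: for every non-trivial bipartition
# present in at least one optimal tree, entries side / label / key / rat /
# rooted_rat.  A bipartition appears in an optimum iff the corresponding
# root split attains f(S), and the number of unrooted optima containing it is
# optsubtrees(side) * optsubtrees(complement).
dag_support_map <- function(dag) {
  S <- seq_len(dag$n)
  U <- count_unrooted_optima(dag)
  R <- count_rooted_optima(dag)
  out <- list()
  for (p in dag$splits[[dag$root_key]]) {
    a <- dag$clades[[p$a]]; b <- dag$clades[[p$b]]
    if (length(a) < 2L || length(b) < 2L) next   # trivial bipartition
    bp <- make_bip(a, S)
    num <- big_mul(dag_optsub(dag, p$a), dag_optsub(dag, p$b))
    out[[bp$key]] <- list(side = bp$side,
                          label = bip_label(bp$side, dag$taxa),
                          key = bp$key,
                          # tie-break key: the side containing the first taxon
                          tiekey = clade_sortkey(setdiff(S, bp$side)),
                          rat = rat(num, U),
                          rooted_rat = rat(num, R))
  }
  out
}

#' Exact bipartition frequencies over the optimal trees
#'
#' For every non-trivial bipartition present in at least one optimal unrooted
#' tree, the exact fraction of optimal unrooted trees containing it.
#' `rooted_fraction` is the companion fraction over rooted optima (the
#' fraction of rooted optima rooted on that edge), included for inspection.
#'
#' @param dag a `solution_dag`.
#' @return a data.frame with columns `bipartition` (comma-separated labels of
#'   the canonical side), `frequency` (numeric), `frequency_exact` (decimal
#'   string at 6 places), `numerator`, `denominator` (exact integer strings),
#'   and `rooted_fraction`.
#' @export
bipartition_frequencies <- function(dag) {
  sm <- dag_support_map(dag)
  ord <- order(vapply(sm, function(e) clade_sortkey(e$side), ""))
  sm <- sm[ord]
  data.frame(
    bipartition = vapply(sm, `[[`, "", "label"),
    frequency = vapply(sm, function(e) rat_to_double(e$rat), numeric(1)),
    frequency_exact = vapply(sm, function(e) rat_decimal(e$rat), character(1)),
    numerator = vapply(sm, function(e) as.character(e$rat$num), character(1)),
    denominator = vapply(sm, function(e) as.character(e$rat$den), character(1)),
    rooted_fraction = vapply(sm, function(e) rat_to_double(e$rooted_rat), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# ---- enumeration ------------------------------------------------------------

# all optimal rooted subtrees on a clade, as nested lists, up to `limit`
dag_enum_nested <- function(dag, key, limit = Inf) {
  cl <- dag$clades[[key]]
  if (length(cl) == 1L) return(list(cl))
  out <- list()
  for (p in dag$splits[[key]]) {
    las <- dag_enum_nested(dag, p$a, limit - length(out))
    for (la in las) {
      lbs <- dag_enum_nested(dag, p$b, limit - length(out))
      for (lb in lbs) {
        kids <- list(la, lb)
        out[[length(out) + 1L]] <- kids[order(vapply(kids, nested_min, numeric(1)))]
        if (length(out) >= limit) return(out)
      }
      if (length(out) >= limit) return(out)
    }
  }
  out
}

#' Enumerate the optimal unrooted trees
#'
#' Yields each distinct optimal unrooted tree exactly once, in a
#' deterministic order, by walking the DAG rooted on the pendant edge of the
#' first taxon (a rooting every unrooted tree has exactly once).
#'
#' @param dag a `solution_dag`.
#' @param limit optional maximum number of trees.
#' @return a list of unrooted `phylo` objects.
#' @export
enumerate_optimal_trees <- function(dag, limit = NULL) {
  stopifnot(inherits(dag, "solution_dag"))
  if (is.null(limit)) limit <- Inf
  S <- seq_len(dag$n)
  k1 <- ckey(1L)
  krest <- ckey(setdiff(S, 1L))
  pend <- Filter(function(p) p$a == k1 || p$b == k1, dag$splits[[dag$root_key]])
  if (length(pend) == 0L) {
    stop("internal consistency error: no optimal rooting on the first pendant edge")
  }
  subs <- dag_enum_nested(dag, krest, limit)
  lapply(subs, function(sub) ape::unroot(nested_to_phylo(list(1L, sub), dag$taxa)))
}

# ---- sampling ---------------------------------------------------------------

#' Draw a random optimal tree
#'
#' Uniform over optimal rooted trees -- at each clade a split is chosen with
#' probability proportional to the product of its two subtree counts -- and
#' then unrooted.  Since every unrooted optimum has exactly 2n - 3 rooted
#' representatives, the induced distribution over unrooted optima is uniform.
#'
#' @param dag a `solution_dag`.
#' @param seed optional integer seed for reproducibility.
#' @param reps number of draws.
#' @param as `"phylo"` (default) or `"newick"`; the latter returns canonical
#'   newick strings and is much faster for large numbers of draws.
#' @return an unrooted `phylo` (or canonical newick string), or a list/vector
#'   of them when `reps > 1`.
#' @export
sample_optimal_tree <- function(dag, seed = NULL, reps = 1L, as = c("phylo", "newick")) {
  as <- match.arg(as)
  stopifnot(inherits(dag, "solution_dag"))
  if (!is.null(seed)) set.seed(seed)
  draw <- function(key) {
    cl <- dag$clades[[key]]
    if (length(cl) == 1L) return(cl)
    ps <- dag$splits[[key]]
    if (length(ps) == 1L) {
      p <- ps[[1L]]
    } else {
      wts <- vapply(ps, function(p) {
        as.double(big_mul(dag_optsub(dag, p$a), dag_optsub(dag, p$b)))
      }, numeric(1))
      p <- ps[[sample.int(length(ps), 1L, prob = wts)]]
    }
    kids <- list(draw(p$a), draw(p$b))
    kids[order(vapply(kids, nested_min, numeric(1)))]
  }
  if (as == "newick") {
    res <- vapply(seq_len(reps), function(i) {
      nested_unrooted_canonical(draw(dag$root_key), dag$taxa)
    }, character(1))
    return(if (reps == 1L) res[[1L]] else res)
  }
  res <- lapply(seq_len(reps), function(i) {
    ape::unroot(nested_to_phylo(draw(dag$root_key), dag$taxa))
  })
  if (reps == 1L) res[[1L]] else res
}

# canonical unrooted newick of a rooted nested tree, without building a phylo
nested_unrooted_canonical <- function(nested, taxa) {
  leafset <- nested_leaves(nested)
  sides <- list()
  walk <- function(node, is_root) {
    if (!is.list(node)) return(invisible(NULL))
    if (!is_root) {
      b <- make_bip(nested_leaves(node), leafset)
      if (!is.null(b)) sides[[b$key]] <<- b$side
    }
    for (ch in node) walk(ch, FALSE)
  }
  walk(nested, TRUE)
  nested_newick(build_nested_from_clades(unname(sides), leafset), taxa)
}

# ---- consensus --------------------------------------------------------------

# exact descending sort of support-map entries by frequency, ties broken by
# canonical clade order
sort_support_desc <- function(entries) {
  m <- length(entries)
  if (m <= 1L) return(entries)
  keys <- vapply(entries, `[[`, "", "tiekey")
  idx <- seq_len(m)
  gt <- function(i, j) {
    cmp <- rat_cmp(entries[[i]]$rat, entries[[j]]$rat)
    if (cmp != 0L) cmp > 0L else keys[i] < keys[j]
  }
  for (i in seq_len(m - 1L)) {      # selection sort with the exact comparator
    best <- i
    for (j in (i + 1L):m) if (gt(idx[j], idx[best])) best <- j
    if (best != i) { tmp <- idx[i]; idx[i] <- idx[best]; idx[best] <- tmp }
  }
  entries[idx]
}

greedy_insert <- function(entries, leafset) {
  accepted <- list()
  for (e in entries) {
    ok <- all(vapply(accepted, function(a) compatible_sides(a, e$side, leafset), logical(1)))
    if (ok) accepted[[length(accepted) + 1L]] <- e$side
  }
  accepted
}

#' Consensus trees over the set of optimal trees
#'
#' * `strict`: bipartitions present in every optimal tree (frequency 1).
#' * `majority`: bipartitions with frequency > 1/2.
#' * `greedy`: all bipartitions in descending frequency, skipping any
#'   incompatible with those already placed (ties broken by canonical clade
#'   order).
#' * `alpha`: with `alpha >= 0.5`, exactly the bipartitions with frequency
#'   > alpha; with `alpha < 0.5`, greedy insertion restricted to frequency
#'   > alpha.
#'
#' All threshold comparisons are exact.
#'
#' @param dag a `solution_dag`.
#' @param kind one of `"strict"`, `"majority"`, `"greedy"`, `"alpha"`.
#' @param alpha threshold in `[0, 1)`, required for `kind = "alpha"`.
#' @return a `phylo`, with polytomies where unresolved.
#' @export
consensus_tree <- function(dag, kind = c("strict", "majority", "greedy", "alpha"),
                           alpha = NULL) {
  kind <- match.arg(kind)
  sm <- dag_support_map(dag)
  leafset <- seq_len(dag$n)
  half <- rat(1, 2)
  sides <- switch(kind,
    strict = lapply(Filter(function(e) rat_eq_one(e$rat), sm), `[[`, "side"),
    majority = lapply(Filter(function(e) rat_cmp(e$rat, half) > 0L, sm), `[[`, "side"),
    greedy = greedy_insert(sort_support_desc(sm), leafset),
    alpha = {
      if (is.null(alpha) || !is.numeric(alpha) || alpha < 0 || alpha >= 1) {
        stop("alpha must be supplied in [0, 1)")
      }
      thr <- rat_from_double(alpha)
      keep <- Filter(function(e) rat_cmp(e$rat, thr) > 0L, sm)
      if (alpha >= 0.5) {
        lapply(keep, `[[`, "side")
      } else {
        greedy_insert(sort_support_desc(keep), leafset)
      }
    })
  nested_to_phylo(build_nested_from_clades(unname(sides), leafset), dag$taxa)
}

# ---- corrected support and MCC ----------------------------------------------

#' Frequency-corrected branch support
#'
#' Each bipartition of `phy` gets the fraction of optimal trees that contain
#' it (zero if absent from all optima): an optimal tree lacking the
#' bipartition contributes zero support, so raw per-tree support values are
#' down-weighted by this fraction.  With `base_support` (a named numeric
#' vector of raw supports keyed by bipartition label), the corrected value is
#' `raw * frequency`; otherwise it is the frequency itself.
#'
#' @param phy a tree complete on the DAG's taxa.
#' @param dag a `solution_dag`.
#' @param base_support optional named numeric vector of raw supports; names
#'   are bipartition labels (comma-separated taxon labels of the canonical
#'   side).
#' @return a data.frame with columns `bipartition`, `frequency`,
#'   `frequency_exact`, `raw`, `corrected`.
#' @export
corrected_support <- function(phy, dag, base_support = NULL) {
  stopifnot(inherits(dag, "solution_dag"))
  if (length(phy$tip.label) != dag$n) stop("tree is not complete on the taxon set")
  sm <- dag_support_map(dag)
  bips <- bipartitions_of(phy, dag$taxa)
  rows <- lapply(bips, function(b) {
    e <- sm[[b$key]]
    freq <- if (is.null(e)) 0 else rat_to_double(e$rat)
    fex <- if (is.null(e)) "0.000000" else rat_decimal(e$rat)
    lab <- bip_label(b$side, dag$taxa)
    raw <- if (!is.null(base_support) && lab %in% names(base_support)) {
      as.numeric(base_support[[lab]])
    } else NA_real_
    corrected <- if (is.na(raw)) freq else raw * freq
    data.frame(bipartition = lab, frequency = freq, frequency_exact = fex,
               raw = raw, corrected = corrected, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(bipartition = character(0), frequency = numeric(0),
                      frequency_exact = character(0), raw = numeric(0),
                      corrected = numeric(0))
  }
  out[order(out$bipartition), , drop = FALSE]
}

#' Greedy maximum clade credibility tree
#'
#' Greedy consensus of all bipartitions occurring in any optimum, ranked by
#' corrected support (descending), annotated with those values as internal
#' node labels.  Without `base_support` the ranking is by frequency, so the
#' topology coincides with the greedy consensus.
#'
#' @param dag a `solution_dag`.
#' @param base_support optional named numeric vector of raw supports (see
#'   [corrected_support()]).
#' @return a `phylo` whose `node.label` carries the corrected support values.
#' @export
mcc_tree <- function(dag, base_support = NULL) {
  sm <- dag_support_map(dag)
  leafset <- seq_len(dag$n)
  if (is.null(base_support)) {
    entries <- sort_support_desc(sm)
    corrected <- vapply(entries, function(e) rat_to_double(e$rat), numeric(1))
  } else {
    corrected <- vapply(sm, function(e) {
      raw <- if (e$label %in% names(base_support)) as.numeric(base_support[[e$label]]) else 1
      raw * rat_to_double(e$rat)
    }, numeric(1))
    ord <- order(-corrected, vapply(sm, `[[`, "", "tiekey"))
    entries <- sm[ord]
    corrected <- corrected[ord]
  }
  names(corrected) <- vapply(entries, `[[`, "", "key")
  accepted <- greedy_insert(entries, leafset)
  nested <- build_nested_from_clades(accepted, leafset)
  smap <- vapply(accepted, function(s) {
    formatC(corrected[[paste0(ckey(s), "|", ckey(leafset))]], digits = 6, format = "f")
  }, "")
  names(smap) <- vapply(accepted, function(s) paste0(ckey(s), "|", ckey(leafset)), "")
  txt <- nested_newick(nested, dag$taxa, leafset = leafset, support = smap)
  ape::read.tree(text = txt)
}

# ---- error metrics ----------------------------------------------------------

#' Topological error of an estimated tree against a model tree
#'
#' FN = bipartitions of the (binary) model tree missing from the estimate,
#' FP = bipartitions of the estimate absent from the model, each divided by
#' n - 3 (the number of internal edges of an unrooted binary tree on n taxa).
#' Also reports their average and the F1 score (harmonic mean of precision
#' and recall of the estimated bipartitions).
#'
#' @param estimated a `phylo` (possibly unresolved).
#' @param model a binary `phylo` on the same leaf set.
#' @return a list of class `tree_error_report`: `fn`, `fp`, `average`, `f1`,
#'   plus the underlying counts.
#' @export
tree_error_rates <- function(estimated, model) {
  if (!setequal(estimated$tip.label, model$tip.label)) {
    stop("estimated and model trees have different leaf sets")
  }
  taxa <- taxon_index_from_trees(model)
  n <- n_taxa(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  cm <- names(bipartitions_of(ape::unroot(model), taxa))
  if (length(cm) != n - 3L) stop("model tree must be binary")
  ce <- names(bipartitions_of(ape::unroot(estimated), taxa))
  shared <- length(intersect(cm, ce))
  fn_count <- length(cm) - shared
  fp_count <- length(ce) - shared
  precision <- if (length(ce) == 0L) 0 else shared / length(ce)
  recall <- shared / length(cm)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(list(fn = fn_count / (n - 3), fp = fp_count / (n - 3),
                 average = (fn_count + fp_count) / (2 * (n - 3)), f1 = f1,
                 n = n, shared = shared, n_model = length(cm), n_estimated = length(ce)),
            class = "tree_error_report")
}

#' @export
print.tree_error_report <- function(x, ...) {
  cat(sprintf("tree error: FN = %.4f  FP = %.4f  avg = %.4f  F1 = %.4f  (n = %d)\n",
              x$fn, x$fp, x$average, x$f1, x$n))
  invisible(x)
}
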