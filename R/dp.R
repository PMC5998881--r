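# The constrained dynamic program and its all-optima solution DAG.
#
# f(c) is the optimal criterion score of a rooted binary subtree on clade c
# drawing all its clades from the allowed set; f is 0 on singletons and
# f(c) = opt over allowed splits {a,b} of c of f(a) + f(b) + w(a, b, S\c).
# Instead of one backpointer per clade, EVERY split attaining f(c) is kept,
# so the table doubles as a DAG whose source-to-sink trees are exactly the
# optimal rooted trees.  Ties are exact integer equality: both criteria are
# counts, so no tolerance is involved anywhere.

#' Run the constrained dynamic program, recording all optimal splits
#'
#' Processes allowed clades from smallest to largest.  `f(S)` is the optimal
#' criterion value over all complete binary trees whose bipartitions are
#' allowed; for each clade the set of all score-attaining splits is recorded.
#'
#' @param table a `tripartition_table` from [enumerate_splits()].
#' @param scorer a `tripartition_scorer` ([rfs_scorer()] or
#'   [quartet_scorer()]).
#' @return an object of class `solution_dag` with the per-clade optimal scores
#'   (`f`), the optimal split sets (`splits`), and lazily-filled
#'   arbitrary-precision subtree counts.
#' @export
run_dp <- function(table, scorer) {
  stopifnot(inherits(table, "tripartition_table"),
            inherits(scorer, "tripartition_scorer"))
  taxa <- table$taxa
  n <- n_taxa(taxa)
  S <- seq_len(n)
  clades <- table$clades
  keys <- names(clades)
  sizes <- vapply(clades, length, integer(1))
  ord <- keys[order(sizes, vapply(clades, clade_sortkey, ""))]

  sgn <- if (scorer$direction == "max") 1 else -1
  f <- new.env(parent = emptyenv())
  I <- new.env(parent = emptyenv())
  for (key in ord) {
    cl <- clades[[key]]
    if (length(cl) == 1L) {
      f[[key]] <- 0
      I[[key]] <- list()
      next
    }
    Crest <- setdiff(S, cl)
    best <- -Inf
    best_pairs <- list()
    for (p in table$splits[[key]]) {
      fa <- f[[p$a]]; fb <- f[[p$b]]
      if (is.null(fa) || is.null(fb) || !is.finite(fa) || !is.finite(fb)) next
      val <- fa + fb + sgn * scorer$weight(clades[[p$a]], clades[[p$b]], Crest)
      if (val > best) {
        best <- val
        best_pairs <- list(p)
      } else if (val == best) {
        best_pairs[[length(best_pairs) + 1L]] <- p
      }
    }
    f[[key]] <- best
    I[[key]] <- best_pairs
  }

  skey <- ckey(S)
  if (!is.finite(f[[skey]])) {
    witness <- skey
    for (key in ord) {
      if (length(clades[[key]]) > 1L && !is.finite(f[[key]])) { witness <- key; break }
    }
    stop("constraint set is infeasible: clade {",
         paste(unclass(taxa)[clades[[witness]]], collapse = ","),
         "} admits no allowed split into allowed clades")
  }

  structure(list(taxa = taxa, n = n, clades = clades, f = f, splits = I,
                 root_key = skey, criterion = scorer$name,
                 direction = scorer$direction, sgn = sgn,
                 optsub = new.env(parent = emptyenv())),
            class = "solution_dag")
}

#' Optimal criterion value of a solution DAG
#' @param dag a `solution_dag`.
#' @return the optimal score f(S) on the scorer's own scale.
#' @export
optimal_score <- function(dag) dag$sgn * dag$f[[dag$root_key]]

#' @export
print.solution_dag <- function(x, ...) {
  cat("solution_dag:", x$criterion, "criterion on", x$n, "taxa; f(S) =",
      optimal_score(x), "\n")
  cat("  clades:", length(x$clades),
      " optimal splits:", sum(vapply(ls(x$splits), function(k) length(x$splits[[k]]), integer(1))), "\n")
  invisible(x)
}

# deterministic descent: at each clade pick the canonically smallest optimal
# split; returns a nested rooted tree
dag_first_nested <- function(dag, key) {
  cl <- dag$clades[[key]]
  if (length(cl) == 1L) return(cl)
  p <- dag$splits[[key]][[1L]]
  kids <- list(dag_first_nested(dag, p$a), dag_first_nested(dag, p$b))
  kids[order(vapply(kids, nested_min, numeric(1)))]
}

#' Extract one optimal tree from the DAG
#'
#' Deterministic: at every clade the canonically smallest optimal split is
#' taken.  The result is the unrooted complete binary tree with score f(S).
#'
#' @param dag a `solution_dag`.
#' @return an unrooted `phylo`.
#' @export
extract_one_tree <- function(dag) {
  nested <- dag_first_nested(dag, dag$root_key)
  phy <- nested_to_phylo(nested, dag$taxa)
  ape::unroot(phy)
}
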