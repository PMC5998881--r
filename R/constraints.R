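# The allowed-bipartition set X and the table of allowed clade splits that
# the dynamic program runs over.

#' Build the allowed-bipartition constraint set
#'
#' X is the union of the non-trivial bipartitions of the supplied constraint
#' trees, which must all be complete on the taxon set (they are the outputs of
#' other supertree/species-tree methods).  The allowed clades are the two
#' halves of every bipartition in X, plus all singletons and the full set S.
#' At least one constraint tree should be binary: that tree is then itself a
#' feasible solution, guaranteeing the optimization is feasible.
#'
#' @param constraint_trees a `phylo` or list of `phylo`, each complete on the
#'   taxon set.
#' @param taxa optional `taxon_index`; defaults to first-appearance order over
#'   the constraint trees.
#' @param extra_bipartitions optional list of taxon-index vectors (or
#'   character vectors of labels), each one side of an extra allowed
#'   bipartition to add to X.
#' @return an object of class `constraint_set` with elements `taxa`, `X`
#'   (named list of bipartitions) and `clades` (named list of taxon-index
#'   vectors).
#' @export
build_constraint_set <- function(constraint_trees, taxa = NULL, extra_bipartitions = NULL) {
  if (inherits(constraint_trees, "phylo")) constraint_trees <- list(constraint_trees)
  if (length(constraint_trees) == 0L) stop("at least one constraint tree is required")
  if (is.null(taxa)) taxa <- taxon_index_from_trees(constraint_trees)
  n <- n_taxa(taxa)
  if (n < 4L) stop("need at least 4 taxa")
  S <- seq_len(n)

  X <- list()
  any_binary <- FALSE
  for (i in seq_along(constraint_trees)) {
    tr <- constraint_trees[[i]]
    ids <- taxon_id(taxa, tr$tip.label)
    if (length(ids) != n) {
      stop("constraint tree ", i, " is incomplete (", length(ids), " of ", n,
           " taxa); supply complete constraint trees")
    }
    bips <- bipartitions_of(ape::unroot(tr), taxa)
    if (length(bips) == n - 3L) any_binary <- TRUE
    for (b in bips) X[[b$key]] <- b
  }
  if (!is.null(extra_bipartitions)) {
    for (s in extra_bipartitions) {
      if (is.character(s)) s <- taxon_id(taxa, s)
      b <- make_bip(s, S)
      if (is.null(b)) next  # trivial bipartitions are always allowed
      X[[b$key]] <- b
    }
  }
  if (!any_binary) {
    warning("no binary constraint tree supplied; feasibility is not guaranteed")
  }

  clades <- list()
  for (b in X) {
    clades[[ckey(b$side)]] <- b$side
    comp <- setdiff(S, b$side)
    clades[[ckey(comp)]] <- comp
  }
  for (i in S) clades[[ckey(i)]] <- i
  clades[[ckey(S)]] <- S

  structure(list(taxa = taxa, X = X, clades = clades), class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("constraint_set: n =", n_taxa(x$taxa), " |X| =", length(x$X),
      " |clades| =", length(x$clades), "\n")
  invisible(x)
}

#' Enumerate the allowed splits of every allowed clade
#'
#' For every clade c with at least 2 taxa, lists all unordered pairs {a, b} of
#' allowed clades with a and b disjoint and a union b = c; together with
#' C = S minus c these are the allowed tripartitions the dynamic program
#' scores.  In addition to the constraint set's clades, the table includes the
#' complement of every singleton, so that each optimal unrooted tree is
#' representable rooted on any of its 2n - 3 edges (pendant edges included);
#' this is what makes the rooted-optima count an exact (2n - 3)-fold multiple
#' of the unrooted count.
#'
#' @param cs a `constraint_set`.
#' @return an object of class `tripartition_table` with elements `taxa`,
#'   `clades` (including rooting clades) and `splits` (named list mapping each
#'   clade key with >= 2 taxa to a list of pairs `list(a, b)` of clade keys,
#'   canonically ordered).
#' @export
enumerate_splits <- function(cs) {
  stopifnot(inherits(cs, "constraint_set"))
  n <- n_taxa(cs$taxa)
  S <- seq_len(n)
  clades <- cs$clades
  for (i in S) {  # rooting clades: complements of singletons
    comp <- setdiff(S, i)
    clades[[ckey(comp)]] <- comp
  }

  keys <- names(clades)
  sizes <- vapply(clades, length, integer(1))
  member <- lapply(clades, function(cl) {
    m <- logical(n); m[cl] <- TRUE; m
  })

  splits <- list()
  ord <- order(sizes, keys)
  for (ci in ord) {
    if (sizes[ci] < 2L) next
    c_members <- member[[ci]]
    c_size <- sizes[ci]
    pairs <- list()
    for (ai in seq_along(keys)) {
      if (sizes[ai] >= c_size) next
      if (any(member[[ai]] & !c_members)) next        # a must be subset of c
      bvec <- which(c_members & !member[[ai]])        # b = c \ a
      bkey <- ckey(bvec)
      if (is.null(clades[[bkey]])) next
      akey <- keys[ai]
      if (!clade_lt(clades[[akey]], bvec)) next       # keep each unordered pair once
      pairs[[length(pairs) + 1L]] <- list(a = akey, b = bkey)
    }
    if (length(pairs) > 1L) {
      o <- order(vapply(pairs, function(p) clade_sortkey(clades[[p$a]]), ""),
                 vapply(pairs, function(p) clade_sortkey(clades[[p$b]]), ""))
      pairs <- pairs[o]
    }
    splits[[keys[ci]]] <- pairs
  }
  structure(list(taxa = cs$taxa, clades = clades, splits = splits),
            class = "tripartition_table")
}

#' @export
print.tripartition_table <- function(x, ...) {
  cat("tripartition_table: n =", n_taxa(x$taxa), " clades =", length(x$clades),
      " splits =", sum(lengths(x$splits)), "\n")
  invisible(x)
}
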