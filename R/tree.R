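# Newick I/O and the clade / bipartition / tripartition calculus.
#
# Trees are ape "phylo" objects at the interface; internally most operations
# run on a nested-list form (leaf = taxon index, internal node = list of
# children ordered by smallest descendant taxon), which makes output
# deterministic and clade extraction trivial.  Branch lengths and input
# support labels are read and discarded: every criterion here is purely
# topological.

# ---- clade primitives -------------------------------------------------------

ckey <- function(ids) paste(sort(ids), collapse = " ")

# zero-padded key whose string order equals the canonical clade order
clade_sortkey <- function(ids) paste(sprintf("%05d", sort(ids)), collapse = " ")

# fixed total order on clades: elementwise on sorted indices, then length
clade_lt <- function(a, b) {
  a <- sort(a); b <- sort(b)
  m <- min(length(a), length(b))
  for (i in seq_len(m)) {
    if (a[i] != b[i]) return(a[i] < b[i])
  }
  length(a) < length(b)
}

# Canonical bipartition of `leafset` with one side `side`: the stored side is
# the one NOT containing the smallest taxon index present.  Returns NULL for
# trivial bipartitions (a side with < 2 taxa).
make_bip <- function(side, leafset) {
  side <- sort(side); leafset <- sort(leafset)
  canon <- if (leafset[1L] %in% side) setdiff(leafset, side) else side
  if (length(canon) < 2L || length(leafset) - length(canon) < 2L) return(NULL)
  list(side = canon, leafset = leafset,
       key = paste0(ckey(canon), "|", ckey(leafset)))
}

bip_label <- function(side, taxa) paste(sort(unclass(taxa)[sort(side)]), collapse = ",")

# ---- phylo <-> nested -------------------------------------------------------

phylo_to_nested <- function(phy, taxa) {
  ids <- taxon_id(taxa, phy$tip.label)
  ntip <- length(phy$tip.label)
  kids <- split(phy$edge[, 2L], phy$edge[, 1L])
  build <- function(node) {
    if (node <= ntip) return(ids[node])
    sub <- lapply(kids[[as.character(node)]], build)
    if (length(sub) == 1L) return(sub[[1L]])  # suppress unifurcation
    sub[order(vapply(sub, nested_min, numeric(1)))]
  }
  build(ntip + 1L)
}

nested_min <- function(node) if (!is.list(node)) node else min(vapply(node, nested_min, numeric(1)))

nested_leaves <- function(node) {
  if (!is.list(node)) return(node)
  sort(unlist(node, use.names = FALSE))
}

nested_is_binary <- function(node) {
  if (!is.list(node)) return(TRUE)
  length(node) == 2L && all(vapply(node, nested_is_binary, logical(1)))
}

nested_newick <- function(node, taxa, leafset = NULL, support = NULL, top = TRUE) {
  if (!is.list(node)) {
    s <- unclass(taxa)[node]
    return(if (top) paste0("(", s, ");") else s)
  }
  inner <- paste(vapply(node, nested_newick, "", taxa = taxa, leafset = leafset,
                        support = support, top = FALSE), collapse = ",")
  lab <- ""
  if (!top && !is.null(support)) {
    b <- make_bip(nested_leaves(node), leafset)
    if (!is.null(b) && b$key %in% names(support)) lab <- support[[b$key]]
  }
  if (top) paste0("(", inner, ");") else paste0("(", inner, ")", lab)
}

nested_to_phylo <- function(node, taxa) {
  phy <- ape::read.tree(text = nested_newick(node, taxa))
  phy
}

# ---- parsing ----------------------------------------------------------------

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("malformed newick: unbalanced ')' at offset ", i)
    }
  }
  if (depth != 0L) stop("malformed newick: ", depth, " unclosed '(' at end of string")
  if (!grepl(";", text, fixed = TRUE)) stop("malformed newick: missing ';' terminator")
  invisible(TRUE)
}

#' Parse a newick string into a tree
#'
#' Reads one tree in standard newick dialect (optional branch lengths and
#' internal-node labels are accepted and discarded; the criteria implemented
#' here are purely topological).  Unifurcations are suppressed.
#'
#' @param text a newick string (one tree).
#' @param taxa optional `taxon_index`; if supplied, every leaf label must be
#'   present in it.
#' @return an ape `phylo` object.
#' @examples
#' parse_newick("((a,b),(c,d));")
#' @export
parse_newick <- function(text, taxa = NULL) {
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(phy)) stop("malformed newick: ape could not parse the string")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop("expected a single tree, got ", length(phy))
    phy <- phy[[1L]]
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf label: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  if (!is.null(taxa)) taxon_id(taxa, phy$tip.label)  # errors on unknown labels
  phy$edge.length <- NULL
  phy$node.label <- NULL
  phy <- ape::collapse.singles(phy)
  phy
}

#' Read newick trees from a file (one tree per line)
#'
#' @param path path to a multi-newick file.
#' @param taxa optional `taxon_index` to validate leaf labels against.
#' @return a list of `phylo` objects.
#' @export
read_newick <- function(path, taxa = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("no trees found in ", path)
  lapply(seq_along(lines), function(i) {
    tryCatch(parse_newick(lines[i], taxa),
             error = function(e) stop(path, " line ", i, ": ", conditionMessage(e)))
  })
}

#' Write a tree as a deterministic newick string
#'
#' Children are ordered by the smallest taxon index in their subtree, so equal
#' topologies always serialize identically.  Optional per-bipartition support
#' values are written as internal node labels with 6 decimal places.
#'
#' @param phy a `phylo`.
#' @param taxa optional `taxon_index` (defaults to the tree's own tips in
#'   appearance order).
#' @param support optional named numeric vector; names are bipartition labels
#'   as produced by [bipartition_frequencies()] (comma-separated taxon labels
#'   of the canonical side).
#' @param file optional path; if given the string is also written there.
#' @return the newick string, invisibly if `file` is given.
#' @export
write_newick <- function(phy, taxa = NULL, support = NULL, file = NULL) {
  if (is.null(taxa)) taxa <- taxon_index_from_trees(phy)
  nested <- phylo_to_nested(phy, taxa)
  leafset <- nested_leaves(nested)
  smap <- NULL
  if (!is.null(support)) {
    bips <- bipartitions_of(phy, taxa)
    smap <- character(0)
    for (nm in names(support)) {
      ids <- taxon_id(taxa, strsplit(nm, ",", fixed = TRUE)[[1L]])
      b <- make_bip(ids, leafset)
      if (is.null(b) || !(b$key %in% names(bips))) {
        stop("support key is not a bipartition of the tree: ", nm)
      }
      smap[[b$key]] <- formatC(support[[nm]], digits = 6, format = "f")
    }
  }
  out <- nested_newick(nested, taxa, leafset = leafset, support = smap)
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

# ---- bipartitions and tripartitions ----------------------------------------

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge, computed on the tree's own leaf set
#' (so incomplete source trees yield bipartitions over their restricted leaf
#' set).  Trivial (singleton) bipartitions are excluded; for a rooted tree the
#' root edge contributes at most one bipartition.
#'
#' @param phy a `phylo`.
#' @param taxa a `taxon_index` covering the tree's tips.
#' @return a named list; each element has `side` (canonical taxon indices,
#'   the side not containing the smallest present index), `leafset`, and `key`.
#' @export
bipartitions_of <- function(phy, taxa) {
  nested <- phylo_to_nested(phy, taxa)
  leafset <- nested_leaves(nested)
  acc <- list()
  walk <- function(node, is_root) {
    if (!is.list(node)) return(invisible(NULL))
    if (!is_root) {
      b <- make_bip(nested_leaves(node), leafset)
      if (!is.null(b)) acc[[b$key]] <<- b
    }
    for (ch in node) walk(ch, FALSE)
  }
  walk(nested, TRUE)
  acc
}

#' Tripartitions of a rooted binary tree
#'
#' Each internal node v with child clades A and B defines the tripartition
#' (A, B, C) with C the remaining taxa; C is empty exactly at the root.
#' (A,B,C) and (B,A,C) are equivalent; the stored order has A before B under
#' the canonical clade order.
#'
#' @param phy a rooted binary `phylo`, complete on `taxa`.
#' @param taxa a `taxon_index`.
#' @return a list of `n - 1` tripartitions, each `list(A, B, C)` of sorted
#'   taxon indices.
#' @export
tripartitions_of <- function(phy, taxa) {
  nested <- phylo_to_nested(phy, taxa)
  S <- seq_len(n_taxa(taxa))
  if (!setequal(nested_leaves(nested), S)) stop("tree is not complete on the taxon set")
  if (!is.list(nested) || !nested_is_binary(nested)) stop("tree is not rooted binary")
  acc <- list()
  walk <- function(node) {
    if (!is.list(node)) return(invisible(NULL))
    A <- nested_leaves(node[[1L]])
    B <- nested_leaves(node[[2L]])
    if (clade_lt(B, A)) { tmp <- A; A <- B; B <- tmp }
    acc[[length(acc) + 1L]] <<- list(A = A, B = B, C = sort(setdiff(S, c(A, B))))
    for (ch in node) walk(ch)
  }
  walk(nested)
  acc
}

# ---- restriction, rooting ---------------------------------------------------

#' Restrict a tree to a subset of its leaves
#'
#' Induced subtree on the intersection of the tree's leaves with `leaves`,
#' with unifurcations suppressed.
#'
#' @param phy a `phylo`.
#' @param leaves taxon labels (character) or indices into `taxa`.
#' @param taxa a `taxon_index` (required when `leaves` is numeric).
#' @return a `phylo` on the intersection.
#' @export
restrict_tree <- function(phy, leaves, taxa = NULL) {
  labs <- if (is.character(leaves)) leaves else {
    if (is.null(taxa)) stop("taxa required when leaves are given as indices")
    unclass(taxa)[leaves]
  }
  keep <- intersect(phy$tip.label, labs)
  if (length(keep) == 0L) stop("restriction has empty intersection with the tree's leaves")
  if (length(keep) == length(phy$tip.label)) return(phy)
  if (length(keep) < 2L) stop("restriction to fewer than 2 leaves is not a tree")
  ape::keep.tip(phy, keep)
}

#' Remove the root of a tree
#' @param phy a `phylo`.
#' @return an unrooted `phylo` (degree-2 root suppressed).
#' @export
unroot_tree <- function(phy) ape::unroot(phy)

#' Root a tree on the edge defined by a bipartition
#'
#' Returns the rooted version whose two root children have leaf sets equal to
#' the two sides of the given bipartition.  A singleton side roots the tree on
#' that leaf's pendant edge.
#'
#' @param phy an unrooted (or rooted; it is unrooted first) `phylo`.
#' @param side taxon indices (or labels) of one side of the bipartition.
#' @param taxa a `taxon_index`.
#' @return a rooted `phylo`.
#' @export
root_at_edge <- function(phy, side, taxa) {
  if (is.character(side)) side <- taxon_id(taxa, side)
  u <- ape::unroot(phy)
  leafset <- sort(taxon_id(taxa, u$tip.label))
  side <- sort(side)
  comp <- setdiff(leafset, side)
  if (length(side) == 0L || length(comp) == 0L || !all(side %in% leafset)) {
    stop("side is not a proper non-empty subset of the tree's leaves")
  }
  if (length(side) >= 2L && length(comp) >= 2L) {
    b <- make_bip(side, leafset)
    if (!(b$key %in% names(bipartitions_of(u, taxa)))) {
      stop("bipartition is not an edge of the tree")
    }
  }
  og <- unclass(taxa)[if (length(side) <= length(comp)) side else comp]
  r <- ape::root(u, outgroup = og, resolve.root = TRUE)
  r
}

#' All rootings of an unrooted binary tree
#'
#' One rooting per edge (internal and pendant): 2n - 3 rooted trees for a
#' complete unrooted binary tree on n taxa.
#'
#' @param phy an unrooted binary `phylo`.
#' @param taxa a `taxon_index`.
#' @return a list of rooted `phylo` objects.
#' @export
all_rootings <- function(phy, taxa) {
  u <- ape::unroot(phy)
  leafset <- sort(taxon_id(taxa, u$tip.label))
  sides <- lapply(bipartitions_of(u, taxa), `[[`, "side")
  sides <- c(sides, as.list(leafset))   # pendant edges
  lapply(sides, function(s) root_at_edge(u, s, taxa))
}

# ---- canonical form ---------------------------------------------------------

# Deterministically assemble a nested tree from a set of pairwise-compatible
# clades (each excluding the smallest member of `leafset`).
build_nested_from_clades <- function(sides, leafset) {
  leafset <- sort(leafset)
  sides <- lapply(sides, sort)
  build <- function(members, clades) {
    if (length(members) == 1L) return(members)
    is_max <- vapply(seq_along(clades), function(i) {
      !any(vapply(seq_along(clades), function(j) {
        j != i && length(clades[[j]]) > length(clades[[i]]) && all(clades[[i]] %in% clades[[j]])
      }, logical(1)))
    }, logical(1))
    if (length(clades) == 0L) is_max <- logical(0)
    maximal <- clades[is_max]
    covered <- unlist(maximal, use.names = FALSE)
    children <- lapply(maximal, function(cl) {
      inner <- Filter(function(x) length(x) < length(cl) && all(x %in% cl), clades)
      build(cl, inner)
    })
    children <- c(children, as.list(setdiff(members, covered)))
    children[order(vapply(children, nested_min, numeric(1)))]
  }
  build(leafset, Filter(function(s) length(s) >= 2L, sides))
}

#' Canonical string form of an unrooted tree
#'
#' Two trees get the same string exactly when their unrooted topologies are
#' equal; used to deduplicate enumerated optima.
#'
#' @param phy a `phylo` (rootedness is ignored).
#' @param taxa a `taxon_index` covering the tree's tips.
#' @return a newick string.
#' @export
canonical_form <- function(phy, taxa) {
  bips <- bipartitions_of(ape::unroot(phy), taxa)
  leafset <- sort(taxon_id(taxa, phy$tip.label))
  nested <- build_nested_from_clades(lapply(bips, `[[`, "side"), leafset)
  nested_newick(nested, taxa)
}

#' Build a tree from a set of compatible bipartitions
#'
#' @param sides list of taxon-index vectors, one side per bipartition; they
#'   must be pairwise compatible.
#' @param taxa a `taxon_index`; the tree is built on all of it.
#' @return a `phylo`, with polytomies where the bipartitions leave the
#'   topology unresolved.
#' @export
tree_from_bipartitions <- function(sides, taxa) {
  leafset <- seq_len(n_taxa(taxa))
  canon <- lapply(sides, function(s) {
    b <- make_bip(s, leafset)
    if (is.null(b)) stop("trivial bipartition supplied")
    b$side
  })
  if (length(canon) >= 2L) {
    for (i in seq_along(canon)) for (j in seq_len(i - 1L)) {
      if (!compatible_sides(canon[[i]], canon[[j]], leafset)) {
        stop("bipartitions are not pairwise compatible")
      }
    }
  }
  keys <- vapply(canon, ckey, "")
  canon <- canon[!duplicated(keys)]
  nested_to_phylo(build_nested_from_clades(canon, leafset), taxa)
}

# two canonical sides (both excluding taxon min(leafset)) are compatible iff
# nested or disjoint
compatible_sides <- function(a, b, leafset) {
  inter <- length(intersect(a, b))
  inter == 0L || inter == length(a) || inter == length(b)
}
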