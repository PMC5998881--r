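#' Taxon index
#'
#' An ordered set of distinct taxon labels defining the global species set S.
#' Taxon i refers to `labels[i]`; all clade and bipartition machinery works on
#' these integer indices.
#'
#' @param labels character vector of distinct, non-empty labels.
#' @return an object of class `taxon_index` (a character vector).
#' @export
taxon_index <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stop("taxon_index needs at least one label")
  if (anyNA(labels) || any(!nzchar(labels))) stop("taxon labels must be non-empty")
  if (anyDuplicated(labels)) {
    stop("duplicate taxon labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  structure(labels, class = "taxon_index")
}

#' Number of taxa in a taxon index
#' @param taxa a `taxon_index`.
#' @return integer count.
#' @export
n_taxa <- function(taxa) length(unclass(taxa))

#' Map labels to taxon indices
#' @param taxa a `taxon_index`.
#' @param labels character vector of labels, all of which must be present.
#' @return integer vector of indices into `taxa`.
#' @export
taxon_id <- function(taxa, labels) {
  idx <- match(labels, unclass(taxa))
  if (anyNA(idx)) {
    stop("labels not in taxon index: ", paste(labels[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Build a taxon index from trees, in first-appearance order
#' @param trees a `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @return a `taxon_index` over the union of all tip labels.
#' @export
taxon_index_from_trees <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  labs <- unlist(lapply(trees, function(t) t$tip.label))
  taxon_index(unique(labs))
}

#' @export
print.taxon_index <- function(x, ...) {
  cat("taxon_index with", length(unclass(x)), "taxa:",
      paste(utils::head(unclass(x), 8), collapse = ", "),
      if (length(unclass(x)) > 8) "..." else "", "\n")
  invisible(x)
}
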