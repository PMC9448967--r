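#' Read a set of trees from a Newick file
#'
#' Reads one or more ';'-terminated Newick statements (one file may hold e.g.
#' a posterior sample of 100 dated trees) and verifies that all trees are
#' rooted, have finite nonnegative branch lengths, and share an identical tip
#' set.
#'
#' @param path Newick file, or a character vector of Newick strings via
#'   `text =` (see [ape::read.tree()]).
#' @param text optional Newick text instead of a file.
#' @return A `tree_set`: a `multiPhylo` list with a `provenance` attribute.
#' @export
read_tree_set <- function(path = NULL, text = NULL) {
  trees <- withCallingHandlers(
    tryCatch(
      if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
      error = function(e) stop("Newick parse error: ", conditionMessage(e))),
    warning = function(w) {
      # ape warns (and returns NULL) on unbalanced/unterminated statements
      stop("Newick parse error: ", conditionMessage(w))
    })
  if (is.null(trees)) stop("Newick parse error: no tree could be read")
  if (inherits(trees, "phylo")) trees <- structure(list(trees), class = "multiPhylo")
  as_tree_set(trees, provenance = if (is.null(text)) path else "text")
}

#' Assemble a tree set from phylo objects
#'
#' @param trees a `multiPhylo` object or list of `phylo` trees.
#' @param provenance free-text note on where the trees came from.
#' @return A validated `tree_set` object.
#' @export
as_tree_set <- function(trees, provenance = "unspecified") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, validate_phylogeny)
  tips <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), tips))
      stop("tree ", i, " has a different tip set from tree 1")
  structure(trees, class = c("tree_set", "multiPhylo"), provenance = provenance)
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("tree set: %d tree(s), %d tips (provenance: %s)\n",
              length(x), length(x[[1L]]$tip.label), attr(x, "provenance")))
  invisible(x)
}

#' Write a tree set as plain Newick
#'
#' @param trees a `tree_set` or `multiPhylo`.
#' @param path output file; one tree per line.
#' @return `path`, invisibly.
#' @export
write_tree_set <- function(trees, path) {
  ape::write.tree(structure(unclass(trees), class = "multiPhylo"), file = path)
  invisible(path)
}

validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and nonnegative")
  if (anyDuplicated(tree$tip.label))
    stop("duplicated tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  tree
}

#' Prune a phylogeny to a taxon subset
#'
#' Returns the induced subtree on `taxa`: path lengths between retained tips
#' are preserved exactly and unbranched internal nodes are suppressed. This
#' replaces re-downloading a reduced tree when species are dropped from an
#' analysis.
#'
#' @param tree a `phylo` object.
#' @param taxa character vector of tip labels to keep (at least 2).
#' @return The pruned `phylo`.
#' @export
prune_to_taxa <- function(tree, taxa) {
  validate_phylogeny(tree)
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  if (length(taxa) < 2L) stop("need at least 2 taxa to keep")
  ape::keep.tip(tree, taxa)
}

root_to_tip_depths <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  d[seq_along(tree$tip.label)]
}

#' Phylogenetic correlation matrix
#'
#' For an ultrametric tree the expected correlation of a neutrally evolving
#' trait between two tips equals their shared root-to-tip path length divided
#' by the tree depth. The matrix (unit diagonal, entries in \[0, 1\]) is the
#' covariance structure of the phylogenetic random effect in the binary mixed
#' model.
#'
#' Trees read from truncated Newick text are rarely exactly ultrametric; a
#' relative spread of root-to-tip depths up to `tol` is accepted and the
#' depths averaged.
#'
#' @param tree a rooted, (near-)ultrametric `phylo`.
#' @param tol relative tolerance on the root-to-tip depth spread.
#' @return Symmetric positive semi-definite matrix with species dimnames.
#' @export
phylo_correlation <- function(tree, tol = 1e-3) {
  validate_phylogeny(tree)
  depths <- root_to_tip_depths(tree)
  spread <- (max(depths) - min(depths)) / max(depths)
  if (spread > tol) {
    worst <- tree$tip.label[which.max(abs(depths - mean(depths)))]
    stop(sprintf("tree is not ultrametric (relative depth spread %.3g; worst tip '%s')",
                 spread, worst))
  }
  V <- ape::vcv(tree)
  C <- V / mean(depths)
  diag(C) <- 1
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("phylogenetic correlation matrix is not positive semi-definite")
  C
}
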