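# Tree handling: Newick I/O, tip surgery, phylogenetic covariance matrices.
# Parsing and core tree primitives are delegated to ape.

#' Parse a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]: accepts a Newick string
#' or a file path and requires branch lengths.
#'
#' @param text Newick string (use `file` for a path).
#' @param file path to a Newick file.
#' @return an `ape::phylo` tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  tr <- if (!is.null(file)) {
    if (!file.exists(file)) stop("tree file not found: ", file)
    ape::read.tree(file)
  } else {
    # ape warns and returns NULL on malformed text; we raise a proper error
    suppressWarnings(ape::read.tree(text = text))
  }
  if (is.null(tr)) stop("malformed Newick input")
  if (is.null(tr$edge.length)) stop("Newick input lacks branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch lengths")
  tr
}

#' Write a tree as Newick text
#'
#' @param tree an `ape::phylo` tree.
#' @param file optional output path; if omitted the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  if (is.null(file)) return(ape::write.tree(tree))
  ape::write.tree(tree, file = file)
  invisible(ape::write.tree(tree))
}

#' Substitute tip labels
#'
#' Relabels tips according to `mapping` (names = old labels, values = new),
#' e.g. to stand a sampled species in for an unsampled sister taxon while
#' keeping topology and branch lengths identical.
#'
#' @param tree an `ape::phylo` tree.
#' @param mapping named character vector old -> new.
#' @return the relabeled tree.
#' @export
substitute_tips <- function(tree, mapping) {
  unknown <- setdiff(names(mapping), tree$tip.label)
  if (length(unknown) > 0) {
    stop("tip(s) not in tree: ", paste(unknown, collapse = ", "))
  }
  idx <- match(names(mapping), tree$tip.label)
  tree$tip.label[idx] <- unname(mapping)
  if (anyDuplicated(tree$tip.label)) stop("substitution created duplicate tip labels")
  tree
}

#' Graft a new tip next to an existing one
#'
#' Attaches `new_tip` as sister of `sister`, diverging `divergence_time`
#' before the present (i.e. at that distance above the sister tip on its
#' terminal branch). On an ultrametric tree the graft preserves
#' ultrametricity: the new tip's root-to-tip distance equals the sister's.
#'
#' @param tree an `ape::phylo` tree.
#' @param new_tip label of the tip to add.
#' @param sister existing tip label.
#' @param divergence_time positive, at most the sister's terminal branch
#'   length.
#' @return the enlarged tree.
#' @export
graft_tip <- function(tree, new_tip, sister, divergence_time) {
  s <- match(sister, tree$tip.label)
  if (is.na(s)) stop("sister tip not in tree: ", sister)
  term_edge <- which(tree$edge[, 2] == s)
  tb <- tree$edge.length[term_edge]
  if (divergence_time <= 0 || divergence_time > tb) {
    stop("infeasible divergence time ", divergence_time,
         ": sister's terminal branch is ", tb)
  }
  scion <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                          tip.label = new_tip,
                          edge.length = divergence_time,
                          Nnode = 1L),
                     class = "phylo")
  ape::bind.tree(tree, scion, where = s, position = divergence_time)
}

#' Phylogenetic variance-covariance matrix
#'
#' C\[i, j\] is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip distances. Under Brownian motion the trait
#' covariance of a tip subset is the corresponding submatrix, so requesting
#' `tips` simply subsets (marginalizes) the full matrix in the given order.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param tips optional ordered subset of tip labels.
#' @return symmetric positive semi-definite matrix with tip-label dimnames.
#' @export
phylo_vcv <- function(tree, tips = NULL) {
  C <- ape::vcv(tree)
  if (is.null(tips)) return(C)
  missing_tips <- setdiff(tips, rownames(C))
  if (length(missing_tips) > 0) {
    stop("tip(s) not in tree: ", paste(missing_tips, collapse = ", "))
  }
  C[tips, tips, drop = FALSE]
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies all off-diagonal entries by `lambda`, leaving the diagonal
#' unchanged. lambda = 1 returns the matrix unchanged (Brownian motion);
#' lambda = 0 removes all phylogenetic covariance.
#'
#' @param C phylogenetic covariance matrix.
#' @param lambda value in \[0, 1\].
#' @return transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.finite(lambda) || lambda < 0 || lambda > 1) {
    stop("lambda must lie in [0, 1]")
  }
  V <- C * lambda
  diag(V) <- diag(C)
  V
}

#' Most recent common ancestor
#'
#' Node id of the MRCA of a set of tips; a single tip is its own MRCA.
#'
#' @param tree an `ape::phylo` tree.
#' @param tips character vector of tip labels (length >= 1).
#' @return integer node id (ape numbering: tips 1..n, root n+1).
#' @export
mrca_node <- function(tree, tips) {
  if (length(tips) == 0) stop("empty tip set")
  missing_tips <- setdiff(tips, tree$tip.label)
  if (length(missing_tips) > 0) {
    stop("tip(s) not in tree: ", paste(missing_tips, collapse = ", "))
  }
  if (length(unique(tips)) == 1) return(match(tips[1], tree$tip.label))
  ape::getMRCA(tree, tips)
}

# Relative departure from ultrametricity: max spread of root-to-tip depths.
.ultrametric_error <- function(tree) {
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  (max(d) - min(d)) / max(d)
}
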