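# Learning representations of a phylogeny: graph tensor, branching-time
# sequence, and Newick plumbing. Node numbering follows the ape convention
# (tips 1..n, root n+1, internal nodes n+2..2n-1), which is deterministic
# for a given tree, so encodings are reproducible.

assert_binary_tree <- function(tree, min_tips = 2L) {
  if (!inherits(tree, "phylo")) stop_data("expected a 'phylo' object")
  if (ape::Ntip(tree) < min_tips)
    stop_data("tree must have at least ", min_tips, " tips")
  tab <- tabulate(tree$edge[, 1L], nbins = ape::Ntip(tree) + tree$Nnode)
  bad <- which(tab != 0L & tab != 2L)
  if (length(bad))
    stop_data("tree is not fully bifurcating: node ", bad[1L], " has ",
              tab[bad[1L]], " children")
  if (is.null(tree$edge.length)) stop_data("tree has no branch lengths")
  invisible(tree)
}

#' Graph representation of a phylogeny
#'
#' Encodes a fully bifurcating tree as a directed graph: an edge index
#' (2 x m, parent over child, one column per branch, m = N - 1) and an
#' N x 3 node-feature matrix whose columns are the distance to the direct
#' ancestor and the distances to the two descendants. Distances to
#' non-existing neighbours are zero, so the root's first feature and the
#' tips' second and third features are 0. Branch lengths appear exactly once
#' as an ancestor-distance, so the feature matrix preserves the tree length.
#'
#' @param tree A fully bifurcating `phylo` with branch lengths and >= 3 tips.
#' @param targets Optional named numeric vector of generating parameters to
#'   carry along as the regression target.
#' @return An object of class `divnn_graph`: list with `edge_index`
#'   (2 x m integer, 1-based ape node numbers), `node_features` (N x 3),
#'   `targets`, `n_tips`.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "((t1:2,t2:2):1,(t3:1,(t4:0.5,t5:0.5):0.5):2);")
#' g <- phylo_to_graph(tr)
#' dim(g$edge_index)   # 2 x 8
#' nrow(g$node_features)  # 9
phylo_to_graph <- function(tree, targets = NULL) {
  assert_binary_tree(tree, min_tips = 3L)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  edge <- tree$edge
  feats <- matrix(0, nrow = N, ncol = 3L,
                  dimnames = list(NULL, c("to_ancestor", "to_child1", "to_child2")))
  feats[edge[, 2L], 1L] <- tree$edge.length
  # children in edge-matrix (cladewise) order: first seen = child 1
  first_seen <- !duplicated(edge[, 1L])
  feats[edge[first_seen, 1L], 2L] <- tree$edge.length[first_seen]
  feats[edge[!first_seen, 1L], 3L] <- tree$edge.length[!first_seen]
  if (!is.null(targets)) {
    if (is.null(names(targets)) || !is.numeric(targets))
      stop_config("targets must be a named numeric vector")
    targets <- unlist(targets)
  }
  structure(list(edge_index = t(edge), node_features = feats,
                 targets = targets, n_tips = n),
            class = "divnn_graph")
}

#' @export
print.divnn_graph <- function(x, ...) {
  cat(sprintf("<divnn_graph: %d nodes, %d edges%s>\n",
              nrow(x$node_features), ncol(x$edge_index),
              if (!is.null(x$targets))
                paste0(", targets [", paste(names(x$targets), collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Branching times of a reconstructed tree
#'
#' Ages of the internal nodes measured backwards from the present, ordered
#' from past to present (the crown age comes first), as consumed by the
#' recurrent network. The tree must be ultrametric: in a reconstructed tree
#' all extant tips end at the present.
#'
#' @param tree An ultrametric, fully bifurcating `phylo`.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Numeric vector of length `n_tips - 1`, sorted decreasing.
#' @export
branching_times <- function(tree, tol = 1e-6) {
  assert_binary_tree(tree, min_tips = 2L)
  if (!ape::is.ultrametric(tree, tol = tol))
    stop_data("tree is not ultrametric within tolerance ", tol,
              "; see prepare_empirical() for tip alignment")
  sort(unname(ape::branching.times(tree)), decreasing = TRUE)
}

#' Read a phylogeny from a Newick file
#'
#' Reads a single rooted, fully bifurcating tree with branch lengths;
#' polytomies and missing branch lengths are rejected with an informative
#' error. The crown age (maximum root-to-tip depth) is attached as an
#' attribute.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string, used instead of `path`.
#' @return A tree of class `c("divnn_tree", "phylo")`.
#' @export
read_newick <- function(path, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(file = path) else ape::read.tree(text = text)
  if (is.null(tr)) stop_data("could not parse Newick input")
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop_data("expected a single tree, found ", length(tr))
    tr <- tr[[1L]]
  }
  if (is.null(tr$edge.length)) stop_data("Newick tree has no branch lengths")
  assert_binary_tree(tr)   # polytomies (incl. unrooted basal trifurcations)
  if (!ape::is.rooted(tr)) stop_data("tree must be rooted")
  class(tr) <- c("divnn_tree", "phylo")
  attr(tr, "crown_age") <- max(ape::node.depth.edgelength(tr))
  attr(tr, "extant") <- setNames(rep(TRUE, ape::Ntip(tr)), tr$tip.label)
  tr
}

#' Write a phylogeny to a Newick file
#'
#' Branch lengths are written with 15 significant digits so that a
#' write/read round trip preserves them to numerical precision.
#'
#' @param tree A `phylo` object.
#' @param path Output file path; `""` returns the Newick string invisibly.
#' @return Invisibly, the Newick string.
#' @export
write_newick <- function(tree, path = "") {
  if (!inherits(tree, "phylo")) stop_data("expected a 'phylo' object")
  out <- ape::write.tree(tree, file = "", digits = 15L)
  if (nzchar(path)) writeLines(out, path)
  invisible(out)
}
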