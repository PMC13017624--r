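# Reconstructed-tree utilities: pruning extinct lineages, node-count
# filtering, and batch simulation with crown-survival retries.

#' Total node count of a tree
#'
#' Root + internal + tip nodes; for a fully bifurcating tree with `n` tips
#' this equals `2n - 1`.
#'
#' @param tree A `phylo` object.
#' @return Integer node count.
#' @export
n_nodes <- function(tree) {
  if (is_rejected(tree)) stop_data("cannot count nodes of a rejected tree")
  ape::Ntip(tree) + tree$Nnode
}

#' Prune extinct lineages from a complete tree
#'
#' Drops all tips flagged extinct, suppressing the degree-2 nodes this
#' creates (their branch lengths are summed), so that only lineages ancestral
#' to extant tips remain. The result is ultrametric with every root-to-tip
#' path equal to the crown age. Trees in which fewer than two tips survive,
#' or in which one of the two crown lineages left no extant descendant (so
#' the reconstructed crown would be younger than the simulated one), are
#' flagged rejected rather than raising an error.
#'
#' @param tree A complete tree from [sim_bd()], [sim_ddd()] or
#'   [sim_pbd()]`$complete` (tips carry `extant` flags). A tree without
#'   extinct tips is returned unchanged.
#' @return A reconstructed tree of class `c("divnn_tree", "phylo")`, or a
#'   rejection marker (see [is_rejected()]).
#' @export
prune_extinct <- function(tree) {
  if (is_rejected(tree)) return(tree)
  extant <- attr(tree, "extant")
  if (is.null(extant)) extant <- setNames(rep(TRUE, ape::Ntip(tree)), tree$tip.label)
  if (!any(extant)) return(rejected("all tips extinct"))
  if (sum(extant) == 1L) return(rejected("single extant tip"))
  surviving <- attr(tree, "surviving")
  if (!is.null(surviving) && !surviving) return(rejected("crown lineage extinct"))
  crown_age <- attr(tree, "crown_age")
  if (all(extant)) return(tree)
  pruned <- ape::keep.tip(tree, names(extant)[extant])
  class(pruned) <- c("divnn_tree", "phylo")
  if (!is.null(crown_age)) {
    depth <- max(ape::node.depth.edgelength(pruned))
    if (abs(depth - crown_age) > 1e-8 * max(1, crown_age))
      return(rejected("crown lineage extinct"))
    attr(pruned, "crown_age") <- crown_age
  }
  attr(pruned, "extant") <- setNames(rep(TRUE, ape::Ntip(pruned)), pruned$tip.label)
  sp <- attr(tree, "species")
  if (!is.null(sp)) attr(pruned, "species") <- sp[pruned$tip.label]
  pruned
}

#' Filter trees by total node count
#'
#' Retains exactly the trees with `node_min <= n_nodes <= node_max`
#' (defaults 5 and 3000): very small trees carry too little information for
#' encoding and summary statistics, and very large ones produce outsized
#' graph tensors.
#'
#' @param trees List of `phylo` objects (rejection markers count as removed
#'   below the minimum).
#' @param node_min,node_max Inclusive node-count bounds.
#' @return List with `trees` (kept trees), `kept` (logical index into the
#'   input), `n_below`, `n_above`.
#' @export
filter_trees <- function(trees, node_min = 5L, node_max = 3000L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  nn <- vapply(trees, function(tr) {
    if (is_rejected(tr)) return(0L)
    n_nodes(tr)
  }, integer(1L))
  below <- nn < node_min
  above <- nn > node_max
  keep <- !below & !above
  list(trees = trees[keep], kept = keep,
       n_below = sum(below), n_above = sum(above))
}

#' Simulate a batch of reconstructed trees
#'
#' Draws one parameter vector per requested tree from [sample_params()],
#' simulates a complete tree, and reduces it to a reconstructed tree
#' ([prune_extinct()] for BD/DDD; the species tree for PBD). Trees rejected
#' by the crown-survival condition are re-simulated with the *same*
#' parameter vector, so the output has exactly `n_trees` entries whose
#' parameters still follow the training distribution conditioned on
#' survival. Node-count filtering is a separate step ([filter_trees()]).
#'
#' @param config A [sim_config()] object (its `rng_seed`, when non-`NULL`,
#'   makes the whole batch reproducible).
#' @param params Optional data.frame of generating parameters (one row per
#'   tree, recycled if fewer than `n_trees` rows); defaults to fresh draws.
#' @param max_retries Retry cap per tree before giving up with an error.
#' @return List with `trees` (list of reconstructed trees), `params`
#'   (data.frame: `tree_id`, `scenario`, parameter columns, `n_tips`,
#'   `n_nodes`), and `n_rejected` (total survival rejections encountered).
#' @export
#' @examples
#' out <- sim_trees(sim_config("BD", n_trees = 3, rng_seed = 1))
#' out$params
sim_trees <- function(config, params = NULL, max_retries = 10000L) {
  stopifnot(inherits(config, "divnn_sim_config"))
  with_seed(config$rng_seed, {
    scn <- config$scenario
    if (is.null(params)) params <- sample_params(scn, config$n_trees)
    params <- params[rep_len(seq_len(nrow(params)), config$n_trees), , drop = FALSE]
    rownames(params) <- NULL
    trees <- vector("list", config$n_trees)
    n_rej <- 0L
    for (i in seq_len(config$n_trees)) {
      p <- as.list(params[i, , drop = FALSE])
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > max_retries)
          stop_data("no surviving tree after ", max_retries,
                    " attempts for parameter row ", i)
        recon <- switch(scn,
          BD  = prune_extinct(sim_bd(p, config$crown_age)),
          DDD = prune_extinct(sim_ddd(p, config$crown_age)),
          PBD = sim_pbd(p, config$crown_age)$species_tree)
        if (!is_rejected(recon)) break
        n_rej <- n_rej + 1L
      }
      trees[[i]] <- recon
    }
    tab <- cbind(data.frame(tree_id = seq_len(config$n_trees), scenario = scn),
                 params,
                 n_tips = vapply(trees, ape::Ntip, integer(1L)),
                 n_nodes = vapply(trees, n_nodes, integer(1L)))
    list(trees = trees, params = tab, n_rejected = n_rej)
  })
}

#' @export
print.divnn_tree <- function(x, ...) {
  ca <- attr(x, "crown_age")
  extant <- attr(x, "extant")
  cat(sprintf("<divnn_tree: %d tips, %d nodes%s%s>\n",
              ape::Ntip(x), n_nodes(x),
              if (!is.null(ca)) sprintf(", crown age %g", ca) else "",
              if (!is.null(extant) && !all(extant))
                sprintf(", %d extinct tips", sum(!extant)) else ""))
  invisible(x)
}
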