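# Deterministic miniature corpus used by the test-suite and examples.

#' Deterministic test fixtures
#'
#' A tiny corpus rebuilt bit-identically from a seed: a five-tip example
#' tree (the shape used to illustrate the graph encoding), a perfectly
#' balanced four-tip tree, a six-tip caterpillar, and 50-tree reconstructed
#' mini-sets for each scenario with their generating parameters. All trees
#' pass [filter_trees()] at its defaults.
#'
#' @param seed Integer seed.
#' @param n_mini Trees per scenario mini-set.
#' @return List with `five_tip`, `balanced4`, `caterpillar6`, and per-scenario
#'   lists `bd`, `ddd`, `pbd` (each `trees` + `params`).
#' @export
make_fixtures <- function(seed = 1L, n_mini = 50L) {
  five_tip <- read_newick(text = "((t1:2,t2:2):8,(t3:7,(t4:4,t5:4):3):3);")
  balanced4 <- read_newick(text = "((a:1,b:1):1,(c:1,d:1):1);")
  caterpillar6 <- read_newick(
    text = "(a:5,(b:4,(c:3,(d:2,(e:1,f:1):1):1):1):1);")
  mini <- function(scenario, sub_seed) {
    trees <- list(); params <- NULL
    k <- 0L
    while (length(trees) < n_mini) {
      k <- k + 1L
      out <- sim_trees(sim_config(scenario, n_trees = n_mini,
                                  rng_seed = sub_seed + k))
      fl <- filter_trees(out$trees)
      trees <- c(trees, fl$trees)
      params <- rbind(params, out$params[fl$kept, , drop = FALSE])
    }
    idx <- seq_len(n_mini)
    params <- params[idx, , drop = FALSE]
    params$tree_id <- idx
    rownames(params) <- NULL
    list(trees = trees[idx], params = params)
  }
  list(five_tip = five_tip, balanced4 = balanced4, caterpillar6 = caterpillar6,
       bd = mini("BD", seed * 1000L),
       ddd = mini("DDD", seed * 1000L + 100L),
       pbd = mini("PBD", seed * 1000L + 200L))
}
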