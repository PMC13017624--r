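# A fixed, named set of 54 tree summary statistics for the dense network.
# The set draws on the standard families used in phylogenetic and
# phylodynamic inference: size and scale, branch-length moments for all /
# external / internal branches, branching-time moments, lineage-through-time
# behaviour (including the Pybus-Harvey gamma), topological imbalance
# (Colless, Sackin, cherries, ladders), and tip-depth dispersion. All
# statistics are label-invariant, deterministic, and finite for any fully
# bifurcating tree with >= 3 tips.

SUMMARY_STAT_NAMES <- c(
  "n_tips", "n_nodes", "tree_length",
  "bl_mean", "bl_median", "bl_sd", "bl_min", "bl_max", "bl_cv",
  "ext_mean", "ext_median", "ext_sd", "ext_min", "ext_max", "ext_cv",
  "int_mean", "int_median", "int_sd", "int_min", "int_max", "int_cv",
  "treeness", "int_frac_mean",
  "bt_mean", "bt_median", "bt_sd", "bt_min", "bt_max", "bt_cv",
  "bt_skew", "bt_mean_norm",
  "gamma", "ltt_slope1", "ltt_slope2", "ltt_slope_ratio", "t_half_norm",
  "spacing_cv", "spacing_max_norm",
  "colless", "colless_norm", "sackin", "sackin_norm",
  "cherries", "cherries_norm", "pitchforks", "max_ladder",
  "stairs1", "stairs2",
  "tip_depth_max", "tip_depth_min", "tip_depth_mean", "tip_depth_var",
  "int_depth_mean",
  "height_over_length")

safe_sd <- function(x) if (length(x) < 2L) 0 else sd(x)
safe_cv <- function(x) {
  m <- mean(x)
  if (m <= 0) 0 else safe_sd(x) / m
}
safe_skew <- function(x) {
  s <- safe_sd(x)
  if (length(x) < 3L || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

#' Pybus-Harvey gamma statistic
#'
#' Measures whether internal nodes are closer to the root (gamma < 0) or the
#' tips (gamma > 0) than expected under a pure-birth process, computed from
#' the inter-node intervals of an ultrametric tree.
#'
#' @param bt Branching times sorted decreasing (crown age first), length
#'   `n - 1` for `n` tips (`n >= 3`).
#' @return The gamma statistic (0 when the variance term degenerates).
#' @export
gamma_statistic <- function(bt) {
  n <- length(bt) + 1L
  if (n < 3L) stop_data("gamma statistic needs at least 3 tips")
  # g[j] = duration of the interval with j lineages, j = 2..n
  g <- c(-diff(bt), bt[n - 1L])
  T_total <- sum((2:n) * g)
  if (T_total <= 0) return(0)
  Tk <- cumsum((2:(n - 1L)) * g[seq_len(n - 2L)])
  (mean(Tk) - T_total / 2) / (T_total * sqrt(1 / (12 * (n - 2L))))
}

# Topology scan: per-node tip counts, per-tip/internal topological depths,
# and imbalance summaries, from a single pass over the edge matrix.
topology_stats <- function(tree) {
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  edge <- tree$edge
  depth <- integer(N)
  for (e in seq_len(nrow(edge)))          # cladewise: parent precedes child
    depth[edge[e, 2L]] <- depth[edge[e, 1L]] + 1L
  ndesc <- integer(N); ndesc[seq_len(n)] <- 1L
  for (e in rev(seq_len(nrow(edge))))
    ndesc[edge[e, 1L]] <- ndesc[edge[e, 1L]] + ndesc[edge[e, 2L]]
  kids <- split(edge[, 2L], edge[, 1L])   # order of names irrelevant below
  ints <- as.integer(names(kids))
  lr <- vapply(kids, function(ch) ndesc[ch], numeric(2L))
  balance_gap <- abs(lr[1L, ] - lr[2L, ])
  cherry <- vapply(kids, function(ch) all(ch <= n), logical(1L))
  # ladder: chain of internal nodes each with exactly one tip child
  one_tip <- vapply(kids, function(ch) sum(ch <= n) == 1L, logical(1L))
  ladder <- integer(N)
  for (i in order(depth[ints], decreasing = TRUE)) {
    v <- ints[i]
    if (!one_tip[i]) next
    ch <- kids[[i]]
    internal_child <- ch[ch > n]
    ladder[v] <- 1L + if (length(internal_child)) ladder[internal_child] else 0L
  }
  list(
    colless = sum(balance_gap),
    sackin = sum(depth[seq_len(n)]),
    cherries = sum(cherry),
    pitchforks = sum(ndesc[ints] == 3L),
    max_ladder = max(ladder),
    stairs1 = mean(balance_gap > 0),
    stairs2 = mean(pmin(lr[1L, ], lr[2L, ]) / pmax(lr[1L, ], lr[2L, ])),
    tip_depth = depth[seq_len(n)],
    int_depth = depth[ints]
  )
}

#' Summary-statistic vector of a phylogeny
#'
#' Computes the fixed 54-element, named statistic vector used as input to
#' the dense network; see `SUMMARY_STAT_NAMES` for the full list and the
#' package vignette for definitions. Statistics are invariant to tip
#' relabelling and finite for every fully bifurcating tree with at least 3
#' tips.
#'
#' @param tree A fully bifurcating `phylo` with branch lengths and >= 3 tips.
#' @return Named numeric vector of length 54.
#' @export
#' @examples
#' set.seed(1)
#' tr <- prune_extinct(sim_bd(list(lambda = 0.5, mu = 0.1)))
#' length(tree_summary_stats(tr))
tree_summary_stats <- function(tree) {
  assert_binary_tree(tree, min_tips = 3L)
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  bl <- tree$edge.length
  is_ext <- tree$edge[, 2L] <= n
  ext <- bl[is_ext]; int <- bl[!is_ext]
  depths <- ape::node.depth.edgelength(tree)
  height <- max(depths[seq_len(n)])
  node_ages <- height - depths[(n + 1L):N]
  bt <- sort(node_ages, decreasing = TRUE)   # crown age first
  tlen <- sum(bl)
  # lineage-through-time slopes on log(lineage count) vs time since root,
  # over the older and younger halves of the branching events
  ev_time <- height - bt                     # increasing event times
  lineages <- 2:n
  half <- ceiling(length(bt) / 2)
  slope_fit <- function(tt, ll) {
    if (length(tt) < 2L || diff(range(tt)) <= 0) return(0)
    unname(stats::lm.fit(cbind(1, tt), log(ll))$coefficients[2L])
  }
  s1 <- slope_fit(ev_time[seq_len(half)], lineages[seq_len(half)])
  s2 <- slope_fit(ev_time[half:length(bt)], lineages[half:length(bt)])
  t_half <- ev_time[which(lineages >= ceiling(n / 2))[1L]]
  spacing <- diff(c(ev_time, height))
  top <- topology_stats(tree)
  g <- gamma_statistic(bt)
  out <- c(
    n, N, tlen,
    mean(bl), median(bl), safe_sd(bl), min(bl), max(bl), safe_cv(bl),
    mean(ext), median(ext), safe_sd(ext), min(ext), max(ext), safe_cv(ext),
    mean(int), median(int), safe_sd(int), min(int), max(int), safe_cv(int),
    sum(int) / max(tlen, .Machine$double.eps),
    mean(int) / max(mean(int) + mean(ext), .Machine$double.eps),
    mean(bt), median(bt), safe_sd(bt), min(bt), max(bt), safe_cv(bt),
    safe_skew(bt), mean(bt) / max(height, .Machine$double.eps),
    g, s1, s2, if (abs(s1) > 0) s2 / s1 else 0,
    t_half / max(height, .Machine$double.eps),
    safe_cv(spacing), max(spacing) / max(height, .Machine$double.eps),
    top$colless, top$colless / max((n - 1) * (n - 2) / 2, 1),
    top$sackin, top$sackin / n,
    top$cherries, top$cherries / floor(n / 2),
    top$pitchforks, top$max_ladder,
    top$stairs1, top$stairs2,
    max(top$tip_depth), min(top$tip_depth), mean(top$tip_depth),
    if (n > 1) var(top$tip_depth) else 0,
    mean(top$int_depth),
    height / max(tlen, .Machine$double.eps))
  setNames(out, SUMMARY_STAT_NAMES)
}

#' Summary-statistic table for a list of trees
#'
#' @param trees List of trees.
#' @return A data.frame with one row per tree and 54 named columns.
#' @export
summary_stat_table <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  as.data.frame(do.call(rbind, lapply(trees, tree_summary_stats)))
}
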