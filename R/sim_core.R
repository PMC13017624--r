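# Exact (Gillespie) simulation of diversification processes with a fixed
# crown age, on a lineage table: every lineage is born at a branching event
# (or at the crown) and ends by speciating, dying, or reaching the present,
# so each lineage maps to exactly one edge of the complete tree.

# Grow-by-doubling lineage store shared by the engines.
new_lineage_store <- function(cap = 256L) {
  list(parent = integer(cap), t_birth = numeric(cap), t_end = numeric(cap),
       n_children = integer(cap), dead = logical(cap))
}

# NB: `length<-` pads with NA; pad explicitly with zeros/FALSE instead.
grow_store <- function(st, need) {
  cap <- length(st$parent)
  if (need <= cap) return(st)
  new_cap <- max(need, 2L * cap)
  for (f in names(st)) {
    pad <- new_cap - length(st[[f]])
    st[[f]] <- c(st[[f]], vector(typeof(st[[f]]), pad))
  }
  st
}

# Convert a lineage table to an ape "phylo" object (complete tree).
# Lineages with two children become internal nodes; the crown point is the
# root. Tip-level metadata (extant flags, species ids) is carried in
# attributes aligned with tip numbering.
lineages_to_phylo <- function(parent, t_birth, t_end, n_children, extant,
                              crown_age, species = NULL, status = NULL) {
  L <- length(parent)
  is_tip <- n_children == 0L
  tip_idx <- which(is_tip)
  int_idx <- which(!is_tip)
  n <- length(tip_idx)
  S <- length(int_idx)
  node_of <- integer(L)
  node_of[tip_idx] <- seq_len(n)
  node_of[int_idx] <- n + 1L + seq_len(S)
  root <- n + 1L
  from <- ifelse(parent == 0L, root, node_of[pmax(parent, 1L)])
  edge <- cbind(from, node_of[seq_len(L)])
  dimnames(edge) <- NULL
  phy <- structure(list(edge = edge,
                        edge.length = t_end - t_birth,
                        Nnode = S + 1L,
                        tip.label = paste0("t", seq_len(n))),
                   class = c("divnn_tree", "phylo"))
  phy <- ape::reorder.phylo(phy, "cladewise")
  # crown side of each lineage (parents precede children in the table)
  side <- integer(L)
  for (j in seq_len(L)) side[j] <- if (parent[j] == 0L) j else side[parent[j]]
  tip_extant <- extant[tip_idx]
  attr(phy, "crown_age") <- crown_age
  attr(phy, "extant") <- setNames(tip_extant, phy$tip.label)
  attr(phy, "crown_side") <- setNames(side[tip_idx], phy$tip.label)
  attr(phy, "surviving") <- any(tip_extant & side[tip_idx] == 1L) &&
                            any(tip_extant & side[tip_idx] == 2L)
  if (!is.null(species))
    attr(phy, "species") <- setNames(species[tip_idx], phy$tip.label)
  if (!is.null(status))
    attr(phy, "status") <- setNames(status[tip_idx], phy$tip.label)
  phy
}

# Shared engine for BD (constant rates) and DDD (linearly diversity-dependent
# speciation). Starts from the two crown lineages at t = 0 and runs to
# crown_age; the event loop lives in C++ (driven by R's RNG). Returns a
# complete tree, or a rejection marker when the lineage count exceeds
# max_alive (such runs could not pass the node-count filter).
gillespie_bd_ddd <- function(model, lambda0, mu0, K, crown_age,
                             max_alive = 100000L) {
  st <- cpp_bdd_gillespie(if (model == "bd") 0L else 1L, lambda0, mu0,
                          if (is.finite(K)) K else .Machine$double.xmax,
                          crown_age, max_alive)
  if (st$oversize) return(rejected("oversize"))
  extant <- !st$dead & st$n_children == 0L
  lineages_to_phylo(st$parent, st$t_birth, st$t_end, st$n_children,
                    extant, crown_age)
}

#' Simulate a complete constant-rate birth-death tree
#'
#' Exact continuous-time simulation starting from the two crown lineages at
#' time 0, run to the crown age. The returned complete tree retains extinct
#' subtrees; tips carry `extant` flags and the tree a `surviving` attribute
#' (`TRUE` when both crown lineages left extant descendants). Use
#' [prune_extinct()] to obtain the reconstructed tree.
#'
#' @param pars Named list or vector with `lambda` (speciation rate, > 0
#'   unless `mu` is also 0) and `mu` (extinction rate, >= 0).
#' @param crown_age Crown age in time units.
#' @param max_alive Safety cap on coexisting lineages; exceeding it returns a
#'   rejection marker (see [is_rejected()]).
#' @return A complete tree of class `c("divnn_tree", "phylo")`, or a
#'   rejection marker.
#' @export
#' @examples
#' set.seed(1)
#' tr <- sim_bd(list(lambda = 0.4, mu = 0.1), crown_age = 10)
#' sum(attr(tr, "extant"))
sim_bd <- function(pars, crown_age = 10, max_alive = 100000L) {
  lambda <- pars[["lambda"]]; mu <- pars[["mu"]]
  if (!is_scalar_num(lambda) || !is_scalar_num(mu) || lambda < 0 || mu < 0)
    stop_config("BD parameters must satisfy lambda >= 0, mu >= 0")
  gillespie_bd_ddd("bd", lambda, mu, Inf, crown_age, max_alive)
}

#' Simulate a complete diversity-dependent tree
#'
#' Exact simulation of the linear diversity-dependence model: the
#' per-lineage speciation rate is
#' `max(0, lambda0 - (lambda0 - mu0) * n / K)` at standing diversity `n`
#' (see [ddd_speciation_rate()]), while extinction stays constant at `mu0`.
#' As `K -> Inf` the process reduces to constant-rate birth-death.
#'
#' @param pars Named list or vector with `lambda0`, `mu0`, `K`.
#' @inheritParams sim_bd
#' @return A complete tree of class `c("divnn_tree", "phylo")`, or a
#'   rejection marker.
#' @export
sim_ddd <- function(pars, crown_age = 10, max_alive = 100000L) {
  lambda0 <- pars[["lambda0"]]; mu0 <- pars[["mu0"]]; K <- pars[["K"]]
  if (!is_scalar_num(lambda0) || lambda0 <= 0 || !is_scalar_num(mu0) || mu0 < 0)
    stop_config("DDD parameters must satisfy lambda0 > 0, mu0 >= 0")
  if (!(is.numeric(K) && length(K) == 1L && K > 0))
    stop_config("DDD carrying capacity K must be > 0 (may be Inf)")
  gillespie_bd_ddd("ddd", lambda0, mu0, K, crown_age, max_alive)
}

#' Simulate a protracted birth-death tree and its species tree
#'
#' Lineages are either good species or incipient. Good lineages initiate new
#' incipient lineages at rate `lambda1` and die at rate `mu1`; incipient
#' lineages initiate at `lambda3`, complete speciation (becoming a good
#' species) at `lambda2`, and die at `mu2`. An incipient lineage belongs to
#' its parent's species until its own completion, at which point it founds a
#' new species. The species tree keeps one representative extant lineage per
#' extant species (chosen uniformly at random among conspecific extant
#' lineages) and prunes everything else, so extinct species disappear.
#'
#' @param pars Named list or vector with `lambda1`, `lambda2`, `lambda3`,
#'   `mu1`, `mu2`.
#' @inheritParams sim_bd
#' @return List with `complete` (the full lineage tree, tips annotated with
#'   `species` and `status`) and `species_tree` (reconstructed, ultrametric;
#'   a rejection marker when fewer than two species survive or a crown
#'   lineage died out).
#' @export
sim_pbd <- function(pars, crown_age = 10, max_alive = 100000L) {
  la1 <- pars[["lambda1"]]; la2 <- pars[["lambda2"]]; la3 <- pars[["lambda3"]]
  mu1 <- pars[["mu1"]]; mu2 <- pars[["mu2"]]
  ok <- vapply(list(la1, la2, la3, mu1, mu2), is_scalar_num, TRUE)
  if (!all(ok) || la2 <= 0 || min(la1, la3, mu1, mu2) < 0)
    stop_config("PBD parameters must be non-negative with lambda2 > 0")
  st <- new_lineage_store()
  # per-lineage protracted state
  good <- logical(256L); sp <- integer(256L)
  st$parent[1:2] <- 0L; st$t_birth[1:2] <- 0
  good[1:2] <- TRUE; sp[1:2] <- 1:2
  next_sp <- 3L
  L <- 2L
  # constant-time bookkeeping: one swap-list per status class
  glist <- integer(1024L); ilist <- integer(1024L)
  glist[1:2] <- 1:2; ng <- 2L; ni <- 0L
  pos <- integer(1024L); pos[1:2] <- 1:2
  t <- 0
  grow_state <- function(need) {
    if (need > length(good)) {
      nc <- max(need, 2L * length(good))
      good <<- c(good, logical(nc - length(good)))
      sp <<- c(sp, integer(nc - length(sp)))
      if (nc > length(pos)) pos <<- c(pos, integer(nc - length(pos)))
    }
  }
  repeat {
    r_init_g <- ng * la1; r_die_g <- ng * mu1
    r_init_i <- ni * la3; r_comp <- ni * la2; r_die_i <- ni * mu2
    total <- r_init_g + r_die_g + r_init_i + r_comp + r_die_i
    if (total <= 0) break
    t <- t + rexp(1L, total)
    if (t >= crown_age) break
    u <- runif(1L) * total
    if (u < r_init_g + r_init_i) {
      # speciation initiation by a good (u < r_init_g) or incipient lineage
      from_good <- u < r_init_g
      if (from_good) { k <- sample.int(ng, 1L); j <- glist[k] }
      else           { k <- sample.int(ni, 1L); j <- ilist[k] }
      st <- grow_store(st, L + 2L)
      grow_state(L + 2L)
      st$t_end[j] <- t; st$n_children[j] <- 2L
      # continuation child inherits state; new child is incipient and
      # conspecific with the parent until it completes
      c1 <- L + 1L; c2 <- L + 2L
      st$parent[c1] <- j; st$t_birth[c1] <- t
      good[c1] <- good[j]; sp[c1] <- sp[j]
      st$parent[c2] <- j; st$t_birth[c2] <- t
      good[c2] <- FALSE; sp[c2] <- sp[j]
      # continuation child replaces the parent in its list
      if (from_good) glist[k] <- c1 else ilist[k] <- c1
      pos[c1] <- k
      ni <- ni + 1L
      if (ni > length(ilist)) length(ilist) <- 2L * length(ilist)
      ilist[ni] <- c2; pos[c2] <- ni
      L <- L + 2L
      if (ng + ni > max_alive)
        return(list(complete = rejected("oversize"),
                    species_tree = rejected("oversize")))
    } else if (u < r_init_g + r_init_i + r_comp) {
      # speciation completion: incipient becomes a new good species
      k <- sample.int(ni, 1L); j <- ilist[k]
      ilist[k] <- ilist[ni]; pos[ilist[k]] <- k; ni <- ni - 1L
      ng <- ng + 1L
      if (ng > length(glist)) length(glist) <- 2L * length(glist)
      glist[ng] <- j; pos[j] <- ng
      good[j] <- TRUE
      sp[j] <- next_sp
      next_sp <- next_sp + 1L
    } else {
      # extinction of a good (first branch) or incipient lineage
      if (u < r_init_g + r_init_i + r_comp + r_die_g) {
        k <- sample.int(ng, 1L); j <- glist[k]
        glist[k] <- glist[ng]; pos[glist[k]] <- k; ng <- ng - 1L
      } else {
        k <- sample.int(ni, 1L); j <- ilist[k]
        ilist[k] <- ilist[ni]; pos[ilist[k]] <- k; ni <- ni - 1L
      }
      st$t_end[j] <- t; st$dead[j] <- TRUE
      if (ng + ni == 0L) break
    }
  }
  live <- c(glist[seq_len(ng)], ilist[seq_len(ni)])
  if (length(live) > 0L) st$t_end[live] <- crown_age
  extant <- !st$dead[seq_len(L)] & st$n_children[seq_len(L)] == 0L
  complete <- lineages_to_phylo(st$parent[seq_len(L)], st$t_birth[seq_len(L)],
                                st$t_end[seq_len(L)], st$n_children[seq_len(L)],
                                extant, crown_age,
                                species = sp[seq_len(L)],
                                status = ifelse(good[seq_len(L)], "good", "incipient"))
  list(complete = complete, species_tree = pbd_species_tree(complete))
}

# Collapse a complete protracted tree to its reconstructed species tree.
pbd_species_tree <- function(complete) {
  extant <- attr(complete, "extant")
  species <- attr(complete, "species")
  side <- attr(complete, "crown_side")
  ext_tips <- names(extant)[extant]
  if (length(ext_tips) == 0L) return(rejected("all lineages extinct"))
  reps <- vapply(split(ext_tips, species[ext_tips]), function(tips) {
    if (length(tips) == 1L) tips else sample(tips, 1L)
  }, character(1L))
  if (length(reps) < 2L) return(rejected("fewer than 2 extant species"))
  if (length(unique(side[reps])) < 2L) return(rejected("crown lineage extinct"))
  stree <- ape::keep.tip(complete, unname(reps))
  class(stree) <- c("divnn_tree", "phylo")
  attr(stree, "crown_age") <- attr(complete, "crown_age")
  attr(stree, "extant") <- setNames(rep(TRUE, length(reps)), stree$tip.label)
  attr(stree, "species") <- setNames(species[reps][match(stree$tip.label, unname(reps))],
                                     stree$tip.label)
  stree
}
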