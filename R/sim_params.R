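# Parameter samplers for the three diversification scenarios.
#
# Training boxes (rates in events per lineage per time unit):
#   BD : lambda ~ U(0.1, 0.8), mu ~ U(0, 0.9 lambda)
#   DDD: lambda0 ~ U(0.1, 4.0), mu0 ~ U(0, min(0.9 lambda0, 1.5)),
#        K ~ U(10, 1000)
#   PBD: lambda1 ~ U(0.1, 1), lambda2 = 10^i with i ~ U(-3, 1),
#        lambda3 ~ U(0.1, 1), mu1 ~ U(0, 0.8 lambda1), mu2 ~ U(0, 0.8 lambda3)
# Extinction upper bounds depend on the drawn speciation rate so that whole
# clades rarely die out; the DDD extinction bound is additionally capped at
# 1.5 to keep event counts tractable.

SCENARIOS <- c("BD", "DDD", "PBD")

#' Scenario parameter names
#'
#' Column/parameter names used throughout the package for each scenario, in
#' the order networks and estimators emit them.
#'
#' @param scenario One of `"BD"`, `"DDD"`, `"PBD"`.
#' @return Character vector of parameter names (length 2, 3 or 5).
#' @export
param_names <- function(scenario) {
  switch(match_scenario(scenario),
    BD  = c("lambda", "mu"),
    DDD = c("lambda0", "mu0", "K"),
    PBD = c("lambda1", "lambda2", "lambda3", "mu1", "mu2")
  )
}

match_scenario <- function(scenario) {
  if (!is.character(scenario) || length(scenario) != 1L ||
      !toupper(scenario) %in% SCENARIOS)
    stop_config("unknown scenario; must be one of ", paste(SCENARIOS, collapse = ", "))
  toupper(scenario)
}

#' Sample generating parameters for a diversification scenario
#'
#' Draws parameter vectors from the training distributions: independent
#' uniforms with extinction upper bounds proportional to the drawn speciation
#' rate (0.9 lambda for BD, min(0.9 lambda0, 1.5) for DDD, 0.8 lambda for the
#' two PBD extinction rates) and a log10-uniform speciation-completion rate
#' for PBD. Uses the ambient RNG; seed with [set.seed()] for reproducibility.
#'
#' @param scenario One of `"BD"`, `"DDD"`, `"PBD"`.
#' @param n Number of parameter vectors to draw.
#' @return A data.frame with `n` rows and [param_names()] columns.
#' @export
#' @examples
#' set.seed(1)
#' sample_params("DDD", 3)
sample_params <- function(scenario, n = 1L) {
  scenario <- match_scenario(scenario)
  n <- as.integer(n)
  if (n < 1L) stop_config("n must be >= 1")
  out <- switch(scenario,
    BD = {
      lambda <- runif(n, 0.1, 0.8)
      mu <- runif(n, 0, 0.9 * lambda)
      data.frame(lambda = lambda, mu = mu)
    },
    DDD = {
      lambda0 <- runif(n, 0.1, 4.0)
      mu0 <- runif(n, 0, pmin(0.9 * lambda0, 1.5))
      K <- runif(n, 10, 1000)
      data.frame(lambda0 = lambda0, mu0 = mu0, K = K)
    },
    PBD = {
      lambda1 <- runif(n, 0.1, 1.0)
      lambda2 <- 10^runif(n, -3, 1)
      lambda3 <- runif(n, 0.1, 1.0)
      mu1 <- runif(n, 0, 0.8 * lambda1)
      mu2 <- runif(n, 0, 0.8 * lambda3)
      data.frame(lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 mu1 = mu1, mu2 = mu2)
    })
  out
}

#' Simulation configuration
#'
#' Bundles the settings of a tree-simulation run. All trees share a fixed
#' crown age (default 10 time units); reconstructed trees outside
#' `[node_min, node_max]` total nodes are meant to be removed afterwards by
#' [filter_trees()].
#'
#' @param scenario One of `"BD"`, `"DDD"`, `"PBD"`.
#' @param n_trees Number of reconstructed trees to deliver.
#' @param crown_age Crown age in time units (> 0).
#' @param node_min,node_max Inclusive bounds on total node count
#'   (root + internal + tips) used by [filter_trees()].
#' @param rng_seed Optional integer seed; `NULL` uses the ambient RNG.
#' @return An object of class `divnn_sim_config`.
#' @export
sim_config <- function(scenario, n_trees = 1L, crown_age = 10,
                       node_min = 5L, node_max = 3000L, rng_seed = NULL) {
  scenario <- match_scenario(scenario)
  if (!is_scalar_num(crown_age) || crown_age <= 0)
    stop_config("crown_age must be a positive number")
  node_min <- as.integer(node_min); node_max <- as.integer(node_max)
  if (node_min < 5L) stop_config("node_min must be >= 5")
  if (node_max < node_min) stop_config("node_max must be >= node_min")
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop_config("n_trees must be >= 1")
  structure(list(scenario = scenario, n_trees = n_trees, crown_age = crown_age,
                 node_min = node_min, node_max = node_max, rng_seed = rng_seed),
            class = "divnn_sim_config")
}

#' Per-lineage speciation rate under linear diversity dependence
#'
#' The diversity-dependent model uses a speciation rate that declines
#' linearly with standing diversity `n`:
#' `lambda_n = max(0, lambda0 - (lambda0 - mu0) * n / K)`.
#' The rate reaches zero at `n = K' = K * lambda0 / (lambda0 - mu0)`, and the
#' model reduces to constant-rate birth-death as `K -> Inf`.
#'
#' @param n Standing diversity (number of coexisting lineages); vectorised.
#' @param lambda0 Intrinsic speciation rate at `n = 0`.
#' @param mu0 Intrinsic extinction rate.
#' @param K Clade-level carrying capacity (diversity at which the speciation
#'   rate equals the extinction rate).
#' @return Per-lineage speciation rate(s).
#' @export
ddd_speciation_rate <- function(n, lambda0, mu0, K) {
  pmax(0, lambda0 - (lambda0 - mu0) * n / K)
}
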