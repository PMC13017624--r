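# Evaluation protocols: residual analysis by tree-size class, the
# carrying-capacity effect, robustness grids over repeated identical
# parameter settings, misspecification bands for carrying-capacity
# estimates, empirical-tree preparation, and parametric-bootstrap
# uncertainty. All analyses accept any registered estimator.

#' Tree-size class
#'
#' Classifies trees by total node count: `small` below 200 nodes, `medium`
#' 200 to 500 nodes (inclusive), `large` above 500.
#'
#' @param n_nodes Integer vector of total node counts (>= 5).
#' @return Factor with levels `small`, `medium`, `large`.
#' @export
size_bin <- function(n_nodes) {
  if (any(n_nodes < 5L)) stop_data("n_nodes below the minimum tree size")
  cut(n_nodes, c(-Inf, 199.5, 500.5, Inf),
      labels = c("small", "medium", "large"))
}

#' Build an estimate-record table
#'
#' One row per tree and method, carrying the truth (when known), the
#' estimates, the tree size and the convergence flag -- the common currency
#' of the evaluation functions.
#'
#' @param tree_id Identifier vector.
#' @param method Method name (recycled).
#' @param scenario Scenario string.
#' @param truth Data.frame/matrix of true parameters (or `NULL`).
#' @param estimates Data.frame/matrix of estimated parameters.
#' @param n_nodes Total node counts.
#' @param converged Logical vector (default all `TRUE`).
#' @return A data.frame with `truth_*` and `est_*` columns.
#' @export
estimate_records <- function(tree_id, method, scenario, truth, estimates,
                             n_nodes, converged = TRUE) {
  pn <- param_names(scenario)
  est <- as.data.frame(estimates)[, pn, drop = FALSE]
  names(est) <- paste0("est_", pn)
  out <- data.frame(tree_id = tree_id, method = method, scenario = scenario,
                    n_nodes = n_nodes, size_bin = size_bin(n_nodes),
                    converged = converged)
  if (!is.null(truth)) {
    tr <- as.data.frame(truth)[, pn, drop = FALSE]
    names(tr) <- paste0("truth_", pn)
    out <- cbind(out, tr)
  }
  cbind(out, est)
}

#' Residuals and mean absolute errors by method, parameter and size class
#'
#' Residuals are `truth - estimate` per parameter. Estimates whose absolute
#' residual exceeds `exclude_beyond` are excluded from the MAE (as extreme
#' maximum-likelihood estimates are excluded from plots) but never silently:
#' the excluded counts are reported per cell. Non-converged records are
#' excluded the same way.
#'
#' @param records An [estimate_records()] data.frame with truth columns.
#' @param exclude_beyond Absolute-residual display threshold (default
#'   `Inf`: nothing excluded).
#' @return List with `residuals` (long data.frame: tree_id, method,
#'   parameter, truth, estimate, residual, size_bin, converged) and `mae`
#'   (per method x parameter x size_bin: `mae`, `n`, `n_excluded`).
#' @export
residual_table <- function(records, exclude_beyond = Inf) {
  pn <- sub("^truth_", "", grep("^truth_", names(records), value = TRUE))
  if (length(pn) == 0L) stop_config("records carry no truth columns")
  long <- do.call(rbind, lapply(pn, function(p) {
    data.frame(tree_id = records$tree_id, method = records$method,
               parameter = p, truth = records[[paste0("truth_", p)]],
               estimate = records[[paste0("est_", p)]],
               size_bin = records$size_bin, converged = records$converged)
  }))
  long$residual <- long$truth - long$estimate
  keep <- long$converged & is.finite(long$residual) &
    abs(long$residual) <= exclude_beyond
  key <- paste(long$method, long$parameter, long$size_bin, sep = "\001")
  cells <- split(seq_len(nrow(long)), key)
  mae <- do.call(rbind, lapply(names(cells), function(k) {
    idx <- cells[[k]]
    ok <- idx[keep[idx]]
    key <- strsplit(k, "\001", fixed = TRUE)[[1L]]
    data.frame(method = key[1L], parameter = key[2L], size_bin = key[3L],
               mae = if (length(ok)) mean(abs(long$residual[ok])) else NA_real_,
               n = length(ok), n_excluded = length(idx) - length(ok))
  }))
  rownames(mae) <- NULL
  list(residuals = long, mae = mae)
}

#' Carrying-capacity effect strength
#'
#' `(lambda - mu) / K`: the reciprocal of the diversity at which speciation
#' reaches zero under linear diversity dependence. Larger values mean the
#' diversity feedback binds sooner and shapes the tree more strongly.
#'
#' @param lambda,mu,K Numeric (vectorised); `K > 0`.
#' @return `(lambda - mu) / K`.
#' @export
cc_effect <- function(lambda, mu, K) {
  if (any(K <= 0)) stop_config("K must be positive")
  (lambda - mu) / K
}

#' Expected total node count under constant-rate birth-death
#'
#' `E[N_nodes(t)] = 2 exp((lambda - mu) t) - 1`, from the expected extant
#' tip count of the two-lineage crown process; used to interpret
#' carrying-capacity estimates on misspecified (true birth-death) trees.
#'
#' @param lambda,mu Rates; `t` elapsed time (>= 0).
#' @param t Time since the crown split.
#' @return Expected node count (vectorised).
#' @export
expected_nodes <- function(lambda, mu, t) {
  if (any(t < 0)) stop_config("t must be non-negative")
  2 * exp((lambda - mu) * t) - 1
}

#' Classify a carrying-capacity estimate against tree size
#'
#' Bands of `K_hat` relative to the total node count `N`:
#' `below` (< 2N), `band1` `[2N, 5N)`, `band2` `[5N, 20N)`, `band3`
#' `[20N, Inf)` finite, and `infinite` for exactly infinite estimates.
#' Bands are left-closed/right-open and partition `[2N, Inf]`.
#'
#' @param K_hat Estimated carrying capacities (may contain `Inf`).
#' @param n_nodes Total node counts (recycled).
#' @return Factor with levels `below`, `band1`, `band2`, `band3`,
#'   `infinite`.
#' @export
misspec_classify <- function(K_hat, n_nodes) {
  if (any(n_nodes < 5L)) stop_data("n_nodes below the minimum tree size")
  n <- rep_len(n_nodes, length(K_hat))
  ratio <- K_hat / n
  out <- ifelse(is.infinite(K_hat), "infinite",
         ifelse(ratio < 2, "below",
         ifelse(ratio < 5, "band1",
         ifelse(ratio < 20, "band2", "band3"))))
  factor(out, levels = c("below", "band1", "band2", "band3", "infinite"))
}

#' Mean duration of speciation under the protracted model
#'
#' Expected time from speciation initiation to completion, conditional on
#' completion, accounting for branching of the incipient clade (rate
#' `lambda3`), its extinction (`mu2`), and completion (`lambda2`):
#' `tau = 2 / (D - phi) * log(2 D / (D + phi))` with
#' `phi = lambda2 - lambda3 + mu2` and
#' `D = sqrt((lambda2 + lambda3)^2 + 2 (lambda2 - lambda3) mu2 + mu2^2)`.
#' Instantaneous completion (`lambda2 -> Inf`) gives `tau -> 0`; with
#' neither branching nor extinction it reduces to `1 / lambda2`.
#'
#' @param lambda2 Speciation-completion rate (> 0).
#' @param lambda3 Speciation-initiation rate of incipient species.
#' @param mu2 Extinction rate of incipient species.
#' @return Mean duration of speciation (vectorised).
#' @export
pbd_mean_duration <- function(lambda2, lambda3, mu2) {
  if (any(lambda2 <= 0)) stop_config("lambda2 must be positive")
  D <- sqrt((lambda2 + lambda3)^2 + 2 * (lambda2 - lambda3) * mu2 + mu2^2)
  phi <- lambda2 - lambda3 + mu2
  b <- D - phi
  out <- ifelse(abs(b) < 1e-9 * D, 1 / D, 2 / b * log(2 * D / (D + phi)))
  unname(out)
}

#' Composite diversification parameters
#'
#' BD/DDD: net diversification rate `lambda - mu` and
#' extinction-to-speciation ratio `mu / lambda`. PBD: the mean duration of
#' speciation ([pbd_mean_duration()]), which is considerably better
#' identified than the individual protracted rates.
#'
#' @param estimates Data.frame/matrix with the scenario's parameter columns.
#' @param scenario Scenario string.
#' @return Data.frame of composite parameters.
#' @export
composite_params <- function(estimates, scenario) {
  scenario <- match_scenario(scenario)
  est <- as.data.frame(estimates)
  if (scenario %in% c("BD", "DDD")) {
    l <- est[[if (scenario == "BD") "lambda" else "lambda0"]]
    m <- est[[if (scenario == "BD") "mu" else "mu0"]]
    if (any(l == 0)) stop_data("zero speciation rate: ratio undefined")
    data.frame(net_div = l - m, eps_ratio = m / l)
  } else {
    data.frame(mean_duration = pbd_mean_duration(est$lambda2, est$lambda3,
                                                 est$mu2))
  }
}

#' Robustness of estimators over repeated identical parameter settings
#'
#' For each parameter combination of the grid, simulates `n_per_cell`
#' diversity-dependent trees (same parameters, independent stochastic
#' realisations, re-drawn until they satisfy the node-count bounds),
#' applies every estimator, and reports the per-cell per-parameter mean
#' absolute error. Expensive estimators can be run on a seeded subsample of
#' each cell via `subsample`.
#'
#' @param grid Data.frame with columns `lambda0`, `mu0`, `K`; defaults to
#'   the full factorial `lambda = 1, 1.5, 2, 2.5, 3`,
#'   `mu = 0.2, 0.4, 0.6, 0.8`, `K = 200, 400, 600, 800` (80 cells).
#' @param n_per_cell Trees per combination (default 1000).
#' @param estimators Named list of functions `f(tree) -> list(estimates =
#'   named vector, converged = logical)` (or names registered via
#'   [register_estimator()]).
#' @param subsample Optional named integer vector: number of trees per cell
#'   an estimator is run on (seeded subsample).
#' @param crown_age,node_min,node_max Simulation settings.
#' @param rng_seed Seed for the whole analysis.
#' @return Data.frame: one row per cell x method x parameter with `mae`,
#'   `n_trees`, `n_failed`.
#' @export
robustness_grid <- function(grid = NULL, n_per_cell = 1000L, estimators,
                            subsample = NULL, crown_age = 10,
                            node_min = 5L, node_max = 3000L, rng_seed = NULL) {
  if (is.null(grid))
    grid <- expand.grid(lambda0 = c(1, 1.5, 2, 2.5, 3),
                        mu0 = c(0.2, 0.4, 0.6, 0.8),
                        K = c(200, 400, 600, 800))
  if (n_per_cell < 2L) stop_config("n_per_cell must be >= 2")
  estimators <- resolve_estimators(estimators)
  pn <- param_names("DDD")
  with_seed(rng_seed, {
    out <- list()
    for (ci in seq_len(nrow(grid))) {
      pars <- as.list(grid[ci, pn])
      trees <- sim_cell_trees(pars, n_per_cell, crown_age, node_min, node_max)
      for (m in names(estimators)) {
        idx <- seq_along(trees)
        if (!is.null(subsample) && m %in% names(subsample))
          idx <- sort(sample(idx, min(subsample[[m]], length(idx))))
        res <- lapply(trees[idx], run_estimator, fn = estimators[[m]], pn = pn)
        est <- do.call(rbind, lapply(res, `[[`, "estimates"))
        ok <- vapply(res, `[[`, TRUE, "converged") &
          apply(is.finite(est), 1L, all)
        truth <- matrix(unlist(pars), nrow = sum(ok), ncol = length(pn),
                        byrow = TRUE)
        mae <- if (any(ok)) colMeans(abs(truth - est[ok, , drop = FALSE]))
               else rep(NA_real_, length(pn))
        out[[length(out) + 1L]] <- data.frame(
          grid[ci, , drop = FALSE], method = m, parameter = pn,
          mae = unname(mae), n_trees = sum(ok), n_failed = sum(!ok),
          row.names = NULL)
      }
    }
    do.call(rbind, out)
  })
}

# simulate reconstructed DDD trees at fixed parameters until n pass the
# node-count bounds
sim_cell_trees <- function(pars, n, crown_age, node_min, node_max,
                           max_tries = 200L) {
  trees <- vector("list", n)
  have <- 0L
  tries <- 0L
  while (have < n) {
    tries <- tries + 1L
    if (tries > max_tries * n)
      stop_data("could not simulate enough in-bounds trees for cell")
    tr <- prune_extinct(sim_ddd(pars, crown_age))
    if (is_rejected(tr)) next
    nn <- n_nodes(tr)
    if (nn < node_min || nn > node_max) next
    have <- have + 1L
    trees[[have]] <- tr
  }
  trees
}

run_estimator <- function(tree, fn, pn) {
  res <- tryCatch(fn(tree), error = function(e) NULL)
  if (is.null(res))
    return(list(estimates = setNames(rep(NA_real_, length(pn)), pn),
                converged = FALSE))
  est <- res$estimates[pn]
  conv <- if (is.null(res$converged)) TRUE else isTRUE(res$converged)
  list(estimates = est, converged = conv)
}

#' Prepare an empirical tree for estimation
#'
#' Rescales all branch lengths so the crown age equals the training crown
#' age (default 10 time units); estimates must then be interpreted on the
#' rescaled time axis. If the tree fails an ultrametricity check -- branch
#' length precision issues are common in empirical trees -- every tip
#' branch is extended so that all tips end exactly at the present (aligned
#' with the farthest tip). Non-bifurcating trees are rejected.
#'
#' @param tree A rooted, fully bifurcating `phylo` with branch lengths.
#' @param crown_age Target crown age.
#' @param tol Relative ultrametricity tolerance beyond which tips are
#'   extended.
#' @return A tree of class `c("divnn_tree", "phylo")` with crown age
#'   `crown_age`; attribute `"rescale_factor"` records the applied factor.
#' @export
prepare_empirical <- function(tree, crown_age = 10, tol = 1e-6) {
  assert_binary_tree(tree, min_tips = 3L)
  depths <- ape::node.depth.edgelength(tree)
  old_age <- max(depths[seq_len(ape::Ntip(tree))])
  if (old_age <= 0) stop_data("tree has zero crown age")
  f <- crown_age / old_age
  tree$edge.length <- tree$edge.length * f
  depths <- ape::node.depth.edgelength(tree)
  n <- ape::Ntip(tree)
  tipd <- depths[seq_len(n)]
  gap <- max(tipd) - tipd
  if (any(gap > tol * crown_age)) {
    term <- match(seq_len(n), tree$edge[, 2L])
    tree$edge.length[term] <- tree$edge.length[term] + gap
  }
  class(tree) <- c("divnn_tree", "phylo")
  attr(tree, "crown_age") <- crown_age
  attr(tree, "extant") <- setNames(rep(TRUE, n), tree$tip.label)
  attr(tree, "rescale_factor") <- f
  tree
}

#' Parametric-bootstrap uncertainty of point estimates
#'
#' Simulates `n_boot` trees under the fitted scenario at the point
#' estimates, re-estimates each with every estimator, and summarises the
#' resulting empirical distributions; the spread quantifies how much the
#' estimate could move under re-realisation of the process.
#'
#' @param estimates Named vector/list of point estimates (must lie in the
#'   simulator's valid ranges).
#' @param scenario Scenario string.
#' @param n_boot Number of bootstrap trees (default 1000).
#' @param estimators Named list of estimator functions (or registered
#'   names).
#' @param crown_age,node_min,node_max Simulation settings.
#' @param rng_seed Seed.
#' @return List with `summary` (per method x parameter: mean, sd and the
#'   2.5/25/50/75/97.5 percent quantiles) and `draws` (per method: matrix
#'   of re-estimates).
#' @export
bootstrap_uncertainty <- function(estimates, scenario, n_boot = 1000L,
                                  estimators, crown_age = 10, node_min = 5L,
                                  node_max = 3000L, rng_seed = NULL) {
  scenario <- match_scenario(scenario)
  if (n_boot < 2L) stop_config("n_boot must be >= 2")
  pn <- param_names(scenario)
  est <- unlist(estimates)[pn]
  if (any(is.na(est)) || any(est[grep("^lambda", pn)] <= 0) ||
      any(est[grep("^mu", pn)] < 0) ||
      (scenario == "DDD" && est[["K"]] <= 2))
    stop_config("estimates outside simulator-valid ranges")
  estimators <- resolve_estimators(estimators)
  with_seed(rng_seed, {
    sim <- sim_trees(sim_config(scenario, n_trees = n_boot,
                                crown_age = crown_age),
                     params = as.data.frame(as.list(est)))
    keep <- vapply(sim$trees, function(tr)
      n_nodes(tr) >= node_min && n_nodes(tr) <= node_max, TRUE)
    trees <- sim$trees[keep]
    draws <- list(); summaries <- list()
    for (m in names(estimators)) {
      res <- lapply(trees, run_estimator, fn = estimators[[m]], pn = pn)
      em <- do.call(rbind, lapply(res, `[[`, "estimates"))
      ok <- vapply(res, `[[`, TRUE, "converged")
      em <- em[ok, , drop = FALSE]
      draws[[m]] <- em
      qs <- apply(em, 2L, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975),
                  na.rm = TRUE)
      summaries[[m]] <- data.frame(
        method = m, parameter = pn, point = unname(est),
        mean = colMeans(em, na.rm = TRUE),
        sd = apply(em, 2L, sd, na.rm = TRUE),
        q025 = qs[1L, ], q25 = qs[2L, ], q50 = qs[3L, ], q75 = qs[4L, ],
        q975 = qs[5L, ], n = nrow(em), row.names = NULL)
    }
    list(summary = do.call(rbind, summaries), draws = draws)
  })
}
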