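# Maximum-likelihood baseline: constant-rate birth-death likelihood of a
# reconstructed tree's branching times, conditioned on the crown age and
# (by default) on survival of both crown lineages, optimised by Nelder-Mead
# simplex from either the true parameters ("best" case) or a random draw
# from the training box ("naive" case).

# log g(t) with g(t) = exp(-r t) / (lambda - mu exp(-r t))^2, written via
# expm1 so that the critical limit lambda -> mu stays accurate. The
# denominator is r + mu * (1 - exp(-r t)).
bd_log_g <- function(t, lambda, mu) {
  r <- lambda - mu
  if (abs(r) < 1e-14) r <- 1e-14
  den <- r - mu * expm1(-r * t)   # same sign as r for all valid rates
  -r * t - 2 * log(abs(den))
}

# log P(survive to present | age t) = log[ r / (r + mu (1 - e^{-rt})) ]
bd_log_psurv <- function(t, lambda, mu) {
  r <- lambda - mu
  if (abs(r) < 1e-14) r <- 1e-14
  den <- r - mu * expm1(-r * t)
  log(abs(r)) - log(abs(den))
}

#' Birth-death log-likelihood of branching times
#'
#' Log-likelihood of the reconstructed constant-rate birth-death process for
#' the branching times of an ultrametric tree, conditioned on the crown age
#' (the oldest branching time) and, by default, on survival of both crown
#' lineages -- the same conditioning the simulators impose. Tip-labelling
#' constants are omitted. Along every edge the extinction-pruned lineage
#' propagator applies; each of the `n - 2` non-root branchings contributes a
#' factor `lambda`.
#'
#' @param pars Named list/vector with `lambda` (> 0) and `mu` (>= 0).
#' @param bt Branching times sorted decreasing, crown age first (see
#'   [branching_times()]).
#' @param conditioning `"crown_survival"` (divide by the squared survival
#'   probability of a crown lineage) or `"crown_age"` (no survival term).
#' @return Log-likelihood (`-Inf` where the data are impossible, e.g.
#'   `lambda = 0` with more than two tips).
#' @export
bd_loglik <- function(pars, bt, conditioning = c("crown_survival", "crown_age")) {
  conditioning <- match.arg(conditioning)
  lambda <- pars[["lambda"]]; mu <- pars[["mu"]]
  if (!is_scalar_num(lambda) || !is_scalar_num(mu) || lambda < 0 || mu < 0)
    stop_config("rates must be non-negative numbers")
  n <- length(bt) + 1L
  if (n < 2L) stop_data("need at least one branching time")
  if (lambda == 0) return(-Inf)
  x1 <- bt[1L]
  ll <- (n - 2) * log(lambda) +
    2 * bd_log_g(x1, lambda, mu) +
    (if (n > 2L) sum(bd_log_g(bt[-1L], lambda, mu)) else 0) -
    n * bd_log_g(0, lambda, mu)
  if (conditioning == "crown_survival")
    ll <- ll - 2 * bd_log_psurv(x1, lambda, mu)
  ll
}

#' Nelder-Mead simplex maximisation with failure-as-data semantics
#'
#' Maximises `objective` by the simplex method. Optimisation failures
#' (non-finite objective everywhere, iteration cap) are reported through
#' `converged = FALSE`, never raised, so estimation tables can show failed
#' fits alongside successful ones.
#'
#' @param objective Function of a numeric vector returning a scalar to
#'   maximise (non-finite values are treated as very bad, not as errors).
#' @param start Numeric start vector.
#' @param reltol Relative convergence tolerance.
#' @param max_eval Maximum number of function evaluations.
#' @return List with `par`, `value`, `converged`, `n_evaluations`.
#' @export
simplex_optimize <- function(objective, start, reltol = 1e-8, max_eval = 2000L) {
  n_eval <- 0L
  any_finite <- FALSE
  wrapped <- function(p) {
    n_eval <<- n_eval + 1L
    v <- tryCatch(objective(p), error = function(e) -Inf)
    if (!is.finite(v)) return(-1e300)
    any_finite <<- TRUE
    v
  }
  res <- tryCatch(
    optim(start, wrapped, method = "Nelder-Mead",
          control = list(fnscale = -1, reltol = reltol, maxit = max_eval)),
    error = function(e) NULL)
  if (is.null(res) || !any_finite || res$value <= -1e299)
    return(list(par = start, value = -Inf, converged = FALSE,
                n_evaluations = n_eval))
  list(par = res$par, value = res$value,
       converged = res$convergence == 0L, n_evaluations = n_eval)
}

#' Birth-death maximum-likelihood estimate for one tree
#'
#' Optimises [bd_loglik()] over `(log lambda, logit(mu / lambda))`, which
#' enforces `0 <= mu < lambda` without explicit constraint handling. The
#' `"best"` protocol starts from the true parameters (requires `truth`);
#' the `"naive"` protocol starts from a random point of the training box
#' (`lambda ~ U(0.1, 0.8)`, `mu ~ U(0, 0.9 lambda)`), reproducible through
#' the ambient RNG.
#'
#' @param tree A reconstructed ultrametric tree, or a numeric vector of
#'   branching times (decreasing).
#' @param protocol `"best"` or `"naive"`.
#' @param truth Named vector/list with the true `lambda`, `mu` (best case).
#' @param conditioning Passed to [bd_loglik()].
#' @inheritParams simplex_optimize
#' @return An `MLEResult`-style list: `estimates` (named), `log_likelihood`,
#'   `converged`, `start_protocol`, `start`, `n_evaluations`.
#' @export
bd_mle <- function(tree, protocol = c("best", "naive"), truth = NULL,
                   conditioning = "crown_survival", reltol = 1e-8,
                   max_eval = 2000L) {
  protocol <- match.arg(protocol)
  bt <- if (is.numeric(tree)) sort(tree, decreasing = TRUE)
        else branching_times(tree)
  start_par <- if (protocol == "best") {
    if (is.null(truth)) stop_config("best-case protocol requires the true parameters")
    c(truth[["lambda"]], truth[["mu"]])
  } else {
    l <- runif(1, 0.1, 0.8)
    c(l, runif(1, 0, 0.9 * l))
  }
  to_theta <- function(p) {
    ratio <- min(max(p[2L] / p[1L], 1e-6), 1 - 1e-6)
    c(log(p[1L]), stats::qlogis(ratio))
  }
  from_theta <- function(th) {
    l <- exp(th[1L])
    c(lambda = l, mu = l * stats::plogis(th[2L]))
  }
  obj <- function(th) bd_loglik(from_theta(th), bt, conditioning)
  res <- simplex_optimize(obj, to_theta(start_par), reltol, max_eval)
  est <- from_theta(res$par)
  list(estimates = est, log_likelihood = res$value,
       converged = res$converged, start_protocol = protocol,
       start = c(lambda = start_par[1L], mu = start_par[2L]),
       n_evaluations = res$n_evaluations)
}

# ---------------------------------------------------------------------------
# plug-in estimator registry: external likelihood estimators (e.g. for the
# diversity-dependent or protracted models) participate in the evaluation
# protocols on the same footing as the built-in methods.

estimator_registry <- new.env(parent = emptyenv())

#' Register an external parameter estimator
#'
#' An estimator is a function `f(tree, ...)` returning a list with at least
#' `estimates` (named numeric vector) and optionally `converged`. Once
#' registered it can be referenced by name in [robustness_grid()] and
#' [bootstrap_uncertainty()].
#'
#' @param name Unique estimator name.
#' @param fn The estimator function.
#' @param overwrite Allow replacing an existing registration.
#' @return Invisibly, `name`.
#' @export
register_estimator <- function(name, fn, overwrite = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_config("estimator name must be a non-empty string")
  if (!is.function(fn)) stop_config("estimator must be a function(tree, ...)")
  if (length(formals(fn)) < 1L)
    stop_config("estimator must accept a tree as its first argument")
  if (!overwrite && exists(name, envir = estimator_registry, inherits = FALSE))
    stop_config("estimator '", name, "' is already registered")
  assign(name, fn, envir = estimator_registry)
  invisible(name)
}

#' @rdname register_estimator
#' @export
list_estimators <- function() sort(ls(estimator_registry))

#' @rdname register_estimator
#' @export
get_estimator <- function(name) {
  if (!exists(name, envir = estimator_registry, inherits = FALSE))
    stop_config("unknown estimator '", name, "'; available: ",
                if (length(list_estimators())) paste(list_estimators(), collapse = ", ")
                else "(none)")
  get(name, envir = estimator_registry)
}

# resolve a user-supplied estimator spec (function or registered name)
resolve_estimators <- function(estimators) {
  if (is.function(estimators)) estimators <- list(estimator = estimators)
  if (is.character(estimators))
    estimators <- setNames(lapply(estimators, get_estimator), estimators)
  if (is.null(names(estimators)) || any(!nzchar(names(estimators))))
    stop_config("estimators must be named")
  lapply(estimators, function(f) if (is.character(f)) get_estimator(f) else f)
}
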