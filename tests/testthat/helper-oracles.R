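# Independent oracles and shared lazily-built data for the test suite.

shared_env <- new.env()

shared <- function(name, builder) {
  if (!exists(name, envir = shared_env, inherits = FALSE))
    assign(name, builder(), envir = shared_env)
  get(name, envir = shared_env, inherits = FALSE)
}

# a small reconstructed BD corpus with targets, reused across files
bd_corpus <- function() shared("bd_corpus", function() {
  out <- sim_trees(sim_config("BD", n_trees = 60, rng_seed = 401))
  fl <- filter_trees(out$trees, 5, 500)
  list(trees = fl$trees, params = out$params[fl$kept, , drop = FALSE],
       ds = encode_dataset(fl$trees, out$params[fl$kept, ], "BD"))
})

# one surviving reconstructed BD tree with a tip-count window
sim_recon_bd <- function(lambda, mu, crown_age = 10, min_tips = 3,
                         max_tips = Inf) {
  repeat {
    tr <- prune_extinct(sim_bd(list(lambda = lambda, mu = mu), crown_age))
    if (!is_rejected(tr) && ape::Ntip(tr) >= min_tips &&
        ape::Ntip(tr) <= max_tips) return(tr)
  }
}

# --- likelihood oracle: lineage-probability ODEs solved numerically along
# the actual tree (extinction probability E and log-density L per edge),
# independent of the closed-form implementation
oracle_bd_loglik <- function(lambda, mu, tree) {
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  h <- max(depths)
  age <- h - depths
  e_at <- function(t) {
    if (t <= 1e-12) return(0)
    out <- deSolve::ode(c(E = 0), c(0, t), function(tt, y, p)
      list(mu - (lambda + mu) * y[1] + lambda * y[1]^2), NULL,
      atol = 1e-13, rtol = 1e-13)
    unname(out[nrow(out), "E"])
  }
  prop <- function(logD, a, b) {
    if (b - a < 1e-12) return(logD)
    out <- deSolve::ode(c(E = e_at(a), L = logD), c(a, b), function(tt, y, p)
      list(c(mu - (lambda + mu) * y[1] + lambda * y[1]^2,
             -(lambda + mu) + 2 * lambda * y[1])), NULL,
      atol = 1e-13, rtol = 1e-13)
    unname(out[nrow(out), "L"])
  }
  edge <- tree$edge
  children <- split(seq_len(nrow(edge)), edge[, 1])
  rec <- function(node) {
    if (node <= n) return(0)
    acc <- if (node == n + 1) 0 else log(lambda)
    for (e in children[[as.character(node)]]) {
      ch <- edge[e, 2]
      acc <- acc + prop(rec(ch), age[ch], age[node])
    }
    acc
  }
  rec(n + 1) - 2 * log(1 - e_at(h))
}

# --- imbalance oracles via a different route (ape::balance, phangorn)
oracle_colless <- function(tree) {
  b <- ape::balance(tree)
  sum(abs(b[, 1] - b[, 2]))
}
oracle_sackin <- function(tree) {
  n <- ape::Ntip(tree)
  sum(lengths(phangorn::Ancestors(tree, seq_len(n), "all")))
}

# --- independent protracted simulator (next-event scheduling per lineage);
# returns the number of extant species at crown age, unconditioned
oracle_pbd_species_count <- function(la1, la2, la3, mu1, mu2, age) {
  # lineage fields: status (TRUE good), species id
  good <- c(TRUE, TRUE); sp <- c(1L, 2L); next_sp <- 3L
  tnow <- rep(0, 2)                      # per-lineage clock
  alive <- c(TRUE, TRUE)
  # schedule each lineage independently: competing exponentials
  i <- 0L
  repeat {
    i <- i + 1L
    if (i > length(alive)) break
    if (!alive[i]) next
    t <- tnow[i]
    repeat {
      rates <- if (good[i]) c(init = la1, comp = 0, death = mu1)
               else c(init = la3, comp = la2, death = mu2)
      tot <- sum(rates)
      if (tot <= 0) { t <- age; break }
      t <- t + rexp(1, tot)
      if (t >= age) break
      ev <- sample(names(rates), 1, prob = rates / tot)
      if (ev == "init") {
        alive <- c(alive, TRUE); good <- c(good, FALSE)
        sp <- c(sp, sp[i]); tnow <- c(tnow, t)
      } else if (ev == "comp") {
        good[i] <- TRUE; sp[i] <- next_sp; next_sp <- next_sp + 1L
      } else { alive[i] <- FALSE; break }
    }
  }
  length(unique(sp[alive]))
}

# --- stochastic oracle for the mean duration of speciation: time of first
# completion in the incipient clade, conditional on completion
oracle_tau <- function(la2, la3, mu2, reps) {
  res <- numeric(reps); ok <- logical(reps)
  for (r in seq_len(reps)) {
    k <- 1L; t <- 0
    repeat {
      t <- t + rexp(1, k * (la2 + la3 + mu2))
      u <- runif(1) * (la2 + la3 + mu2)
      if (u < la2) { res[r] <- t; ok[r] <- TRUE; break }
      else if (u < la2 + la3) k <- k + 1L
      else { k <- k - 1L; if (k == 0L) break }
    }
  }
  list(mean = mean(res[ok]), se = stats::sd(res[ok]) / sqrt(sum(ok)))
}

# numerical gradient of a scalar pass w.r.t. a few entries of one parameter
num_grad_entries <- function(fval, params, key, n_entries = 5, eps = 1e-5) {
  idx <- seq_len(min(length(params[[key]]), n_entries))
  vapply(idx, function(i) {
    p2 <- params; p2[[key]][i] <- p2[[key]][i] + eps
    up <- fval(p2)
    p2[[key]][i] <- p2[[key]][i] - 2 * eps
    (up - fval(p2)) / (2 * eps)
  }, numeric(1))
}

expect_grad_close <- function(analytic, numeric_g, tol = 1e-4) {
  idx <- seq_along(numeric_g)
  rel <- abs(numeric_g - analytic[idx]) /
    pmax(1e-4, abs(numeric_g) + abs(analytic[idx]))
  expect_lt(max(rel), tol)
}
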