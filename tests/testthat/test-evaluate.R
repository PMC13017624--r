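# Size bins, residual tables, carrying-capacity effect, misspecification
# bands, composite parameters, robustness grid, empirical preparation,
# bootstrap.

test_that("size bins split at 200 and 500 nodes", {
  expect_identical(as.character(size_bin(c(5, 199, 200, 500, 501, 2999))),
                   c("small", "small", "medium", "medium", "large", "large"))
  expect_error(size_bin(4), class = "divnn_data_error")
})

test_that("residual tables compute truth-minus-estimate MAE per cell", {
  rec <- estimate_records(
    tree_id = 1:4, method = "m", scenario = "BD",
    truth = data.frame(lambda = c(1, 1, 2, 2), mu = c(0, 0, 0, 0)),
    estimates = data.frame(lambda = c(1, 1, 3, 1), mu = c(1, -1, 0, 0)),
    n_nodes = c(100, 100, 300, 700))
  rt <- residual_table(rec)
  expect_identical(unname(rt$residuals$residual[rt$residuals$parameter == "lambda"]),
                   c(0, 0, -1, 1))
  mae_mu_small <- rt$mae$mae[rt$mae$parameter == "mu" &
                               rt$mae$size_bin == "small"]
  expect_identical(mae_mu_small, 1)      # residuals +1, -1
  # exclusion threshold Inf equals the unfiltered table; finite thresholds
  # report their exclusions
  rt2 <- residual_table(rec, exclude_beyond = 0.5)
  expect_identical(sum(rt2$mae$n_excluded), 4L)   # lambda: 2, mu: 2
  expect_identical(sum(rt$mae$n_excluded), 0L)
  # invariance to record order
  rt3 <- residual_table(rec[sample(4), ])
  sorted <- function(x) {
    x <- x[order(x$parameter, x$size_bin), ]
    rownames(x) <- NULL
    x
  }
  expect_identical(sorted(rt3$mae), sorted(rt$mae))
})

test_that("carrying-capacity effect is (lambda - mu) / K", {
  expect_identical(cc_effect(1, 1, 50), 0)
  expect_identical(cc_effect(1.5, 0.5, 200), 0.005)
  expect_identical(cc_effect(1.5, 0.5, 400), 0.0025)  # doubling K halves it
  expect_error(cc_effect(1, 0, 0), class = "divnn_config_error")
})

test_that("expected node count follows 2 exp((lambda-mu) t) - 1", {
  expect_identical(expected_nodes(0.5, 0.5, 10), 1)
  expect_identical(expected_nodes(0.7, 0.2, 0), 1)
  expect_equal(expected_nodes(0.5, 0.2, 10), 2 * exp(3) - 1)
  # monotone in net diversification and time
  r <- seq(0, 1, by = 0.1)
  expect_true(all(diff(expected_nodes(r, 0, 10)) > 0))
  expect_true(all(diff(expected_nodes(0.5, 0.2, 0:10)) > 0))
})

test_that("carrying-capacity bands partition [2N, Inf] exactly", {
  N <- 120
  expect_identical(as.character(misspec_classify(c(100, 2 * N, 3 * N, 5 * N,
                                                   20 * N, 1e9, Inf), N)),
                   c("below", "band1", "band1", "band2", "band3", "band3",
                     "infinite"))
  set.seed(5)
  k <- c(exp(runif(200, 0, 20)), Inf)
  cls <- misspec_classify(k, N)
  expect_false(any(is.na(cls)))            # every estimate in exactly one band
  expect_identical(sum(table(cls)), 201L)
})

test_that("composite parameters: net diversification, ratio, duration", {
  cp <- composite_params(data.frame(lambda = c(0.5, 0.3), mu = c(0.5, 0.1)),
                         "BD")
  expect_equal(cp$net_div, c(0, 0.2))
  expect_equal(cp$eps_ratio, c(1, 1/3))
  expect_error(composite_params(data.frame(lambda = 0, mu = 0), "BD"),
               class = "divnn_data_error")
  # protracted duration: exponential and instantaneous-completion limits
  expect_equal(pbd_mean_duration(2, 0, 0), 0.5)
  expect_lt(pbd_mean_duration(1e6, 0.4, 0.1), 1e-5)
  expect_gt(pbd_mean_duration(0.1, 0.4, 0.1), pbd_mean_duration(1, 0.4, 0.1))
})

test_that("mean duration of speciation matches the stochastic oracle", {
  set.seed(71)
  o <- oracle_tau(0.5, 0.4, 0.1, reps = 60000)
  expect_lt(abs(pbd_mean_duration(0.5, 0.4, 0.1) - o$mean), 4 * o$se)
  set.seed(72)
  o2 <- oracle_tau(2, 0.5, 0.5, reps = 40000)
  expect_lt(abs(pbd_mean_duration(2, 0.5, 0.5) - o2$mean), 4 * o2$se)
})

test_that("robustness grid: oracle estimator scores zero, midrange scores
           its analytic deviation", {
  grid <- data.frame(lambda0 = c(1, 2), mu0 = c(0.2, 0.4), K = c(60, 120))
  oracle <- function(tree) list(estimates = c(lambda0 = NA, mu0 = NA, K = NA))
  # the oracle needs the cell truth; emulate via closure over the grid by
  # reading the tree's size-independent attributes is impossible, so use a
  # per-cell constant: run cells one at a time
  for (ci in 1:2) {
    truth <- unlist(grid[ci, ])
    est_oracle <- function(tree) list(estimates = truth)
    est_mid <- function(tree) list(estimates = midrange_params("DDD"))
    tab <- robustness_grid(grid[ci, ], n_per_cell = 3,
                           estimators = list(oracle = est_oracle,
                                             mid = est_mid),
                           rng_seed = 80 + ci)
    expect_true(all(tab$mae[tab$method == "oracle"] == 0))
    expect_equal(tab$mae[tab$method == "mid"],
                 unname(abs(truth - midrange_params("DDD"))))
    expect_true(all(tab$n_trees == 3))
  }
})

test_that("robustness subsampling limits an estimator's tree count", {
  est <- function(tree) list(estimates = c(lambda0 = 1, mu0 = 0.2, K = 60))
  tab <- robustness_grid(data.frame(lambda0 = 1, mu0 = 0.2, K = 60),
                         n_per_cell = 5, estimators = list(e = est),
                         subsample = c(e = 2), rng_seed = 3)
  expect_true(all(tab$n_trees == 2))
})

test_that("empirical preparation rescales and aligns tips exactly", {
  tr <- read_newick(text = "((a:25,b:25):25,c:50);")
  p <- prepare_empirical(tr, crown_age = 10)
  expect_equal(attr(p, "rescale_factor"), 0.2)
  expect_lt(abs(max(ape::node.depth.edgelength(p)) - 10), 1e-12)
  # already ultrametric at the target age: identity
  tr10 <- read_newick(text = "((a:5,b:5):5,c:10);")
  p10 <- prepare_empirical(tr10, crown_age = 10)
  expect_equal(p10$edge.length, tr10$edge.length)
  # a tip short by 0.001 is extended by exactly 0.001
  short <- read_newick(text = "((a:5,b:4.999):5,c:10);")
  ps <- prepare_empirical(short, crown_age = 10)
  d <- ape::node.depth.edgelength(ps)[1:3]
  expect_lt(max(abs(d - 10)), 1e-12)
  b_edge <- which(ps$edge[, 2] == which(ps$tip.label == "b"))
  expect_equal(ps$edge.length[b_edge], 5.000, tolerance = 1e-12)
  expect_error(prepare_empirical(ape::read.tree(text = "(a:1,b:1,c:1);")),
               "not fully bifurcating")
})

test_that("bootstrap with an oracle estimator is degenerate at the truth", {
  est <- c(lambda = 0.45, mu = 0.1)
  oracle <- function(tree) list(estimates = est)
  out <- bootstrap_uncertainty(est, "BD", n_boot = 5,
                               estimators = list(oracle = oracle),
                               rng_seed = 9)
  expect_true(all(out$summary$sd == 0))
  expect_equal(out$summary$mean, unname(est))
  expect_error(bootstrap_uncertainty(c(lambda = -1, mu = 0), "BD", 5,
                                     list(o = oracle)),
               class = "divnn_config_error")
})
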