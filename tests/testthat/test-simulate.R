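# Parameter samplers, Gillespie simulators, pruning and filtering.

test_that("samplers respect their boxes and dependent bounds", {
  set.seed(101)
  bd <- sample_params("BD", 10000)
  expect_true(all(bd$lambda >= 0.1 & bd$lambda <= 0.8))
  expect_true(all(bd$mu >= 0 & bd$mu <= 0.9 * bd$lambda))
  expect_gt(max(bd$mu), 0.65)   # supremum 0.72 is approached

  ddd <- sample_params("DDD", 10000)
  expect_true(all(ddd$lambda0 >= 0.1 & ddd$lambda0 <= 4))
  expect_true(all(ddd$mu0 <= pmin(0.9 * ddd$lambda0, 1.5)))
  # the 1.5 cap binds whenever 0.9 lambda0 > 1.5
  capped <- ddd$lambda0 > 1.5 / 0.9
  expect_true(any(capped))
  expect_true(all(ddd$mu0[capped] <= 1.5))
  expect_gt(max(ddd$mu0[capped]), 1.4)
  expect_true(all(ddd$K >= 10 & ddd$K <= 1000))

  pbd <- sample_params("PBD", 10000)
  expect_true(all(pbd$lambda2 >= 1e-3 & pbd$lambda2 <= 10))
  expect_true(all(pbd$mu1 <= 0.8 * pbd$lambda1))
  expect_true(all(pbd$mu2 <= 0.8 * pbd$lambda3))
  expect_error(sample_params("XX"), class = "divnn_config_error")
})

test_that("degenerate and pure-birth cases behave exactly", {
  set.seed(1)
  t0 <- sim_bd(list(lambda = 0, mu = 0), 7)
  expect_equal(ape::Ntip(t0), 2L)
  expect_true(all(attr(t0, "extant")))
  expect_equal(unname(t0$edge.length), c(7, 7))
  # mu = 0: no extinct tips in any replicate
  for (i in 1:20) {
    tr <- sim_bd(list(lambda = 0.4, mu = 0), 5)
    expect_true(all(attr(tr, "extant")))
  }
})

test_that("complete trees satisfy the structural invariants", {
  set.seed(7)
  for (i in 1:15) {
    tr <- sim_bd(list(lambda = 0.5, mu = 0.3), 8)
    n <- ape::Ntip(tr)
    expect_identical(n_nodes(tr), 2L * n - 1L)
    expect_identical(nrow(tr$edge), 2L * n - 2L)
    expect_true(ape::is.binary(tr))
    # extant tips end exactly at the crown age
    depth <- ape::node.depth.edgelength(tr)[seq_len(n)]
    ext <- attr(tr, "extant")
    if (any(ext)) expect_lt(max(abs(depth[ext] - 8)), 1e-9)
    if (any(!ext)) expect_true(all(depth[!ext] < 8))
  }
})

test_that("pruning yields ultrametric crown-age trees and counts match", {
  set.seed(12)
  for (i in 1:15) {
    tr <- sim_bd(list(lambda = 0.5, mu = 0.35), 8)
    p <- prune_extinct(tr)
    n_ext <- sum(attr(tr, "extant"))
    if (is_rejected(p)) {
      expect_true(n_ext < 2 || !attr(tr, "surviving"))
      next
    }
    expect_identical(ape::Ntip(p), n_ext)
    expect_true(ape::is.ultrametric(p, tol = 1e-9))
    expect_lt(abs(max(ape::node.depth.edgelength(p)) - 8), 1e-9)
  }
})

test_that("pruning is the identity on fully extant trees and exact on a toy", {
  set.seed(3)
  tr <- sim_bd(list(lambda = 0.4, mu = 0), 6)
  expect_identical(prune_extinct(tr), tr)
  # hand-built 3-tip complete tree with one extinct tip
  toy <- read_newick(text = "((a:4,b:10):2,c:12);")
  attr(toy, "crown_age") <- 12
  ext <- c(a = FALSE, b = TRUE, c = TRUE)
  attr(toy, "extant") <- ext[toy$tip.label]
  attr(toy, "surviving") <- TRUE
  p <- prune_extinct(toy)
  expect_identical(sort(p$tip.label), c("b", "c"))
  expect_equal(unname(ape::node.depth.edgelength(p)[1:2]), c(12, 12))
})

test_that("prune_extinct flags total and one-sided extinction as data", {
  toy <- read_newick(text = "((a:4,b:5):2,c:12);")
  attr(toy, "crown_age") <- 12
  attr(toy, "extant") <- setNames(c(FALSE, FALSE, FALSE), toy$tip.label)
  expect_true(is_rejected(prune_extinct(toy)))
  attr(toy, "extant") <- setNames(c(TRUE, TRUE, FALSE), toy$tip.label)
  attr(toy, "surviving") <- FALSE
  expect_true(is_rejected(prune_extinct(toy)))
})

test_that("node-count filter keeps exactly the in-bounds trees", {
  two_tip <- read_newick(text = "(a:1,b:1);")          # 3 nodes
  nine <- read_newick(text = "((a:1,b:1):1,((c:1,d:1):0.5,e:1.5):0.5);")
  big <- read_newick(text = paste0(paste(rep("(", 60), collapse = ""), "x0:1",
    paste(sprintf(",x%d:1):1", 1:60), collapse = ""), ";"))  # 121 nodes
  out <- filter_trees(list(two_tip, nine, big), node_min = 5, node_max = 120)
  expect_identical(out$kept, c(FALSE, TRUE, FALSE))
  expect_identical(out$n_below, 1L)
  expect_identical(out$n_above, 1L)
  expect_identical(n_nodes(nine), 9L)
})

test_that("identical seeds reproduce identical tree sets", {
  a <- sim_trees(sim_config("DDD", n_trees = 4, rng_seed = 99))
  b <- sim_trees(sim_config("DDD", n_trees = 4, rng_seed = 99))
  expect_identical(a$params, b$params)
  expect_equal(a$trees, b$trees)
  expect_true(all(vapply(a$trees, function(tr)
    abs(max(ape::node.depth.edgelength(tr)) - 10) < 1e-9, TRUE)))
})

test_that("diversity dependence: rate law and the BD limit", {
  expect_equal(ddd_speciation_rate(0, 2, 0.2, 40), 2)
  # zero-speciation diversity K' = K lambda0 / (lambda0 - mu0)
  kp <- 40 * 2 / (2 - 0.2)
  expect_equal(ddd_speciation_rate(kp, 2, 0.2, 40), 0)
  expect_equal(ddd_speciation_rate(kp + 10, 2, 0.2, 40), 0)
  expect_equal(ddd_speciation_rate(123, 2, 0.2, Inf), 2)
})

test_that("DDD extant diversity matches a master-equation oracle", {
  skip_if_not_installed("Matrix")
  lambda0 <- 2; mu0 <- 0.2; K <- 40; age <- 10
  # birth-death chain on 0..200 with the linear rate law, started at 2
  S <- 201L
  n <- 0:(S - 1L)
  birth <- n * ddd_speciation_rate(n, lambda0, mu0, K)
  death <- n * mu0
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(S - 1L), seq_len(S - 1L) + 1L, seq_len(S)),
    j = c(seq_len(S - 1L) + 1L, seq_len(S - 1L), seq_len(S)),
    x = c(birth[seq_len(S - 1L)], death[seq_len(S - 1L) + 1L],
          -(birth + death)))
  p0 <- rep(0, S); p0[3L] <- 1   # state 2
  pt <- as.numeric(p0 %*% Matrix::expm(Q * age))
  mean_oracle <- sum(n * pt)
  set.seed(55)
  reps <- 2000
  counts <- vapply(seq_len(reps), function(i) {
    tr <- sim_ddd(list(lambda0 = lambda0, mu0 = mu0, K = K), age)
    sum(attr(tr, "extant"))
  }, numeric(1))
  se <- sd(counts) / sqrt(reps)
  expect_lt(abs(mean(counts) - mean_oracle), 3 * se)
  # diversity concentrates near the zero-speciation diversity K'
  expect_lt(abs(median(counts) - 40 * 2 / 1.8), 8)
})

test_that("protracted simulator matches an independent implementation", {
  pars <- list(lambda1 = 0.3, lambda2 = 0.1, lambda3 = 0.3,
               mu1 = 0.05, mu2 = 0.05)
  reps <- 1200
  set.seed(77)
  mine <- vapply(seq_len(reps), function(i) {
    cp <- sim_pbd(pars, 8)$complete
    ext <- attr(cp, "extant")
    length(unique(attr(cp, "species")[ext]))
  }, numeric(1))
  set.seed(78)
  other <- vapply(seq_len(reps), function(i)
    oracle_pbd_species_count(0.3, 0.1, 0.3, 0.05, 0.05, 8), numeric(1))
  se <- sqrt(var(mine) / reps + var(other) / reps)
  expect_lt(abs(mean(mine) - mean(other)), 3 * se)
})

test_that("protracted limits: instantaneous completion approaches BD", {
  set.seed(31)
  reps <- 400
  pb <- vapply(seq_len(reps), function(i) {
    st <- sim_pbd(list(lambda1 = 0.4, lambda2 = 1e6, lambda3 = 0.4,
                       mu1 = 0, mu2 = 0), 6)$species_tree
    if (is_rejected(st)) 0 else ape::Ntip(st)
  }, numeric(1))
  # with instant completion and no extinction every lineage is a species:
  # mean species count equals the pure-birth mean 2 e^{lambda t}
  expect_lt(abs(mean(pb) - 2 * exp(0.4 * 6)), 3 * sd(pb) / sqrt(reps))
})

test_that("species trees collapse conspecific incipients and stay ultrametric", {
  set.seed(91)
  found <- 0
  for (i in 1:30) {
    out <- sim_pbd(list(lambda1 = 0.5, lambda2 = 0.3, lambda3 = 0.5,
                        mu1 = 0.05, mu2 = 0.05), 8)
    st <- out$species_tree
    if (is_rejected(st)) next
    found <- found + 1
    expect_true(ape::is.ultrametric(st, tol = 1e-9))
    expect_lt(abs(max(ape::node.depth.edgelength(st)) - 8), 1e-9)
    # one representative per extant species
    sp_all <- attr(out$complete, "species")[attr(out$complete, "extant")]
    expect_identical(ape::Ntip(st), length(unique(sp_all)))
  }
  expect_gt(found, 5)
})
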