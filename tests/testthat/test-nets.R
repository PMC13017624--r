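# Architectures: shape contracts, analytic gradients vs numerical
# differentiation, invariances of the three encoders' networks.

small_ds <- function() shared("small_ds", function() {
  co <- bd_corpus()
  divnn:::subset_dataset(co$ds, order(vapply(co$ds$bt, length, 1L))[1:10])
})

test_that("output dimensionality follows the scenario", {
  for (sc in c("BD", "DDD", "PBD")) {
    p <- length(param_names(sc))
    set.seed(1)
    d <- build_dnn(sc, width = 8)
    out <- divnn:::cpp_dnn_pass(d$params, matrix(0, 3, 54), NULL, d$bn,
                                FALSE, 1, FALSE, FALSE)
    expect_identical(dim(out$pred), c(3L, p))
    expect_true(all(is.finite(out$pred)))
    l <- build_lstm(sc, hidden = 6)
    out <- divnn:::cpp_lstm_pass(l$params, matrix(1, 2, 4), c(4L, 2L), NULL,
                                 1, FALSE, FALSE)
    expect_identical(dim(out$pred), c(2L, p))
    g <- build_gnn(sc, width = 5, clusters = c(4, 3))
    ds <- small_ds()
    out <- divnn:::cpp_gnn_pass(g$params, ds$graphs[1:2], NULL, g$bn, FALSE,
                                1, 1, FALSE, FALSE)
    expect_identical(dim(out$pred), c(2L, p))
    expect_true(all(is.finite(out$pred)))
  }
})

test_that("analytic gradients match numerical differentiation", {
  ds <- small_ds()
  Y <- scale(ds$y)
  attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
  set.seed(42)
  # dense network
  m <- build_dnn("BD", width = 6)
  ps <- divnn:::cpp_dnn_pass(m$params, ds$ss, Y, m$bn, TRUE, 1, TRUE, FALSE)
  fval <- function(p) divnn:::cpp_dnn_pass(p, ds$ss, Y, m$bn, TRUE, 1,
                                           FALSE, FALSE)$loss
  for (k in c("W1", "b1", "g1", "be1", "W4", "Wr"))
    expect_grad_close(ps$grads[[k]], num_grad_entries(fval, m$params, k))
  # recurrent network
  m <- build_lstm("BD", hidden = 5)
  pb <- divnn:::pad_bt(ds$bt)
  ps <- divnn:::cpp_lstm_pass(m$params, pb$X, pb$lens, Y, 1, TRUE, FALSE)
  fval <- function(p) divnn:::cpp_lstm_pass(p, pb$X, pb$lens, Y, 1,
                                            FALSE, FALSE)$loss
  for (k in c("Wx1", "Wh1", "bl1", "Wx3", "Wh5", "Wf", "Wr"))
    expect_grad_close(ps$grads[[k]], num_grad_entries(fval, m$params, k))
  # graph network (includes the DiffPool assignment path)
  m <- build_gnn("BD", width = 4, clusters = c(3, 2))
  ps <- divnn:::cpp_gnn_pass(m$params, ds$graphs, Y, m$bn, TRUE, 1, 1,
                             TRUE, FALSE)
  fval <- function(p) divnn:::cpp_gnn_pass(p, ds$graphs, Y, m$bn, TRUE, 1, 1,
                                           FALSE, FALSE)$loss
  for (k in c("Wsm1a", "Wnm1a", "bbm1a", "ggm1a", "Wsm3b", "Wp1", "Wp2",
              "Wr1", "br2"))
    expect_grad_close(ps$grads[[k]], num_grad_entries(fval, m$params, k))
})

test_that("stacked model gradients flow into all four components", {
  ds <- small_ds()
  Y <- scale(ds$y)
  attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
  set.seed(43)
  m <- build_stack("BD", dnn_width = 5, lstm_hidden = 4, gnn_width = 3,
                   clusters = c(3, 2))
  pb <- divnn:::pad_bt(ds$bt)
  xss <- scale(ds$ss); xss[!is.finite(xss)] <- 0
  pass <- function(pd, pl, pg, pm, grads)
    divnn:::cpp_stack_pass(pd, pl, pg, pm, xss, pb$X, pb$lens, ds$graphs, Y,
                           m$bn$dnn, m$bn$gnn, TRUE, 1, 1, grads)
  ps <- pass(m$params$dnn, m$params$lstm, m$params$gnn, m$params$meta, TRUE)
  f_meta <- function(p) pass(m$params$dnn, m$params$lstm, m$params$gnn, p, FALSE)$loss
  expect_grad_close(ps$grads$meta$Wm, num_grad_entries(f_meta, m$params$meta, "Wm"))
  f_dnn <- function(p) pass(p, m$params$lstm, m$params$gnn, m$params$meta, FALSE)$loss
  expect_grad_close(ps$grads$dnn$W2, num_grad_entries(f_dnn, m$params$dnn, "W2"))
  f_lstm <- function(p) pass(m$params$dnn, p, m$params$gnn, m$params$meta, FALSE)$loss
  expect_grad_close(ps$grads$lstm$Wh2, num_grad_entries(f_lstm, m$params$lstm, "Wh2"))
  f_gnn <- function(p) pass(m$params$dnn, m$params$lstm, p, m$params$meta, FALSE)$loss
  expect_grad_close(ps$grads$gnn$Wsm1a, num_grad_entries(f_gnn, m$params$gnn, "Wsm1a"))
})

test_that("the graph network is invariant to node relabelling", {
  ds <- small_ds()
  set.seed(3)
  m <- build_gnn("BD", width = 6)
  g1 <- ds$graphs[[3]]
  N <- nrow(g1$node_features)
  perm <- sample(N)
  inv <- order(perm)
  g2 <- g1
  g2$node_features <- g1$node_features[perm, , drop = FALSE]
  g2$edge_index <- matrix(inv[g1$edge_index], nrow = 2)
  o1 <- divnn:::cpp_gnn_pass(m$params, list(g1), NULL, m$bn, FALSE, 1, 1,
                             FALSE, FALSE)$pred
  o2 <- divnn:::cpp_gnn_pass(m$params, list(g2), NULL, m$bn, FALSE, 1, 1,
                             FALSE, FALSE)$pred
  expect_lt(max(abs(o1 - o2)), 1e-5)
})

test_that("masking makes padding irrelevant but order matters", {
  set.seed(4)
  m <- build_lstm("BD", hidden = 6)
  x <- matrix(c(10, 6, 3, 1), 1, 4)
  p1 <- divnn:::cpp_lstm_pass(m$params, x, 4L, NULL, 1, FALSE, FALSE)$pred
  p2 <- divnn:::cpp_lstm_pass(m$params, cbind(x, 99, 99), 4L, NULL, 1,
                              FALSE, FALSE)$pred
  expect_identical(p1, p2)
  p3 <- divnn:::cpp_lstm_pass(m$params, x[, 4:1, drop = FALSE], 4L, NULL, 1,
                              FALSE, FALSE)$pred
  expect_gt(max(abs(p1 - p3)), 1e-8)
})

test_that("inference is deterministic and batch-size independent", {
  ds <- bd_corpus()$ds
  set.seed(6)
  models <- list(build_dnn("BD", width = 8), build_lstm("BD", hidden = 6),
                 build_gnn("BD", width = 6))
  for (m in models) {
    p_all <- divnn:::predict_raw(m, ds)
    expect_identical(p_all, divnn:::predict_raw(m, ds))
    expect_true(all(is.finite(p_all)))
    p_one <- divnn:::predict_raw(m, divnn:::subset_dataset(ds, 7L))
    expect_lt(max(abs(p_one - p_all[7L, ])), 1e-5)
  }
})
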