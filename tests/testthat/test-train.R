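# Splitting, losses, optimisation, capacity and diagnostics.

test_that("dataset splits are seeded, disjoint and correctly sized", {
  sp <- split_dataset(1000, 0.9, rng_seed = 5)
  expect_identical(length(sp$train), 900L)
  expect_identical(length(sp$validation), 100L)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_identical(sort(c(sp$train, sp$validation)), 1:1000)
  expect_identical(split_dataset(1000, 0.9, rng_seed = 5), sp)
  sp10 <- split_dataset(10, 0.9, rng_seed = 1)
  expect_identical(length(sp10$train), 9L)
  expect_identical(length(sp10$validation), 1L)
  expect_error(split_dataset(0), class = "divnn_config_error")
  expect_error(split_dataset(10, 1.2), class = "divnn_config_error")
})

test_that("huber and total loss follow their closed forms", {
  expect_identical(huber_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(huber_loss(0.3, 0), 0.5 * 0.3^2)      # quadratic regime
  expect_equal(huber_loss(2, 0, delta = 1), 1 * (2 - 0.5))  # linear regime
  expect_equal(total_loss(0.3, 0, aux_terms = c(0.2, 0.1), aux_weight = 2),
               0.5 * 0.09 + 2 * 0.3)
  expect_gte(total_loss(rnorm(5), rnorm(5), aux_terms = runif(3)),
             huber_loss(rnorm(5) * 0, rnorm(5) * 0))
  expect_error(huber_loss(NA, 1), class = "divnn_data_error")
})

test_that("initial loss is close to the constant mid-predictor's loss", {
  ds <- bd_corpus()$ds
  set.seed(8)
  m <- build_dnn("BD", width = 8)
  # standardise as fit would, then compare the untrained network's loss to
  # predicting the training mean (zero on the standardised scale)
  m$norm$y_center <- colMeans(ds$y)
  m$norm$y_scale <- apply(ds$y, 2, sd)
  m$norm$x_center <- colMeans(ds$ss)
  m$norm$x_scale <- pmax(apply(ds$ss, 2, sd), 1e-12)
  ps <- divnn:::model_pass(m, ds, training = FALSE)
  y_std <- sweep(sweep(ds$y, 2, m$norm$y_center), 2, m$norm$y_scale, "/")
  const_loss <- huber_loss(y_std * 0, y_std)
  expect_gt(ps$loss / const_loss, 0.5)
  expect_lt(ps$loss / const_loss, 2)
})

test_that("all three architectures memorise a 50-tree fixture", {
  ds <- shared("memo_ds", function() {
    set.seed(500)
    pars <- sample_params("BD", 50)
    trees <- lapply(seq_len(50), function(i) {
      repeat {
        tr <- prune_extinct(sim_bd(as.list(pars[i, ]), 10))
        if (!is_rejected(tr) && ape::Ntip(tr) >= 3 && ape::Ntip(tr) <= 40)
          return(tr)
      }
    })
    encode_dataset(trees, pars, "BD")
  })
  memo_cfg <- function(ep) train_config(n_epochs = ep, batch_size = 50,
                                        lr = 3e-3, weight_decay = 0,
                                        aux_weight = 0, rng_seed = 11,
                                        keep_best = FALSE)
  # feed-forward and graph networks drive the loss to a sub-percent
  # fraction of the epoch-1 loss in 200 epochs
  for (builder in list(function() build_dnn("BD", width = 16),
                       function() build_gnn("BD", width = 8))) {
    m <- fit_model(divnn:::with_seed(2, builder()), ds, memo_cfg(200))
    h <- m$history$train_loss
    expect_lt(h[length(h)], 0.01 * h[1])
  }
  # the stacked recurrent network optimises markedly more slowly on
  # whole-sequence regression; it still collapses the loss by an order of
  # magnitude given longer training
  m <- fit_model(divnn:::with_seed(2, build_lstm("BD", hidden = 16)), ds,
                 memo_cfg(600))
  h <- m$history$train_loss
  expect_lt(h[length(h)], 0.1 * h[1])
})

test_that("training is reproducible from its seed", {
  co <- bd_corpus()
  ds <- divnn:::subset_dataset(co$ds, 1:30)
  cfg <- train_config(n_epochs = 3, rng_seed = 21)
  m1 <- fit_model(divnn:::with_seed(5, build_dnn("BD", width = 8)), ds, cfg)
  m2 <- fit_model(divnn:::with_seed(5, build_dnn("BD", width = 8)), ds, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("fit records history and validation MAE on the natural scale", {
  co <- bd_corpus()
  ds <- divnn:::subset_dataset(co$ds, 1:40)
  m <- fit_model(divnn:::with_seed(5, build_dnn("BD", width = 8)), ds,
                 train_config(n_epochs = 4, rng_seed = 3))
  expect_identical(nrow(m$history), 4L)
  expect_true(all(c("train_loss", "val_loss", "mae_lambda", "mae_mu") %in%
                    names(m$history)))
  expect_true(all(is.finite(unlist(m$history))))
  expect_true(m$trained)
})

test_that("fit diagnostics flag the canonical loss-curve shapes", {
  overfit <- data.frame(train_loss = seq(1, 0.1, length.out = 10),
                        val_loss = c(seq(0.9, 0.5, length.out = 5),
                                     seq(0.55, 0.9, length.out = 5)))
  d <- diagnose_fit(overfit, window = 5)
  expect_true(d$overfit)
  expect_false(d$underfit)
  expect_identical(d$best_epoch, which.min(overfit$val_loss))
  underfit <- data.frame(train_loss = seq(10, 8, length.out = 10),
                         val_loss = seq(10.5, 8.4, length.out = 10))
  d <- diagnose_fit(underfit, window = 5)
  expect_true(d$underfit)
  expect_false(d$overfit)
  plateau <- data.frame(train_loss = c(seq(1, 0.2, length.out = 8), 0.2, 0.2),
                        val_loss = c(seq(1.1, 0.25, length.out = 8), 0.25, 0.25))
  d <- diagnose_fit(plateau, window = 4)
  expect_false(d$overfit)
  expect_false(d$underfit)
  expect_error(diagnose_fit(overfit[1:2, ]), class = "divnn_config_error")
})
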