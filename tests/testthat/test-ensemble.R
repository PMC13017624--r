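# Bagging algebra, stacking contracts and joint training, boosting
# composition.

trained_gnn <- function() shared("trained_gnn", function() {
  co <- bd_corpus()
  g <- divnn:::with_seed(14, build_gnn("BD", width = 8))
  fit_model(g, co$ds, train_config(n_epochs = 2, rng_seed = 15))
})

test_that("bagging aggregators act element-wise with exact identities", {
  a <- matrix(c(1, 1, 1, 1), 2)
  b <- matrix(c(2, 2, 2, 2), 2)
  c9 <- matrix(c(9, 9, 9, 9), 2)
  expect_identical(bag_predictions(list(a, b, c9), "median"), b)
  expect_identical(bag_predictions(list(a, b, c9), "mean"), (a + b + c9) / 3)
  expect_identical(bag_predictions(list(a, b, c9), "min"), a)
  expect_identical(bag_predictions(list(a, b, c9), "max"), c9)
  # k identical learners: identity under every aggregator
  for (agg in c("median", "mean", "max", "min"))
    expect_identical(bag_predictions(list(b, b, b), agg), b)
  # min and max bracket the mean
  set.seed(2)
  preds <- replicate(4, matrix(rnorm(6), 2), simplify = FALSE)
  lo <- bag_predictions(preds, "min")
  hi <- bag_predictions(preds, "max")
  mid <- bag_predictions(preds, "mean")
  expect_true(all(lo <= mid & mid <= hi))
  expect_error(bag_predictions(list(a, matrix(0, 3, 2))), "shapes differ")
  expect_error(bag_predictions(list(a)), class = "divnn_config_error")
})

test_that("stacking meta-learner consumes the concatenated feature widths", {
  set.seed(9)
  s <- build_stack("DDD", dnn_width = 10, lstm_hidden = 7, gnn_width = 5)
  expect_identical(nrow(s$params$meta$Wm), 2L * 5L + 5L * 10L + 7L)
  expect_identical(ncol(s$params$meta$Wm), 3L)
})

test_that("joint stack training decreases the total loss", {
  co <- bd_corpus()
  s <- divnn:::with_seed(10, build_stack("BD", dnn_width = 8, lstm_hidden = 6,
                                         gnn_width = 4))
  s <- fit_model(s, co$ds, train_config(n_epochs = 5, batch_size = 16,
                                        rng_seed = 12))
  expect_lt(s$history$train_loss[5], s$history$train_loss[1])
  p <- predict(s, divnn:::subset_dataset(co$ds, 1:4))
  expect_identical(dim(p), c(4L, 2L))
  expect_true(all(is.finite(p)))
})

test_that("boosting with zero correctors reproduces the base exactly", {
  co <- bd_corpus()
  g <- trained_gnn()
  zc <- divnn:::with_seed(1, build_lstm("BD", hidden = 4))
  zc$params$Wr[] <- 0; zc$params$br[] <- 0
  zc$trained <- TRUE
  b <- structure(list(base = g, correctors = list(zc), order = "BT",
                      scenario = "BD", n_params = 2), class = "divnn_boost")
  sub <- divnn:::subset_dataset(co$ds, 1:8)
  expect_lt(max(abs(predict(b, sub) - predict(g, sub))), 1e-12)
})

test_that("staged contributions sum exactly to the boosted prediction", {
  co <- bd_corpus()
  g <- trained_gnn()
  b <- boost_fit(g, co$ds, c("SS", "BT"),
                 train_config(n_epochs = 2, rng_seed = 16),
                 dnn_width = 8, lstm_hidden = 4)
  sub <- divnn:::subset_dataset(co$ds, 1:8)
  p <- predict(b, sub, stages = TRUE)
  st <- attr(p, "stages")
  expect_identical(length(st), 3L)
  expect_lt(max(abs(Reduce(`+`, st) - divnn:::transform_targets(p, "BD"))),
            1e-10)
})

test_that("truncating a longer boost chain reproduces the shorter variant", {
  co <- bd_corpus()
  g <- trained_gnn()
  cfg <- train_config(n_epochs = 2, rng_seed = 16)
  b2 <- boost_fit(g, co$ds, c("SS", "BT"), cfg, dnn_width = 8, lstm_hidden = 4)
  b1 <- boost_fit(g, co$ds, "SS", cfg, dnn_width = 8, lstm_hidden = 4)
  sub <- divnn:::subset_dataset(co$ds, 1:10)
  expect_lt(max(abs(predict(boost_truncate(b2, 1), sub) - predict(b1, sub))),
            1e-12)
  expect_lt(max(abs(predict(boost_truncate(b2, 0), sub) -
                      predict(g, sub))), 1e-12)
  expect_error(boost_fit(g, co$ds, c("SS", "SS")),
               class = "divnn_config_error")
})

test_that("a summary-statistic corrector recovers a planted residual signal", {
  co <- bd_corpus()
  g <- trained_gnn()
  base_pred <- divnn:::predict_raw(g, co$ds)
  # plant: truth = base prediction + linear function of three statistics
  z <- scale(co$ds$ss[, c("n_tips", "gamma", "colless")])
  planted <- cbind(0.4 * z[, 1] - 0.2 * z[, 2], 0.3 * z[, 3])
  ds2 <- co$ds
  ds2$y <- base_pred + planted
  b <- boost_fit(g, ds2, "SS",
                 train_config(n_epochs = 150, batch_size = 60, lr = 3e-3,
                              weight_decay = 0, rng_seed = 17,
                              keep_best = FALSE), dnn_width = 16)
  corr <- divnn:::predict_raw(b$correctors[[1]], ds2)
  mse <- mean((corr - planted)^2)
  expect_lt(mse, 0.1 * mean(scale(planted, scale = FALSE)^2))
})
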