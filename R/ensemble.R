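# Ensemble strategies over the three base learners: bagging (element-wise
# aggregation of independent predictions), stacking (a jointly trained
# linear meta-learner over the concatenated penultimate features), and
# sequential residual boosting with the graph network as base learner.

#' Aggregate predictions from independently trained learners
#'
#' Element-wise aggregation of two or more prediction matrices of identical
#' shape. The median is the default: in practice the other aggregators are
#' markedly less accurate.
#'
#' @param predictions List of numeric matrices (trees x parameters).
#' @param aggregator One of `"median"`, `"mean"`, `"max"`, `"min"`.
#' @return A matrix of the aggregated predictions.
#' @export
bag_predictions <- function(predictions,
                            aggregator = c("median", "mean", "max", "min")) {
  aggregator <- match.arg(aggregator)
  if (!is.list(predictions) || length(predictions) < 2L)
    stop_config("need at least two prediction matrices")
  d <- dim(predictions[[1L]])
  for (p in predictions)
    if (!identical(dim(p), d)) stop_data("prediction shapes differ")
  arr <- simplify2array(predictions)
  fun <- switch(aggregator, median = median, mean = mean, max = max, min = min)
  out <- apply(arr, c(1L, 2L), fun)
  dimnames(out) <- dimnames(predictions[[1L]])
  out
}

#' Build a stacking ensemble
#'
#' The three base architectures without their readout layers feed their
#' penultimate features (graph representation, dense features, recurrent
#' features) into a linear meta-learner emitting one value per parameter.
#' All four components are trained jointly by [fit_model()].
#'
#' @inheritParams build_dnn
#' @param dnn_width,lstm_hidden,gnn_width,clusters Base architecture sizes
#'   (see [build_dnn()], [build_lstm()], [build_gnn()]).
#' @return A model of class `c("divnn_stack", "divnn_model")`.
#' @export
build_stack <- function(scenario, dnn_width = 64L, lstm_hidden = 32L,
                        gnn_width = 16L, clusters = c(8L, 4L)) {
  scenario <- match_scenario(scenario)
  d <- build_dnn(scenario, dnn_width)
  l <- build_lstm(scenario, lstm_hidden)
  g <- build_gnn(scenario, gnn_width, clusters)
  p <- n_params_for(scenario)
  feat_dim <- 2L * gnn_width + 5L * dnn_width + lstm_hidden
  strip <- function(pr, drop) pr[setdiff(names(pr), drop)]
  m <- new_model("stack", scenario,
                 cfg = list(dnn_width = dnn_width, lstm_hidden = lstm_hidden,
                            gnn_width = gnn_width, clusters = clusters,
                            feat_dim = feat_dim),
                 params = list(dnn = strip(d$params, c("Wr", "br")),
                               lstm = strip(l$params, c("Wr", "br")),
                               gnn = strip(g$params, c("Wr1", "br1", "Wr2", "br2")),
                               meta = list(Wm = glorot(feat_dim, p),
                                           bm = zeros(1, p))),
                 bn = list(dnn = d$bn, gnn = g$bn))
  m
}

# ---------------------------------------------------------------------------
# boosting

#' Sequential residual boosting on a graph-network base
#'
#' Trains (or reuses) a GNN base learner, then trains correctors
#' sequentially on residuals, each on its own representation of the same
#' trees: `"SS"` fits a dense network to the residuals from the summary
#' statistics, `"BT"` fits an LSTM to them from the branching times. With
#' residuals defined as `truth - prediction` on the network output scale,
#' the first corrector targets `r1 = y - pred_base`, the second
#' `r2 = r1 - r1_hat`, and the boosted prediction adds every fitted
#' correction to the base prediction, so perfect correctors recover the
#' truth exactly. The four variants of interest are Boost SS (`"SS"`),
#' Boost BT (`"BT"`), Boost SS+BT (`c("SS","BT")`) and Boost BT+SS
#' (`c("BT","SS")`).
#'
#' @param base A `divnn_gnn` model (trained, or untrained in which case it
#'   is trained first with `config`).
#' @param dataset A `divnn_dataset` with targets.
#' @param corrector_order Character vector over `"SS"`, `"BT"` giving the
#'   correction sequence (no immediate duplicates).
#' @param config [train_config()] used for base (if needed) and correctors.
#' @param dnn_width,lstm_hidden Corrector sizes.
#' @return An object of class `divnn_boost`.
#' @export
boost_fit <- function(base, dataset, corrector_order = "BT",
                      config = train_config(), dnn_width = 64L,
                      lstm_hidden = 32L) {
  stopifnot(inherits(base, "divnn_gnn"))
  if (length(corrector_order) < 1L ||
      !all(corrector_order %in% c("SS", "BT")) ||
      any(corrector_order[-1L] == head(corrector_order, -1L)))
    stop_config("corrector_order must be a sequence over SS/BT without immediate repeats")
  if (!base$trained) base <- fit_model(base, dataset, config)
  resid <- dataset$y - predict_raw(base, dataset)
  correctors <- vector("list", length(corrector_order))
  for (i in seq_along(corrector_order)) {
    kind <- corrector_order[i]
    cds <- dataset
    cds$y <- resid
    # corrector initialisation is tied to the training seed so that a
    # truncated longer variant reproduces the shorter one exactly
    init_seed <- if (is.null(config$rng_seed)) NULL
                 else config$rng_seed + 1000L * i
    cm <- with_seed(init_seed, {
      m0 <- if (kind == "SS") build_dnn(dataset$scenario, dnn_width)
            else build_lstm(dataset$scenario, lstm_hidden)
      fit_model(m0, cds, config)
    })
    correctors[[i]] <- cm
    resid <- resid - predict_raw(cm, dataset)
  }
  structure(list(base = base, correctors = correctors,
                 order = corrector_order, scenario = dataset$scenario,
                 n_params = base$n_params),
            class = c("divnn_boost"))
}

# transformed-scale staged predictions of a boosted model
boost_raw <- function(object, ds) {
  stages <- list(base = predict_raw(object$base, ds))
  for (i in seq_along(object$correctors))
    stages[[paste0("corr", i, "_", object$order[i])]] <-
      predict_raw(object$correctors[[i]], ds)
  stages
}

#' Predict with a boosted model
#'
#' Deterministic composition of the base prediction and the fitted residual
#' corrections; with `stages = TRUE` the per-stage contributions (on the
#' network output scale) are attached, and they sum exactly to the final
#' transformed prediction.
#'
#' @param object A `divnn_boost` model.
#' @param trees List of trees or a `divnn_dataset`.
#' @param stages Attach per-stage contributions as an attribute.
#' @param ... Unused.
#' @return Matrix of natural-scale estimates (attribute `"stages"` when
#'   requested).
#' @export
predict.divnn_boost <- function(object, trees, stages = FALSE, ...) {
  ds <- if (inherits(trees, "divnn_dataset")) trees
        else encode_dataset(trees, NULL, object$scenario)
  st <- boost_raw(object, ds)
  tot <- Reduce(`+`, st)
  colnames(tot) <- param_names(object$scenario)
  out <- untransform_targets(tot, object$scenario)
  if (stages) attr(out, "stages") <- st
  out
}

#' Truncate a boosted model to its first correction stages
#'
#' `boost_truncate(m, 1)` of a Boost SS+BT model reproduces the Boost SS
#' model trained under the same seeds.
#'
#' @param object A `divnn_boost`.
#' @param n_correctors Number of correctors to keep (0 = base GNN only).
#' @return A `divnn_boost` with the leading correctors.
#' @export
boost_truncate <- function(object, n_correctors) {
  stopifnot(inherits(object, "divnn_boost"),
            n_correctors >= 0L, n_correctors <= length(object$correctors))
  object$correctors <- object$correctors[seq_len(n_correctors)]
  object$order <- object$order[seq_len(n_correctors)]
  object
}

#' @export
print.divnn_boost <- function(x, ...) {
  cat(sprintf("<divnn boosted model: GNN base + [%s], scenario %s>\n",
              paste(x$order, collapse = " -> "), x$scenario))
  invisible(x)
}
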