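# Model constructors and prediction for the three base architectures.
#
# All networks regress the scenario's parameter vector (2 for BD, 3 for DDD,
# 5 for PBD). Parameters spanning orders of magnitude -- the carrying
# capacity K and the speciation-completion rate lambda2 -- are regressed on
# the log scale and exponentiated at readout; targets are additionally
# standardised with training-split statistics stored in the model, so the
# Huber delta acts on a comparable scale for every parameter.

n_params_for <- function(scenario) length(param_names(scenario))

# Columns regressed on the log scale, per scenario.
log_scale_cols <- function(scenario) {
  switch(match_scenario(scenario), BD = integer(0), DDD = 3L, PBD = 2L)
}

#' Transform parameters to and from the network output scale
#'
#' The carrying capacity (DDD) and the speciation-completion rate (PBD) are
#' learned on the natural-log scale; other parameters are untouched.
#'
#' @param y Numeric matrix (rows = trees, columns = [param_names()]).
#' @param scenario Scenario string.
#' @return Matrix of the same shape.
#' @export
transform_targets <- function(y, scenario) {
  y <- as.matrix(y)
  for (j in log_scale_cols(scenario)) y[, j] <- log(y[, j])
  y
}

#' @rdname transform_targets
#' @export
untransform_targets <- function(y, scenario) {
  y <- as.matrix(y)
  for (j in log_scale_cols(scenario)) y[, j] <- exp(y[, j])
  y
}

glorot <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}
zeros <- function(nr, nc) matrix(0, nr, nc)
ones <- function(nr, nc) matrix(1, nr, nc)

#' Build a dense network on summary statistics
#'
#' Five linear layers, each followed by batch normalisation and a GELU; the
#' outputs of all five layers are concatenated into a single linear readout
#' emitting one value per scenario parameter. Weights are initialised from
#' the ambient RNG (seed with [set.seed()]).
#'
#' @param scenario `"BD"`, `"DDD"` or `"PBD"` (fixes the output length).
#' @param width Hidden width of each layer.
#' @param input_dim Input dimension (the 54 summary statistics).
#' @return A model of class `c("divnn_dnn", "divnn_model")`.
#' @export
build_dnn <- function(scenario, width = 64L, input_dim = 54L) {
  scenario <- match_scenario(scenario)
  if (width < 1L) stop_config("width must be positive")
  p <- n_params_for(scenario)
  pr <- list()
  din <- input_dim
  for (k in 1:5) {
    pr[[paste0("W", k)]] <- glorot(din, width)
    pr[[paste0("b", k)]] <- zeros(1, width)
    pr[[paste0("g", k)]] <- ones(1, width)
    pr[[paste0("be", k)]] <- zeros(1, width)
    din <- width
  }
  pr$Wr <- glorot(5L * width, p)
  pr$br <- zeros(1, p)
  bn <- list()
  for (k in 1:5) {
    bn[[paste0("rm", k)]] <- zeros(1, width)
    bn[[paste0("rv", k)]] <- ones(1, width)
  }
  new_model("dnn", scenario,
            cfg = list(width = width, input_dim = input_dim),
            params = pr, bn = bn)
}

#' Build a stacked LSTM on branching-time sequences
#'
#' Five stacked LSTM layers consume the branching times past-to-present
#' (padded sequences are masked, so padding provably does not change the
#' output); the final hidden state passes through a GELU-activated linear
#' layer and a linear readout.
#'
#' @inheritParams build_dnn
#' @param hidden Hidden state size of each recurrent layer.
#' @return A model of class `c("divnn_lstm", "divnn_model")`.
#' @export
build_lstm <- function(scenario, hidden = 32L) {
  scenario <- match_scenario(scenario)
  if (hidden < 1L) stop_config("hidden must be positive")
  p <- n_params_for(scenario)
  pr <- list()
  din <- 1L
  for (l in 1:5) {
    pr[[paste0("Wx", l)]] <- glorot(din, 4L * hidden)
    pr[[paste0("Wh", l)]] <- glorot(hidden, 4L * hidden)
    b <- zeros(1, 4L * hidden)
    b[1, (hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
    pr[[paste0("bl", l)]] <- b
    din <- hidden
  }
  pr$Wf <- glorot(hidden, hidden)
  pr$bf <- zeros(1, hidden)
  pr$Wr <- glorot(hidden, p)
  pr$br <- zeros(1, p)
  new_model("lstm", scenario, cfg = list(hidden = hidden), params = pr,
            bn = list())
}

gnn_op_ids <- function() {
  as.vector(t(outer(paste0("m", 1:5), c("a", "b"), paste0)))
}

#' Build a graph network with differentiable pooling
#'
#' Five GraphSAGE-style modules of two mean-aggregation operators each
#' (operator outputs concatenated within a module, each operator followed by
#' batch normalisation and GELU). Two DiffPool coarsenings assign nodes to
#' `clusters[1]` and then `clusters[2]` clusters, contributing
#' link-prediction and assignment-entropy auxiliary losses; a final module,
#' global mean pooling, and a two-layer readout (GELU after the first layer
#' only) produce the parameter predictions. Two operators per module are
#' used throughout: deeper message passing destabilises training on
#' tree-shaped graphs.
#'
#' @inheritParams build_dnn
#' @param width Output width of each GraphSAGE operator.
#' @param clusters Integer vector of length 2: cluster counts of the two
#'   DiffPool coarsenings.
#' @return A model of class `c("divnn_gnn", "divnn_model")`.
#' @export
build_gnn <- function(scenario, width = 16L, clusters = c(8L, 4L)) {
  scenario <- match_scenario(scenario)
  if (width < 1L) stop_config("width must be positive")
  if (length(clusters) != 2L || any(clusters < 2L))
    stop_config("clusters must be two integers >= 2")
  p <- n_params_for(scenario)
  w2 <- 2L * width
  pr <- list()
  bn <- list()
  din_a <- c(3L, 3L, w2, w2, w2)  # first operator of each module
  ids <- gnn_op_ids()
  for (i in seq_along(ids)) {
    id <- ids[i]
    din <- if (substr(id, 3, 3) == "a") din_a[(i + 1L) %/% 2L] else width
    pr[[paste0("Ws", id)]] <- glorot(din, width)
    pr[[paste0("Wn", id)]] <- glorot(din, width)
    pr[[paste0("bb", id)]] <- zeros(1, width)
    pr[[paste0("gg", id)]] <- ones(1, width)
    pr[[paste0("ee", id)]] <- zeros(1, width)
    bn[[paste0("rm", id)]] <- zeros(1, width)
    bn[[paste0("rv", id)]] <- ones(1, width)
  }
  pr$Wp1 <- glorot(w2, clusters[1L]); pr$bp1 <- zeros(1, clusters[1L])
  pr$Wp2 <- glorot(w2, clusters[2L]); pr$bp2 <- zeros(1, clusters[2L])
  pr$Wr1 <- glorot(w2, width); pr$br1 <- zeros(1, width)
  pr$Wr2 <- glorot(width, p); pr$br2 <- zeros(1, p)
  new_model("gnn", scenario, cfg = list(width = width, clusters = clusters),
            params = pr, bn = bn)
}

new_model <- function(type, scenario, cfg, params, bn) {
  structure(list(type = type, scenario = scenario,
                 n_params = n_params_for(scenario), cfg = cfg,
                 params = params, bn = bn,
                 norm = list(x_center = NULL, x_scale = NULL,
                             y_center = rep(0, n_params_for(scenario)),
                             y_scale = rep(1, n_params_for(scenario))),
                 trained = FALSE, history = NULL),
            class = c(paste0("divnn_", type), "divnn_model"))
}

#' @export
print.divnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<divnn %s model: scenario %s, %d weights, %s>\n",
              toupper(x$type), x$scenario, np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# encodings

#' Encode trees into the three learning representations
#'
#' Computes, for each tree, the graph tensor ([phylo_to_graph()]), the
#' branching-time sequence ([branching_times()]) and the summary-statistic
#' vector ([tree_summary_stats()]), plus the regression targets on the
#' network output scale (see [transform_targets()]).
#'
#' @param trees List of reconstructed trees.
#' @param params Optional data.frame (or matrix) holding the generating
#'   parameters, with the [param_names()] columns.
#' @param scenario Scenario string.
#' @return An object of class `divnn_dataset`.
#' @export
encode_dataset <- function(trees, params = NULL, scenario) {
  scenario <- match_scenario(scenario)
  if (inherits(trees, "phylo")) trees <- list(trees)
  y <- NULL
  if (!is.null(params)) {
    y <- as.matrix(as.data.frame(params)[, param_names(scenario), drop = FALSE])
    if (nrow(y) != length(trees))
      stop_config("params must have one row per tree")
    y <- transform_targets(y, scenario)
  }
  structure(list(
    graphs = lapply(trees, phylo_to_graph),
    ss = do.call(rbind, lapply(trees, tree_summary_stats)),
    bt = lapply(trees, branching_times),
    y = y, scenario = scenario, n = length(trees)),
    class = "divnn_dataset")
}

#' @export
print.divnn_dataset <- function(x, ...) {
  cat(sprintf("<divnn_dataset: %d trees, scenario %s%s>\n", x$n, x$scenario,
              if (is.null(x$y)) ", no targets" else ""))
  invisible(x)
}

subset_dataset <- function(ds, idx) {
  structure(list(graphs = ds$graphs[idx], ss = ds$ss[idx, , drop = FALSE],
                 bt = ds$bt[idx], y = if (is.null(ds$y)) NULL
                                     else ds$y[idx, , drop = FALSE],
                 scenario = ds$scenario, n = length(idx)),
            class = "divnn_dataset")
}

pad_bt <- function(bt_list) {
  lens <- vapply(bt_list, length, integer(1))
  X <- matrix(0, length(bt_list), max(lens, 1L))
  for (i in seq_along(bt_list)) if (lens[i]) X[i, seq_len(lens[i])] <- bt_list[[i]]
  list(X = X, lens = lens)
}

standardize_ss <- function(model, ss) {
  if (is.null(model$norm$x_center)) return(ss)
  sweep(sweep(ss, 2, model$norm$x_center), 2, model$norm$x_scale, "/")
}

# Forward pass on the network output scale (standardised); shared by
# training, prediction and boosting. Returns list(pred, loss?, grads?, ...).
model_pass <- function(model, ds, idx = seq_len(ds$n), training = FALSE,
                       want_grads = FALSE, want_features = FALSE,
                       huber_delta = 1, aux_weight = 1) {
  y <- NULL
  if (!is.null(ds$y)) {
    yt <- ds$y[idx, , drop = FALSE]
    y <- sweep(sweep(yt, 2, model$norm$y_center), 2, model$norm$y_scale, "/")
  }
  switch(model$type,
    dnn = cpp_dnn_pass(model$params, standardize_ss(model, ds$ss[idx, , drop = FALSE]),
                       y, model$bn, training, huber_delta, want_grads,
                       want_features),
    lstm = {
      pb <- pad_bt(ds$bt[idx])
      cpp_lstm_pass(model$params, pb$X, pb$lens, y, huber_delta, want_grads,
                    want_features)
    },
    gnn = cpp_gnn_pass(model$params, ds$graphs[idx], y, model$bn, training,
                       huber_delta, aux_weight, want_grads, want_features),
    stack = {
      pb <- pad_bt(ds$bt[idx])
      cpp_stack_pass(model$params$dnn, model$params$lstm, model$params$gnn,
                     model$params$meta,
                     standardize_ss(model, ds$ss[idx, , drop = FALSE]),
                     pb$X, pb$lens, ds$graphs[idx], y,
                     model$bn$dnn, model$bn$gnn, training, huber_delta,
                     aux_weight, want_grads)
    },
    stop_config("unknown model type ", model$type))
}

# de-standardise a pass prediction back to the transformed-target scale
unstandardize_pred <- function(model, pred) {
  sweep(sweep(pred, 2, model$norm$y_scale, "*"), 2, model$norm$y_center, "+")
}

# index chunks for inference; sequence models chunk by length with a token
# cap so padded forward passes stay small
infer_chunks <- function(model, ds, idx, chunk = 64L, max_tokens = 16384L) {
  if (!model$type %in% c("lstm", "stack"))
    return(split(idx, ceiling(seq_along(idx) / chunk)))
  lens <- vapply(ds$bt[idx], length, integer(1))
  ord <- idx[order(lens)]
  lens <- sort(lens)
  out <- list(); cur <- integer(0); cur_max <- 0L
  for (i in seq_along(ord)) {
    nm <- max(cur_max, lens[i])
    if (length(cur) >= chunk ||
        (length(cur) > 0L && nm * (length(cur) + 1L) > max_tokens)) {
      out[[length(out) + 1L]] <- cur; cur <- integer(0); cur_max <- 0L
    }
    cur <- c(cur, ord[i]); cur_max <- max(cur_max, lens[i])
  }
  if (length(cur)) out[[length(out) + 1L]] <- cur
  out
}

# transformed-scale predictions, chunked to bound memory
predict_raw <- function(model, ds, chunk = 64L) {
  out <- matrix(NA_real_, ds$n, model$n_params)
  for (idx in infer_chunks(model, ds, seq_len(ds$n), chunk)) {
    ps <- model_pass(model, ds, idx, training = FALSE)
    out[idx, ] <- unstandardize_pred(model, ps$pred)
  }
  out
}

#' Predict diversification parameters
#'
#' Runs the network in inference mode (normalisation layers use their stored
#' running statistics, so predictions are deterministic) and returns
#' parameter estimates on the natural scale.
#'
#' @param object A trained `divnn_model` (or [boost_fit()] /
#'   [build_stack()] result).
#' @param trees List of reconstructed trees, or a `divnn_dataset`.
#' @param ... Unused.
#' @return Numeric matrix, one row per tree, columns [param_names()].
#' @export
predict.divnn_model <- function(object, trees, ...) {
  ds <- if (inherits(trees, "divnn_dataset")) trees
        else encode_dataset(trees, NULL, object$scenario)
  pred <- predict_raw(object, ds)
  colnames(pred) <- param_names(object$scenario)
  untransform_targets(pred, object$scenario)
}
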