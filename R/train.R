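# Training: seeded splits, Huber-based total loss, AdamW optimisation with
# decoupled weight decay, per-epoch monitoring, and fit diagnostics.

#' Training configuration
#'
#' @param n_epochs Number of passes over the training split.
#' @param split_fraction Fraction of trees allocated to training (the rest
#'   monitors validation loss each epoch).
#' @param batch_size Mini-batch size.
#' @param max_tokens Cap on `batch size x padded sequence length` per
#'   branching-time mini-batch; long sequences get proportionally smaller
#'   batches, bounding backpropagation memory.
#' @param lr,weight_decay,beta1,beta2,eps AdamW settings (defaults are the
#'   optimizer's usual defaults).
#' @param huber_delta Huber loss threshold on the standardised target scale.
#' @param aux_weight Weight of the DiffPool auxiliary losses (graph models).
#' @param rng_seed Seed controlling the split, shuffling and weight
#'   initialisation restore.
#' @param keep_best Restore the weights of the best-validation epoch after
#'   training (early stopping itself stays off; training always runs the
#'   full `n_epochs`).
#' @param verbose Print one line per epoch.
#' @return An object of class `divnn_train_config`.
#' @export
train_config <- function(n_epochs = 10L, split_fraction = 0.9, batch_size = 64L,
                         max_tokens = 16384L, lr = 1e-3, weight_decay = 1e-2,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         huber_delta = 1.0, aux_weight = 1.0, rng_seed = NULL,
                         keep_best = TRUE, verbose = FALSE) {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_config("split_fraction must be in (0, 1)")
  if (batch_size < 1L) stop_config("batch_size must be >= 1")
  structure(as.list(environment()), class = "divnn_train_config")
}

#' Split a dataset into training and validation parts
#'
#' Seeded shuffle followed by a deterministic cut: `floor(f * n)` trees for
#' training, the remainder for validation; the two index sets are disjoint.
#'
#' @param x A `divnn_dataset`, a list of trees, or an integer count.
#' @param split_fraction Training fraction.
#' @param rng_seed Optional seed (otherwise the ambient RNG is used).
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_dataset <- function(x, split_fraction = 0.9, rng_seed = NULL) {
  n <- if (is.numeric(x) && length(x) == 1L) as.integer(x)
       else if (inherits(x, "divnn_dataset")) x$n
       else length(x)
  if (n < 1L) stop_config("empty dataset")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_config("split_fraction must be in (0, 1)")
  with_seed(rng_seed, {
    ord <- sample.int(n)
    k <- floor(split_fraction * n)
    list(train = sort(ord[seq_len(k)]),
         validation = sort(ord[setdiff(seq_len(n), seq_len(k))]))
  })
}

#' Huber loss
#'
#' Mean over all elements of the Huber penalty: quadratic
#' (`0.5 e^2`) for `|e| <= delta`, linear (`delta (|e| - delta / 2)`)
#' beyond.
#'
#' @param pred,truth Numeric matrices/vectors of equal shape.
#' @param delta Quadratic-to-linear threshold.
#' @return Non-negative scalar.
#' @export
huber_loss <- function(pred, truth, delta = 1.0) {
  e <- abs(as.numeric(pred) - as.numeric(truth))
  if (any(!is.finite(e))) stop_data("non-finite values in loss inputs")
  mean(ifelse(e <= delta, 0.5 * e^2, delta * (e - 0.5 * delta)))
}

#' Total training loss
#'
#' The residual (Huber) error plus weighted auxiliary terms, e.g. the
#' DiffPool link-prediction and assignment-entropy losses returned by the
#' graph network.
#'
#' @inheritParams huber_loss
#' @param aux_terms Numeric vector of auxiliary loss values (may be empty).
#' @param aux_weight Scalar weight applied to the summed auxiliary terms.
#' @return Non-negative scalar.
#' @export
total_loss <- function(pred, truth, aux_terms = numeric(0), delta = 1.0,
                       aux_weight = 1.0) {
  if (any(!is.finite(aux_terms))) stop_data("non-finite auxiliary terms")
  huber_loss(pred, truth, delta) + aux_weight * sum(aux_terms)
}

# ---------------------------------------------------------------------------
# AdamW over (possibly nested) lists of parameter matrices

adamw_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0), how = "list")
}

adamw_step <- function(params, grads, state, step, cfg) {
  bc1 <- 1 - cfg$beta1^step
  bc2 <- 1 - cfg$beta2^step
  walk <- function(p, g, s) {
    if (is.list(p) && !is.matrix(p)) {
      out <- Map(walk, p, g, s)
      return(list(params = lapply(out, `[[`, "params"),
                  state = lapply(out, `[[`, "state")))
    }
    s$m <- cfg$beta1 * s$m + (1 - cfg$beta1) * g
    s$v <- cfg$beta2 * s$v + (1 - cfg$beta2) * g^2
    upd <- (s$m / bc1) / (sqrt(s$v / bc2) + cfg$eps)
    list(params = p - cfg$lr * (upd + cfg$weight_decay * p), state = s)
  }
  walk(params, grads, state)
}

update_bn <- function(bn, batch, momentum = 0.1) {
  keys <- names(bn)
  nrm <- grep("^rm", keys, value = TRUE)
  for (i in seq_along(nrm)) {
    k <- nrm[i]
    kv <- sub("^rm", "rv", k)
    bn[[k]] <- (1 - momentum) * bn[[k]] + momentum * batch$mean[[i]]
    bn[[kv]] <- (1 - momentum) * bn[[kv]] + momentum * batch$var[[i]]
  }
  bn
}

# mini-batches honouring batch_size and, for sequence models, the token
# cap. Sequences are bucketed by length (so a batch pads to a similar
# maximum) and the bucket order is shuffled each epoch.
make_batches <- function(ds, idx, cfg, by_tokens) {
  if (!by_tokens) {
    ord <- idx[sample.int(length(idx))]
    return(split(ord, ceiling(seq_along(ord) / cfg$batch_size)))
  }
  lens <- vapply(ds$bt[idx], length, integer(1))
  ord <- idx[order(lens, sample.int(length(idx)))]  # random tie-break
  lens <- sort(lens)
  batches <- list(); cur <- integer(0); cur_max <- 0L
  for (i in seq_along(ord)) {
    nm <- max(cur_max, lens[i])
    if (length(cur) >= cfg$batch_size ||
        (length(cur) > 0L && nm * (length(cur) + 1L) > cfg$max_tokens)) {
      batches[[length(batches) + 1L]] <- cur
      cur <- integer(0); cur_max <- 0L
    }
    cur <- c(cur, ord[i]); cur_max <- max(cur_max, lens[i])
  }
  if (length(cur)) batches[[length(batches) + 1L]] <- cur
  batches[sample.int(length(batches))]
}

eval_loss <- function(model, ds, idx, cfg, chunk = 64L) {
  tot <- 0; n <- 0
  for (sub in infer_chunks(model, ds, idx, chunk, cfg$max_tokens)) {
    ps <- model_pass(model, ds, sub, training = FALSE,
                     huber_delta = cfg$huber_delta, aux_weight = cfg$aux_weight)
    tot <- tot + ps$loss * length(sub)
    n <- n + length(sub)
  }
  tot / n
}

#' Fit a model
#'
#' Mini-batch AdamW optimisation of the total loss (Huber residual plus any
#' DiffPool auxiliary terms). The dataset is shuffled and split once
#' (seeded); summary statistics and targets are standardised with
#' training-split statistics stored inside the model. Per-epoch training
#' loss, validation loss, and per-parameter validation MAE (on the natural
#' parameter scale) are recorded in the returned model's `$history`.
#' Training aborts with a diagnostic if the loss becomes non-finite.
#'
#' @param model A model from [build_dnn()], [build_lstm()], [build_gnn()]
#'   or [build_stack()].
#' @param dataset A `divnn_dataset` with targets ([encode_dataset()]).
#' @param config A [train_config()].
#' @return The trained model, with `$history` (data.frame) and
#'   `$best_epoch` attached.
#' @export
fit_model <- function(model, dataset, config = train_config()) {
  stopifnot(inherits(model, "divnn_model"), inherits(dataset, "divnn_dataset"))
  if (is.null(dataset$y)) stop_config("dataset has no targets")
  if (dataset$n < 10L) stop_config("need at least 10 trees to fit")
  if (dataset$scenario != model$scenario)
    stop_config("dataset scenario does not match the model")
  cfg <- config
  with_seed(cfg$rng_seed, {
    sp <- split_dataset(dataset$n, cfg$split_fraction)
    tr <- sp$train; va <- sp$validation
    # input standardisation (summary statistics) from the training split
    if (model$type %in% c("dnn", "stack")) {
      ctr <- colMeans(dataset$ss[tr, , drop = FALSE])
      scl <- apply(dataset$ss[tr, , drop = FALSE], 2, sd)
      scl[scl < 1e-12] <- 1
      model$norm$x_center <- ctr; model$norm$x_scale <- scl
    }
    yc <- colMeans(dataset$y[tr, , drop = FALSE])
    ys <- apply(dataset$y[tr, , drop = FALSE], 2, sd)
    ys[ys < 1e-12] <- 1
    model$norm$y_center <- yc; model$norm$y_scale <- ys
    opt <- adamw_init(model$params)
    step <- 0L
    by_tokens <- model$type %in% c("lstm", "stack")
    hist <- vector("list", cfg$n_epochs)
    best <- list(val = Inf, params = model$params, bn = model$bn, epoch = NA_integer_)
    pn <- param_names(model$scenario)
    for (epoch in seq_len(cfg$n_epochs)) {
      batches <- make_batches(dataset, tr, cfg, by_tokens)
      ep_loss <- 0
      for (b in batches) {
        ps <- model_pass(model, dataset, b, training = TRUE, want_grads = TRUE,
                         huber_delta = cfg$huber_delta,
                         aux_weight = cfg$aux_weight)
        if (!is.finite(ps$loss))
          stop_data("training diverged (non-finite loss) at epoch ", epoch)
        step <- step + 1L
        if (model$type == "stack") {
          res <- adamw_step(model$params, ps$grads, opt, step, cfg)
          model$params <- res$params; opt <- res$state
          model$bn$dnn <- update_bn(model$bn$dnn, ps$bn_batch_dnn)
          model$bn$gnn <- update_bn(model$bn$gnn, ps$bn_batch_gnn)
        } else {
          res <- adamw_step(model$params, ps$grads, opt, step, cfg)
          model$params <- res$params; opt <- res$state
          if (!is.null(ps$bn_batch)) model$bn <- update_bn(model$bn, ps$bn_batch)
        }
        ep_loss <- ep_loss + ps$loss * length(b)
      }
      ep_loss <- ep_loss / length(tr)
      val_loss <- NA_real_
      mae <- rep(NA_real_, length(pn))
      if (length(va) > 0L) {
        val_loss <- eval_loss(model, dataset, va, cfg)
        pv <- untransform_targets(
          predict_raw(model, subset_dataset(dataset, va)), model$scenario)
        tv <- untransform_targets(dataset$y[va, , drop = FALSE], model$scenario)
        mae <- colMeans(abs(pv - tv))
        if (cfg$keep_best && val_loss < best$val)
          best <- list(val = val_loss, params = model$params, bn = model$bn,
                       epoch = epoch)
      }
      hist[[epoch]] <- c(epoch = epoch, train_loss = ep_loss,
                         val_loss = val_loss, setNames(mae, paste0("mae_", pn)))
      if (cfg$verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f", epoch, ep_loss,
                        val_loss))
    }
    model$history <- as.data.frame(do.call(rbind, hist))
    if (cfg$keep_best && is.finite(best$val)) {
      model$params <- best$params; model$bn <- best$bn
      model$best_epoch <- best$epoch
    } else {
      model$best_epoch <- cfg$n_epochs
    }
    model$trained <- TRUE
    model
  })
}

#' Diagnose a training history
#'
#' Flags overfitting (training loss still falling while validation loss
#' rises over the trailing window) and underfitting (both losses high and
#' declining at a similar rate), and reports the best-validation epoch.
#'
#' @param history Data.frame with `train_loss` and `val_loss` columns (as
#'   produced by [fit_model()]).
#' @param window Number of trailing epochs examined.
#' @return List with `overfit`, `underfit`, `best_epoch`.
#' @export
diagnose_fit <- function(history, window = 5L) {
  if (nrow(history) < 3L) stop_config("need at least 3 epochs to diagnose")
  w <- min(window, nrow(history))
  tailh <- history[(nrow(history) - w + 1L):nrow(history), ]
  slope <- function(y) {
    if (all(is.na(y))) return(NA_real_)
    unname(stats::lm.fit(cbind(1, seq_along(y)), y)$coefficients[2L])
  }
  st <- slope(tailh$train_loss)
  sv <- slope(tailh$val_loss)
  overfit <- isTRUE(st < 0 && sv > 0)
  # both declining at similar rates while validation remains far above its
  # eventual floor -> the model has not finished learning
  high <- isTRUE(mean(tailh$val_loss) > 1.5 * min(history$val_loss, na.rm = TRUE) + 1e-12)
  similar <- isTRUE(st < 0 && sv < 0 &&
                    abs(sv - st) < 0.5 * max(abs(st), abs(sv)))
  underfit <- !overfit && similar && (high || mean(tailh$val_loss) >
                                        0.5 * history$val_loss[1L])
  list(overfit = overfit, underfit = underfit,
       best_epoch = if (all(is.na(history$val_loss))) nrow(history)
                    else which.min(history$val_loss))
}

#' Mid-points of the training parameter space
#'
#' The constant predictor that always answers the mid-point of each
#' parameter's sampled range; networks fall back towards these values when
#' the input carries little signal, so this is the natural no-information
#' baseline.
#'
#' @param scenario Scenario string.
#' @return Named numeric vector.
#' @export
midrange_params <- function(scenario) {
  switch(match_scenario(scenario),
    BD  = c(lambda = (0.1 + 0.8) / 2, mu = (0 + 0.72) / 2),
    DDD = c(lambda0 = (0.1 + 4.0) / 2, mu0 = (0 + 1.5) / 2,
            K = (10 + 1000) / 2),
    PBD = c(lambda1 = 0.55, lambda2 = 10^((-3 + 1) / 2), lambda3 = 0.55,
            mu1 = (0 + 0.8) / 2, mu2 = (0 + 0.8) / 2))
}
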