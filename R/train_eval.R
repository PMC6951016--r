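# Masked multitask losses, evaluation metrics, the training loop with
# best-validation-epoch checkpointing, and the three-repeat protocol.

#' Masked losses
#'
#' Mean binary cross-entropy (from pre-sigmoid scores) or mean squared
#' error over the *observed* cells only. Missing cells contribute
#' neither to the value nor to any gradient, so unlabelled
#' molecule-task pairs never backpropagate. A batch with no observed
#' cell has loss 0 (with a warning).
#'
#' @param scores,preds numeric matrix of model outputs.
#' @param labels numeric matrix of the same shape.
#' @param mask logical observation mask of the same shape.
#' @return scalar loss.
#' @export
masked_classification_loss <- function(scores, labels, mask) {
  stopifnot(identical(dim(as.matrix(scores)), dim(as.matrix(labels))),
            identical(dim(as.matrix(labels)), dim(as.matrix(mask))))
  if (!any(mask)) {
    warning("no observed cells in batch; loss defined as 0", call. = FALSE)
    return(0)
  }
  tape <- ad_tape()
  ad_masked_bce(tape, ad_const(tape, as.matrix(scores)), as.matrix(labels),
                as.matrix(mask) * 1)$val[1L, 1L]
}

#' @rdname masked_classification_loss
#' @export
masked_regression_loss <- function(preds, labels, mask) {
  stopifnot(identical(dim(as.matrix(preds)), dim(as.matrix(labels))),
            identical(dim(as.matrix(labels)), dim(as.matrix(mask))))
  if (!any(mask)) {
    warning("no observed cells in batch; loss defined as 0", call. = FALSE)
    return(0)
  }
  tape <- ad_tape()
  ad_masked_mse(tape, ad_const(tape, as.matrix(preds)), as.matrix(labels),
                as.matrix(mask) * 1)$val[1L, 1L]
}

roc_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) return(NA_real_)
  as.numeric(pROC::auc(labels, scores, quiet = TRUE,
                       direction = "<", levels = c(0, 1)))
}

# average precision (step-wise integral of the precision-recall curve)
prc_auc <- function(labels, scores) {
  npos <- sum(labels == 1)
  if (npos == 0 || npos == length(labels)) return(NA_real_)
  ord <- order(-scores, labels)  # ties: pessimistic (negatives first)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / npos
  sum(prec * c(rec[1L], diff(rec)))
}

METRICS <- c("roc-auc", "prc-auc", "rmse", "mae")

metric_direction <- function(metric) {
  if (metric %in% c("roc-auc", "prc-auc")) "max" else "min"
}

#' Evaluate predictions
#'
#' Per-task metric values over observed cells, plus their arithmetic
#' mean over the tasks for which the metric is computable (a
#' classification task whose observed cells contain a single class is
#' reported `NA` and excluded from the aggregate). Regression
#' predictions are expected in original units -- [train_model()]
#' inverts its target normalization before calling this.
#'
#' @param preds numeric matrix of predictions (pre-sigmoid scores for
#'   classification).
#' @param labels,mask label matrix and observation mask.
#' @param metric one of `"roc-auc"`, `"prc-auc"`, `"rmse"`, `"mae"`.
#' @return list with `metric`, `per_task`, `aggregate`.
#' @export
evaluate <- function(preds, labels, mask, metric) {
  metric <- match.arg(tolower(metric), METRICS)
  preds <- as.matrix(preds); labels <- as.matrix(labels); mask <- as.matrix(mask)
  per_task <- vapply(seq_len(ncol(labels)), function(j) {
    obs <- mask[, j]
    if (!any(obs)) return(NA_real_)
    y <- labels[obs, j]
    p <- preds[obs, j]
    switch(metric,
           "roc-auc" = roc_auc(y, p),
           "prc-auc" = prc_auc(y, p),
           "rmse" = sqrt(mean((p - y)^2)),
           "mae" = mean(abs(p - y)))
  }, numeric(1))
  names(per_task) <- colnames(labels)
  list(metric = metric, per_task = per_task,
       aggregate = if (all(is.na(per_task))) NA_real_ else mean(per_task, na.rm = TRUE))
}

predict_table <- function(model, graphs, idx, batch_size = 64L) {
  out <- matrix(NA_real_, length(idx), model$n_tasks)
  for (start in seq(1L, length(idx), by = batch_size)) {
    sel <- idx[start:min(start + batch_size - 1L, length(idx))]
    b <- batch_graphs(graphs[sel])
    out[start:(start + length(sel) - 1L), ] <- forward_pass(model, b)
  }
  out
}

#' Train a model
#'
#' Minibatch training with the adaptive-moment optimizer at the
#' configured learning rate, masked losses, per-epoch validation, and
#' best-validation-epoch checkpoint selection: the returned model and
#' the reported test metrics come from the epoch with the best
#' validation score. Regression targets are normalized on the training
#' set and predictions transformed back before metrics. Fully
#' deterministic given `(seed, config, split)`.
#'
#' @param config a [model_config()].
#' @param table a [task_table()].
#' @param split a `split_spec` over the rows of `table`.
#' @param seed RNG seed covering weight initialization, shuffling and
#'   dropout.
#' @param metric evaluation metric (see [evaluate()]).
#' @param epochs epoch cap.
#' @param batch_size minibatch size.
#' @param patience early stop after this many epochs without validation
#'   improvement.
#' @param schema atom feature schema used for featurization.
#' @param verbose print per-epoch lines (`epoch, train loss,
#'   validation metric`).
#' @return list of class `molmpnn_fit`: `model` (best checkpoint),
#'   `report` (validation/test metrics at the selected epoch),
#'   `history` (per-epoch data frame), `norm` (normalization stats or
#'   `NULL`), `best_epoch`.
#' @export
train_model <- function(config, table, split, seed = 0L,
                        metric = if (table$task_kind == "classification") "roc-auc" else "rmse",
                        epochs = 100L, batch_size = 50L, patience = Inf,
                        schema = atom_feature_schema(), verbose = FALSE) {
  stopifnot(inherits(table, "task_table"), inherits(split, "split_spec"))
  metric <- match.arg(tolower(metric), METRICS)
  graphs <- featurize_molecules(table$smiles, schema)
  n_tasks <- ncol(table$labels)
  norm <- NULL
  targets <- table$labels
  if (table$task_kind == "regression") {
    norm <- fit_normalization(table$labels[split$train, , drop = FALSE],
                              table$mask[split$train, , drop = FALSE])
    targets <- apply_normalization(table$labels, norm)
    targets[!table$mask] <- 0
  }
  set.seed(seed)
  model <- init_model(config, schema$d_node, n_tasks)
  state <- adam_init(model$params)
  dir <- metric_direction(metric)
  better <- function(a, b) if (dir == "max") a > b else a < b
  eval_idx <- function(idx) {
    preds <- predict_table(model, graphs, idx)
    if (!is.null(norm)) preds <- invert_normalization(preds, norm)
    evaluate(preds, table$labels[idx, , drop = FALSE],
             table$mask[idx, , drop = FALSE], metric)
  }
  best <- list(score = if (dir == "max") -Inf else Inf, params = model$params,
               epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     valid_metric = numeric(0))
  stale <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(split$train)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1L, length(ord), by = batch_size)) {
      sel <- ord[start:min(start + batch_size - 1L, length(ord))]
      b <- batch_graphs(graphs[sel])
      tape <- ad_tape()
      pn <- ad_wrap_params(tape, model$params)
      out <- forward_tape(model, b, pn, tape, training = TRUE)
      mk <- table$mask[sel, , drop = FALSE] * 1
      loss <- if (table$task_kind == "classification") {
        ad_masked_bce(tape, out, table$labels[sel, , drop = FALSE], mk)
      } else {
        ad_masked_mse(tape, out, targets[sel, , drop = FALSE], mk)
      }
      if (!is.finite(loss$val[1L, 1L])) {
        stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
      }
      ad_backward(tape, loss)
      upd <- adam_step(model$params, ad_extract_grads(pn), state, config$learn_rate)
      model$params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + loss$val[1L, 1L]
      nb <- nb + 1L
    }
    vm <- eval_idx(split$valid)$aggregate
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                   valid_metric = vm))
    if (verbose) {
      cat(sprintf("epoch %3d  train_loss %.5f  valid_%s %.5f\n",
                  ep, ep_loss / nb, metric, vm))
    }
    if (!is.na(vm) && better(vm, best$score)) {
      best <- list(score = vm, params = model$params, epoch = ep)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= patience) break
    }
  }
  model$params <- best$params
  test <- eval_idx(split$test)
  valid <- eval_idx(split$valid)
  fit <- list(model = model,
              report = list(metric = metric, valid = valid, test = test),
              history = hist, norm = norm, best_epoch = best$epoch,
              seed = seed, split = split)
  class(fit) <- "molmpnn_fit"
  fit
}

#' @export
print.molmpnn_fit <- function(x, ...) {
  cat("<molmpnn_fit>", x$model$config$architecture,
      "- best epoch", x$best_epoch, "\n")
  cat(sprintf("  valid %s: %.4f   test %s: %.4f\n",
              x$report$metric, x$report$valid$aggregate,
              x$report$metric, x$report$test$aggregate))
  invisible(x)
}

#' Predict on new molecules
#'
#' @param object a `molmpnn_fit` from [train_model()].
#' @param smiles character vector.
#' @param type for classification fits, `"score"` (pre-sigmoid) or
#'   `"prob"`.
#' @param ... unused.
#' @return matrix `length(smiles) x n_tasks`; regression predictions
#'   are returned in original units.
#' @export
predict.molmpnn_fit <- function(object, smiles, type = c("score", "prob"), ...) {
  type <- match.arg(type)
  graphs <- featurize_molecules(smiles)
  preds <- predict_table(object$model, graphs, seq_along(graphs))
  if (!is.null(object$norm)) preds <- invert_normalization(preds, object$norm)
  if (type == "prob") preds <- 1 / (1 + exp(-preds))
  preds
}

#' Three-repeat evaluation protocol
#'
#' Trains three models and aggregates their test metrics as mean and
#' standard deviation. With random splitting, the three repeats use
#' three different split seeds (different memberships); with scaffold
#' splitting, the single deterministic membership is reused and the
#' repeats differ only in weight initialization.
#'
#' @param config a [model_config()].
#' @param table a [task_table()].
#' @param split_method `"random"` or `"scaffold"`.
#' @param seeds three integer seeds.
#' @param ratios split ratios.
#' @inheritParams train_model
#' @param ... passed on to [train_model()].
#' @return list of class `eval_report`: per-repeat fits' reports,
#'   `splits`, and `summary` (per-task and aggregate mean/sd over the
#'   three repeats).
#' @export
repeat_protocol <- function(config, table, split_method = c("random", "scaffold"),
                            seeds = c(0L, 1L, 2L), ratios = c(0.8, 0.1, 0.1),
                            metric = if (table$task_kind == "classification") "roc-auc" else "rmse",
                            ...) {
  split_method <- match.arg(split_method)
  stopifnot(length(seeds) == 3)
  n <- length(table$smiles)
  splits <- if (split_method == "random") {
    lapply(seeds, function(s) random_split(n, ratios, seed = s))
  } else {
    one <- scaffold_split(table$smiles, ratios)
    list(one, one, one)
  }
  fits <- lapply(1:3, function(i) {
    train_model(config, table, splits[[i]], seed = seeds[[i]], metric = metric, ...)
  })
  agg <- vapply(fits, function(f) f$report$test$aggregate, numeric(1))
  per_task <- do.call(rbind, lapply(fits, function(f) f$report$test$per_task))
  rep <- list(metric = metric, split_method = split_method,
              repeats = lapply(fits, `[[`, "report"),
              splits = splits, fits = fits,
              summary = list(mean = mean(agg), sd = stats::sd(agg),
                             per_task_mean = colMeans(per_task),
                             per_task_sd = apply(per_task, 2L, stats::sd)))
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$split_method, "split,", x$metric, "\n")
  cat(sprintf("  test %s over 3 repeats: %.4f +/- %.4f\n",
              x$metric, x$summary$mean, x$summary$sd))
  invisible(x)
}
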