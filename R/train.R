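# Training and evaluation: minibatch gradient training with per-epoch
# class rebalancing, an Adam-style optimiser, checkpointing, and the
# binary-classification evaluation suite (confusion matrix, accuracy,
# precision, recall, F1, ROC/AUC, MCC).

#' Training configuration
#'
#' @param epochs Number of passes over the (rebalanced) training pairs.
#' @param batch_size Minibatch size (default 4).
#' @param l2_lambda L2 regularisation coefficient on weight matrices.
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialisation, rebalancing,
#'   shuffling and dropout.
#' @param max_len Sequence-length cap enforced on training proteins.
#' @param net A [net_config()] describing the architecture.
#' @return List of class `codroplet_train_config`.
#' @export
train_config <- function(epochs = 40L, batch_size = 4L, l2_lambda = 1e-4,
                         learning_rate = 1e-4, seed = 1L, max_len = 1024L,
                         net = net_config()) {
  stopifnot(epochs >= 1L, batch_size >= 1L, l2_lambda >= 0,
            learning_rate >= 0, max_len >= 1L)
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         l2_lambda = l2_lambda, learning_rate = learning_rate,
         seed = as.integer(seed), max_len = as.integer(max_len), net = net),
    class = "codroplet_train_config"
  )
}

# Pure-R reference for the fused C++ kernel (kept for verification).
adam_step_ref <- function(p, state, g, wmask, lr, l2, beta1 = 0.9,
                          beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  g <- g + 2 * l2 * wmask * p
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  p <- p - lr * (state$m / (1 - beta1^state$t)) /
    (sqrt(state$v / (1 - beta2^state$t)) + eps)
  list(p = p, state = state)
}

load_pair_bundles <- function(pairs, store) {
  ids <- unique(c(pairs$id_a, pairs$id_b))
  avail <- store_ids(store)
  missing <- setdiff(ids, avail)
  if (length(missing)) {
    stop(sprintf("feature store is missing protein(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bundles <- lapply(ids, function(id) load_features(store, id))
  names(bundles) <- ids
  bundles
}

#' Train the co-condensation model
#'
#' Rebalances the classes once per epoch (oversampling the minority class,
#' seeded per epoch), iterates minibatches of `batch_size`, averages
#' per-pair gradients of the cross-entropy + L2 loss within each batch and
#' applies Adam updates.  Deterministic given the config seed.
#'
#' @param train_pairs Pair data.frame.
#' @param store Feature store (object or path) containing every protein.
#' @param config A [train_config()].
#' @param init Optional starting parameters (continuation training);
#'   default fresh initialisation from the config seed.
#' @param init_opt_state Optional optimiser state to resume from.
#' @param val_pairs Optional held-out pairs; when given, per-epoch AUC on
#'   them is recorded in the history.
#' @param verbose Print a line per epoch.
#' @return List with `params`, `history` (data.frame: epoch, mean train
#'   loss, optional val_auc), `opt_state`, `config`.
#' @export
train_model <- function(train_pairs, store, config = train_config(),
                        init = NULL, init_opt_state = NULL,
                        val_pairs = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "codroplet_train_config"))
  if (is.character(store)) store <- feature_store(store, create = FALSE)
  bundles <- load_pair_bundles(train_pairs, store)
  too_long <- names(bundles)[vapply(bundles, function(b) b$L, 0L) > config$max_len]
  if (length(too_long)) {
    stop(sprintf("protein(s) exceed max_len=%d: %s", config$max_len,
                 paste(too_long, collapse = ", ")), call. = FALSE)
  }

  # The optimiser mutates the tree's leaf vectors in place; always work on a
  # deep copy so neither a caller-supplied initialisation nor any vector
  # shared by the initialiser (e.g. R's interned constants) is touched.
  params <- param_copy(init %||% init_params(config$net, config$seed))
  leaves <- param_leaves(params)
  wflag <- param_leaf_wflags(params)
  opt <- if (is.null(init_opt_state)) {
    list(m = lapply(leaves, function(x) numeric(length(x))),
         v = lapply(leaves, function(x) numeric(length(x))), t = 0L)
  } else {
    list(m = lapply(init_opt_state$m, function(x) x + 0),
         v = lapply(init_opt_state$v, function(x) x + 0),
         t = init_opt_state$t)
  }
  if (length(opt$m) != length(leaves)) {
    stop("optimiser state does not match the parameter tree", call. = FALSE)
  }
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auc = numeric())

  for (epoch in seq_len(config$epochs)) {
    ep_pairs <- rebalance(train_pairs, derive_seed(config$seed, "epoch", epoch))
    n <- nrow(ep_pairs)
    batch_starts <- seq(1L, n, by = config$batch_size)
    total_bce <- 0
    for (s in batch_starts) {
      rows <- s:min(s + config$batch_size - 1L, n)
      pid <- cbind(ep_pairs$id_a[rows], ep_pairs$id_b[rows])
      labels <- ep_pairs$label[rows]
      fwd <- with_seed(derive_seed(config$seed, "dropout", epoch, s),
                       batch_model_fwd(pid, bundles, params, config$net,
                                       training = TRUE))
      total_bce <- total_bce + sum(bce_loss(fwd$probs, labels))
      grads <- batch_model_bwd(fwd, labels, params, config$net)
      opt$t <- opt$t + 1L
      adam_update_leaves(leaves, opt$m, opt$v, param_leaves(grads), wflag,
                         config$learning_rate, config$l2_lambda,
                         0.9, 0.999, 1e-8, opt$t)
    }
    # mean per-pair cross-entropy plus the L2 penalty at the epoch's end
    l2_term <- config$l2_lambda *
      sum(vapply(which(wflag == 1), function(k) sum(leaves[[k]]^2), 0))
    mean_loss <- total_bce / n + l2_term
    val_auc <- NA_real_
    if (!is.null(val_pairs) && nrow(val_pairs)) {
      val_auc <- evaluate_model(params, val_pairs, store, config$net)$auc
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean_loss,
                                         val_auc = val_auc))
    if (verbose) {
      message(sprintf("epoch %d/%d  loss %.4f%s", epoch, config$epochs,
                      mean_loss,
                      if (is.na(val_auc)) "" else sprintf("  val AUC %.3f", val_auc)))
    }
  }
  list(params = params, history = history, opt_state = opt, config = config)
}

#' Score a table of pairs
#'
#' @param params Model parameters.
#' @param pairs Pair data.frame (columns `id_a`, `id_b`).
#' @param store Feature store.
#' @param net A [net_config()].
#' @param chunk_size Number of complexes evaluated per batched forward
#'   pass.
#' @return Numeric vector of probabilities, one per row of `pairs`.
#' @export
score_pairs <- function(params, pairs, store, net = net_config(),
                        chunk_size = 16L) {
  if (is.character(store)) store <- feature_store(store, create = FALSE)
  bundles <- load_pair_bundles(pairs, store)
  n <- nrow(pairs)
  pid <- cbind(pairs$id_a, pairs$id_b)
  if (isTRUE(net$symmetrize)) pid <- rbind(pid, pid[, 2:1, drop = FALSE])
  probs <- numeric(nrow(pid))
  for (s in seq(1L, nrow(pid), by = chunk_size)) {
    rows <- s:min(s + chunk_size - 1L, nrow(pid))
    probs[rows] <- batch_model_fwd(pid[rows, , drop = FALSE], bundles,
                                   params, net, training = FALSE)$probs
  }
  if (isTRUE(net$symmetrize)) (probs[seq_len(n)] + probs[n + seq_len(n)]) / 2
  else probs
}

#' Evaluate the model on a labelled test set
#'
#' Scores every pair in evaluation mode, thresholds the scores for the
#' confusion matrix and computes the full metric suite.
#'
#' @inheritParams score_pairs
#' @param threshold Decision threshold for the confusion matrix.
#' @return An evaluation report, see [compute_metrics()].
#' @export
evaluate_model <- function(params, pairs, store, net = net_config(),
                           threshold = 0.5) {
  scores <- score_pairs(params, pairs, store, net)
  compute_metrics(labels = pairs$label, scores = scores,
                  threshold = threshold)
}

# ---- metrics --------------------------------------------------------------

safe_div <- function(num, den) if (den == 0) NaN else num / den

#' Empirical ROC curve
#'
#' Sweeps the decision threshold across all distinct scores and returns
#' the (FPR, TPR) points, ordered for trapezoidal integration.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores.
#' @return data.frame with columns `fpr`, `tpr`.
#' @export
roc_curve <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  last <- c(sc[-1L] != sc[-length(sc)], TRUE)  # one point per distinct score
  data.frame(
    fpr = c(0, fp[last] / n_neg),
    tpr = c(0, tp[last] / n_pos)
  )
}

auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1L] + roc$tpr[-nrow(roc)]) / 2)
}

#' F1 score from precision and recall
#'
#' Harmonic mean of precision and recall, the identity used whenever the
#' two component metrics are available without the raw confusion counts.
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return F1 in `[0, 1]`, `NaN` when both inputs are zero.
#' @export
f1_score <- function(precision, recall) {
  if (precision + recall == 0) return(NaN)
  2 * precision * recall / (precision + recall)
}

#' Matthews correlation coefficient
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return MCC in `[-1, 1]`, or `NaN` when a margin is empty.
#' @export
mcc <- function(tp, fp, tn, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(NaN)
  (tp * tn - fp * fn) / den
}

#' Compute the binary-classification evaluation report
#'
#' Either supply `labels` and `scores` (full report including ROC/AUC) or
#' the four confusion counts (threshold metrics only).  Undefined ratios
#' (0/0) are reported as `NaN`, with the affected metrics listed in
#' `undefined`, never silently coerced to 0.  AUC is computed by
#' trapezoidal integration of the empirical ROC; with a single-class
#' input, AUC is `NA` and `auc_error` explains why.
#'
#' @param labels Optional 0/1 vector.
#' @param scores Optional numeric scores.
#' @param tp,fp,tn,fn Optional confusion counts.
#' @param threshold Decision threshold applied to `scores` (default 0.5;
#'   predictions are positive when `score >= threshold`).
#' @return List of class `codroplet_eval` with counts, `accuracy`,
#'   `precision`, `recall`, `f1`, `mcc`, `auc`, `roc` (data.frame),
#'   `threshold`, `undefined`.
#' @export
compute_metrics <- function(labels = NULL, scores = NULL,
                            tp = NULL, fp = NULL, tn = NULL, fn = NULL,
                            threshold = 0.5) {
  roc <- NULL
  auc <- NA_real_
  auc_error <- NULL
  if (!is.null(labels)) {
    stopifnot(!is.null(scores), all(labels %in% c(0L, 1L)))
    pred <- as.integer(scores >= threshold)
    tp <- sum(pred == 1L & labels == 1L)
    fp <- sum(pred == 1L & labels == 0L)
    tn <- sum(pred == 0L & labels == 0L)
    fn <- sum(pred == 0L & labels == 1L)
    if (length(unique(labels)) < 2L) {
      auc_error <- "AUC undefined: test set contains a single class"
    } else {
      roc <- roc_curve(labels, scores)
      auc <- auc_trapezoid(roc)
    }
  } else {
    stopifnot(!is.null(tp), !is.null(fp), !is.null(tn), !is.null(fn),
              tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  }
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.nan(precision) || is.nan(recall) || (precision + recall) == 0) {
    NaN
  } else {
    2 * precision * recall / (precision + recall)
  }
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    precision = precision, recall = recall, f1 = f1,
    mcc = mcc(tp, fp, tn, fn),
    auc = auc, roc = roc, threshold = threshold,
    auc_error = auc_error
  )
  out$undefined <- names(Filter(function(x) is.numeric(x) && length(x) == 1 &&
                                  is.nan(x),
                                out[c("accuracy", "precision", "recall",
                                      "f1", "mcc")]))
  class(out) <- "codroplet_eval"
  out
}

#' @export
print.codroplet_eval <- function(x, ...) {
  cat(sprintf(
    paste0("<codroplet_eval> tp=%d fp=%d tn=%d fn=%d\n",
           "  accuracy %.3f  precision %.3f  recall %.3f  f1 %.3f\n",
           "  auc %.3f  mcc %.3f  (threshold %.2f)\n"),
    x$tp, x$fp, x$tn, x$fn, x$accuracy, x$precision, x$recall, x$f1,
    x$auc, x$mcc, x$threshold
  ))
  invisible(x)
}

#' Cross-validate training configurations
#'
#' Builds `k_folds` condensate-disjoint folds (each fold's positive pairs
#' drawn from condensates unseen by the other folds, via repeated
#' condensate-aware splits), trains every candidate configuration on each
#' fold's training side and selects the configuration with the highest
#' mean held-out AUC.  Ties are broken by smaller `l2_lambda`, then
#' smaller `learning_rate`.
#'
#' @param pairs Pair data.frame.
#' @param store Feature store.
#' @param condensates A [condensate_table()].
#' @param configs List of [train_config()] candidates.
#' @param k_folds Number of folds (>= 2).
#' @param seed Integer seed for fold construction.
#' @return List with `best` (the selected config), `results` (data.frame
#'   of per-fold AUC per config).
#' @export
cross_validate <- function(pairs, store, condensates, configs, k_folds = 3L,
                           seed = 1L) {
  stopifnot(k_folds >= 2L, length(configs) >= 1L)
  folds <- lapply(seq_len(k_folds), function(k) {
    split_by_condensate(pairs, condensates,
                        fraction = 1 - 1 / k_folds,
                        seed = derive_seed(seed, "fold", k))
  })
  rows <- list()
  mean_auc <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    aucs <- c()
    for (k in seq_len(k_folds)) {
      fold <- folds[[k]]
      if (!nrow(fold$test) || length(unique(fold$test$label)) < 2L ||
          !nrow(fold$train) || length(unique(fold$train$label)) < 2L) {
        warning(sprintf("fold %d degenerate; skipped", k))
        next
      }
      fit <- train_model(fold$train, store, configs[[ci]])
      ev <- evaluate_model(fit$params, fold$test, store, configs[[ci]]$net)
      aucs <- c(aucs, ev$auc)
      rows[[length(rows) + 1L]] <- data.frame(config = ci, fold = k,
                                              auc = ev$auc)
    }
    mean_auc[ci] <- if (length(aucs)) mean(aucs) else -Inf
  }
  l2 <- vapply(configs, `[[`, numeric(1L), "l2_lambda")
  lr <- vapply(configs, `[[`, numeric(1L), "learning_rate")
  best <- order(-mean_auc, l2, lr)[1L]
  list(best = configs[[best]], best_index = best,
       results = do.call(rbind, rows), mean_auc = mean_auc)
}

# ---- checkpoints ----------------------------------------------------------

#' Save a parameter checkpoint
#'
#' Writes the named parameter arrays as a single serialized archive plus a
#' JSON header describing the architecture, so a checkpoint is
#' self-describing.
#'
#' @param params Model parameters.
#' @param net The [net_config()] used to build them.
#' @param path Checkpoint path (an `.json` header is written alongside).
#' @param opt_state Optional optimiser state (for continuation training).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, net, path, opt_state = NULL) {
  saveRDS(list(params = params, opt_state = opt_state), path)
  hdr <- unclass(net)
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a parameter checkpoint
#' @param path Checkpoint path from [save_checkpoint()].
#' @return List with `params`, `net`, `opt_state`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  net <- do.call(net_config, hdr[setdiff(names(hdr), character())])
  list(params = obj$params, net = net, opt_state = obj$opt_state)
}
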