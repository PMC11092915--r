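#' Training configuration
#'
#' Defaults are the working hyperparameters of the method: Adam with
#' learning rate 1e-4, weight decay 1e-5, 500 iterations (optimizer update
#' steps), and 64 bags per step. A "batch" of 64 bags is processed one bag
#' at a time with gradient accumulation, so arbitrarily large bags fit in
#' memory. `iteration_unit = "epochs"` reinterprets `iterations` as full
#' passes over the training bags.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 penalty coefficient added to the gradient.
#' @param iterations number of optimizer update steps (or epochs).
#' @param batch_bags bags per optimizer step.
#' @param seed run seed (initialization and bag shuffling).
#' @param attn_dim attention projection dimension.
#' @param hidden bag-MLP hidden width.
#' @param iteration_unit `"steps"` (default) or `"epochs"`.
#' @param selection_metric cross-validation model-selection metric;
#'   validation AUC.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, weight_decay = 1e-5,
                         iterations = 500L, batch_bags = 64L, seed = 1L,
                         attn_dim = 128L, hidden = 128L,
                         iteration_unit = c("steps", "epochs"),
                         selection_metric = "auc") {
  iteration_unit <- match.arg(iteration_unit)
  if (learning_rate < 0) stop_config("learning_rate", "must be >= 0")
  if (weight_decay < 0) stop_config("weight_decay", "must be >= 0")
  if (iterations < 1) stop_config("iterations", "must be >= 1")
  if (batch_bags < 1) stop_config("batch_bags", "must be >= 1")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 iterations = as.integer(iterations),
                 batch_bags = as.integer(batch_bags), seed = as.integer(seed),
                 attn_dim = as.integer(attn_dim), hidden = as.integer(hidden),
                 iteration_unit = iteration_unit,
                 selection_metric = selection_metric),
            class = "train_config")
}

#' Train one attention-MIL model on bags of one magnification
#'
#' Runs Adam over minibatches of `batch_bags` bags; the gradient of each
#' step is the mean of the per-bag analytic gradients plus the weight-decay
#' term. Bag order is reshuffled under the run seed each full pass.
#' Deterministic given the configuration seed.
#'
#' @param bags list of instance-feature matrices (one per bag). Empty bags
#'   (zero rows) are dropped with a warning.
#' @param labels 0/1 bag labels.
#' @param config a [train_config()].
#' @return list with `params` (trained `abmil_params`) and `loss_trace`
#'   (mean batch loss per optimizer step).
#' @export
train_single_scale <- function(bags, labels, config = train_config()) {
  stopifnot(inherits(config, "train_config"), length(bags) == length(labels))
  labels <- as.integer(labels)
  keep <- vapply(bags, function(b) is.matrix(b) && nrow(b) > 0L, logical(1))
  if (!all(keep)) {
    warning(sum(!keep), " empty bag(s) dropped from training")
    bags <- bags[keep]; labels <- labels[keep]
  }
  if (length(bags) < 2L) stop("training error: need at least 2 bags")
  if (length(unique(labels)) < 2L) {
    stop("training error: both classes must be present in the training bags")
  }
  d <- ncol(bags[[1]])
  params <- init_abmil(d, config$attn_dim, config$hidden, seed = config$seed)
  set.seed(derive_seed(config$seed, "shuffle"))

  n_steps <- if (config$iteration_unit == "epochs") {
    config$iterations * max(1L, ceiling(length(bags) / config$batch_bags))
  } else config$iterations

  theta <- param_vector(params)
  m <- numeric(length(theta)); v <- numeric(length(theta))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  order_queue <- integer(0)
  loss_trace <- numeric(n_steps)

  for (step in seq_len(n_steps)) {
    take <- integer(0)
    while (length(take) < config$batch_bags) {
      if (length(order_queue) == 0L) order_queue <- sample.int(length(bags))
      need <- config$batch_bags - length(take)
      take <- c(take, order_queue[seq_len(min(need, length(order_queue)))])
      order_queue <- order_queue[-seq_len(min(need, length(order_queue)))]
    }
    acc <- NULL
    batch_loss <- 0
    for (i in take) {
      bw <- backward_bag(bags[[i]], params, labels[i])
      batch_loss <- batch_loss + bw$loss
      acc <- if (is.null(acc)) bw$grads else {
        Map(`+`, acc, bw$grads)
      }
    }
    batch_loss <- batch_loss / length(take)
    if (!is.finite(batch_loss)) {
      stop("training error: non-finite loss at step ", step)
    }
    loss_trace[step] <- batch_loss
    g <- unlist(lapply(PARAM_NAMES, function(nm) as.vector(acc[[nm]])),
                use.names = FALSE) / length(take)
    g <- g + config$weight_decay * theta
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^step)
    vhat <- v / (1 - beta2^step)
    theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
    params <- set_param_vector(params, theta)
  }
  list(params = params, loss_trace = loss_trace, config = config)
}

#' Positive-class probabilities for a list of bags
#'
#' @param bags list of instance-feature matrices.
#' @param params trained `abmil_params`.
#' @return numeric vector of positive-class probabilities.
#' @export
predict_bags <- function(bags, params) {
  vapply(bags, function(b) forward_bag(b, params)$p[2], numeric(1))
}

#' 5-fold cross-validation with best-model selection
#'
#' Trains one model per fold (on the other folds) and validates it on the
#' held-out fold, so every bag is validated exactly once; the model with the
#' highest validation AUC is retained. A fold whose validation set contains
#' a single class is skipped with a warning and recorded with `NA` AUC.
#'
#' @param bags list of instance-feature matrices (training split only).
#' @param labels 0/1 bag labels.
#' @param folds integer fold assignment (0-based), same length as `bags`.
#' @param config a [train_config()]; fold seeds are derived from its seed.
#' @return list of class `cv_result` with `fold_metrics` (data.frame: fold,
#'   n_val, val_auc, skipped), `best_fold`, `best_params`, `loss_traces`.
#' @export
cross_validate <- function(bags, labels, folds, config = train_config()) {
  stopifnot(length(bags) == length(labels), length(folds) == length(bags))
  labels <- as.integer(labels)
  fold_ids <- sort(unique(folds))
  models <- vector("list", length(fold_ids))
  traces <- vector("list", length(fold_ids))
  val_auc <- rep(NA_real_, length(fold_ids))
  n_val <- integer(length(fold_ids))
  skipped <- logical(length(fold_ids))
  for (j in seq_along(fold_ids)) {
    f <- fold_ids[j]
    val <- folds == f
    n_val[j] <- sum(val)
    if (length(unique(labels[val])) < 2L) {
      warning("fold ", f, " validation set has a single class; skipped")
      skipped[j] <- TRUE
      next
    }
    fold_cfg <- config
    fold_cfg$seed <- derive_seed(config$seed, paste0("fold", f))
    fit <- train_single_scale(bags[!val], labels[!val], fold_cfg)
    models[[j]] <- fit$params
    traces[[j]] <- fit$loss_trace
    val_auc[j] <- roc_auc(predict_bags(bags[val], fit$params), labels[val])
  }
  if (all(is.na(val_auc))) stop("cross-validation failed: every fold skipped")
  best <- which.max(val_auc)
  structure(list(
    fold_metrics = data.frame(fold = fold_ids, n_val = n_val,
                              val_auc = val_auc, skipped = skipped),
    best_fold = fold_ids[best],
    best_val_auc = val_auc[best],
    best_params = models[[best]],
    loss_traces = traces
  ), class = "cv_result")
}

#' Train cross-validated models for all three magnifications
#'
#' One independent cross-validated model per magnification, sharing a single
#' slide-level fold assignment so the three scales never mix train and
#' validation slides.
#'
#' @param bags_by_scale named list (`"20x"`, `"10x"`, `"5x"`) of bag lists,
#'   aligned across scales (element i of every scale is the same slide).
#' @param labels 0/1 slide labels.
#' @param folds shared integer fold assignment (0-based).
#' @param config a [train_config()]; per-scale seeds are derived from its
#'   seed.
#' @param scales required magnification names.
#' @return named list of `cv_result`, one per magnification.
#' @export
train_all_scales <- function(bags_by_scale, labels, folds,
                             config = train_config(),
                             scales = c("20x", "10x", "5x")) {
  missing_sc <- setdiff(scales, names(bags_by_scale))
  if (length(missing_sc) > 0L) {
    stop("configuration error: missing magnification(s): ",
         paste(missing_sc, collapse = ", "))
  }
  lapply(stats::setNames(scales, scales), function(sc) {
    sc_cfg <- config
    sc_cfg$seed <- derive_seed(config$seed, paste0("scale-", sc))
    cross_validate(bags_by_scale[[sc]], labels, folds, sc_cfg)
  })
}
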