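#' Area under the ROC curve
#'
#' Computed through the Mann–Whitney identity: the rank-sum of the positive
#' scores, with tied scores contributing 0.5 per tied pair (midrank
#' convention), divided by `n_pos * n_neg`.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels 0/1 true labels.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("undefined metric: AUC requires both classes present")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Accuracy, false positive rate and false negative rate
#'
#' From the 2x2 confusion table: accuracy = (TP+TN)/N, FPR = FP/(FP+TN),
#' FNR = FN/(FN+TP).
#'
#' @param pred_labels 0/1 predicted labels.
#' @param labels 0/1 true labels.
#' @return named list `accuracy`, `fpr`, `fnr`.
#' @export
confusion_metrics <- function(pred_labels, labels) {
  if (length(pred_labels) != length(labels)) {
    stop("length mismatch between predictions and labels")
  }
  pred_labels <- as.integer(pred_labels); labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop("undefined metric: confusion rates require both classes present")
  }
  tp <- sum(pred_labels == 1L & labels == 1L)
  tn <- sum(pred_labels == 0L & labels == 0L)
  fp <- sum(pred_labels == 1L & labels == 0L)
  fn <- sum(pred_labels == 0L & labels == 1L)
  list(accuracy = (tp + tn) / length(labels),
       fpr = fp / (fp + tn),
       fnr = fn / (fn + tp))
}

#' Stratified bootstrap percentile confidence interval
#'
#' Resamples positives and negatives separately with replacement (so every
#' resample keeps both classes), recomputes the metric B times, and returns
#' the percentile interval. Deterministic given the seed. Fails if the
#' metric is undefined on more than 10% of resamples.
#'
#' @param metric_fn function `(scores, labels) -> scalar`, e.g. [roc_auc()]
#'   on scores or an accuracy function on predicted labels.
#' @param scores numeric scores (or 0/1 predictions for threshold metrics).
#' @param labels 0/1 true labels.
#' @param B number of bootstrap replicates (>= 100; default 2000).
#' @param seed RNG seed.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, B = 2000L, seed = 1L,
                         conf = 0.95) {
  stopifnot(B >= 100L, length(scores) == length(labels))
  labels <- as.integer(labels)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  set.seed(seed)
  stat <- numeric(B)
  for (b in seq_len(B)) {
    idx <- c(pos[sample.int(length(pos), replace = TRUE)],
             neg[sample.int(length(neg), replace = TRUE)])
    stat[b] <- tryCatch(metric_fn(scores[idx], labels[idx]),
                        error = function(e) NA_real_)
  }
  bad <- sum(is.na(stat))
  if (bad > 0.1 * B) {
    stop("CI failure: metric undefined on ", bad, " of ", B, " resamples")
  }
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stat[!is.na(stat)], c(alpha, 1 - alpha), names = FALSE)
  c(lo = q[1], hi = q[2])
}

#' Evaluate slide-level predictions
#'
#' Computes AUC (from the ensemble probabilities), accuracy, FPR and FNR
#' (from the thresholded predictions), each with a stratified bootstrap 95%
#' confidence interval reported with lo <= hi.
#'
#' @param scores positive-class probabilities.
#' @param pred_labels 0/1 predicted labels.
#' @param labels 0/1 true labels.
#' @param B bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return object of class `eval_report`: list with `auc`, `accuracy`,
#'   `fpr`, `fnr`, `ci` (named list of `c(lo, hi)`), `n_pos`, `n_neg`, `B`,
#'   `seed`.
#' @export
evaluate_predictions <- function(scores, pred_labels, labels, B = 2000L,
                                 seed = 1L, conf = 0.95) {
  labels <- as.integer(labels)
  point <- list(
    auc = roc_auc(scores, labels),
    accuracy = confusion_metrics(pred_labels, labels)$accuracy,
    fpr = confusion_metrics(pred_labels, labels)$fpr,
    fnr = confusion_metrics(pred_labels, labels)$fnr
  )
  ci <- list(
    auc = bootstrap_ci(roc_auc, scores, labels, B,
                       derive_seed(seed, "ci-auc"), conf),
    accuracy = bootstrap_ci(function(s, l) confusion_metrics(s, l)$accuracy,
                            pred_labels, labels, B,
                            derive_seed(seed, "ci-acc"), conf),
    fpr = bootstrap_ci(function(s, l) confusion_metrics(s, l)$fpr,
                       pred_labels, labels, B,
                       derive_seed(seed, "ci-fpr"), conf),
    fnr = bootstrap_ci(function(s, l) confusion_metrics(s, l)$fnr,
                       pred_labels, labels, B,
                       derive_seed(seed, "ci-fnr"), conf)
  )
  structure(c(point, list(ci = ci, n_pos = sum(labels == 1L),
                          n_neg = sum(labels == 0L), B = as.integer(B),
                          seed = as.integer(seed))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Slide-level evaluation (%d positive / %d negative, B = %d)\n",
              x$n_pos, x$n_neg, x$B))
  for (m in c("auc", "accuracy", "fpr", "fnr")) {
    cat(sprintf("  %-8s %.4f  (95%% CI %.4f-%.4f)\n",
                toupper(m), x[[m]], x$ci[[m]][1], x$ci[[m]][2]))
  }
  invisible(x)
}
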