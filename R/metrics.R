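#' Confusion-matrix metrics at a probability threshold
#'
#' Accuracy, sensitivity (recall), specificity and F1 at the given
#' threshold (default 0.5, the unadjusted cut used throughout the
#' pipeline). Errors if the truth contains a single class, naming the
#' undefined metric.
#'
#' @param Z Integer 0/1 outcomes.
#' @param p Predicted probabilities.
#' @param threshold Classification threshold.
#' @return List of class `metrics_bundle`: `accuracy`, `sensitivity`,
#'   `specificity`, `f1`, `auc`, `pr_auc` (the last two `NA` here; filled by
#'   [metrics_bundle()]), `n_test`, `threshold`.
#' @export
confusion_metrics <- function(Z, p, threshold = 0.5) {
  if (length(Z) != length(p)) stop_("outcome and prediction lengths differ")
  if (all(Z == 1)) stop_("specificity undefined: no negative outcomes")
  if (all(Z == 0)) stop_("sensitivity undefined: no positive outcomes")
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & Z == 1)
  tn <- sum(pred == 0 & Z == 0)
  fp <- sum(pred == 1 & Z == 0)
  fn <- sum(pred == 0 & Z == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  structure(list(accuracy = (tp + tn) / length(Z),
                 sensitivity = sens, specificity = spec, f1 = f1,
                 auc = NA_real_, pr_auc = NA_real_,
                 n_test = length(Z), threshold = threshold),
            class = "metrics_bundle")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted 1/2 — computed from ranks, so it is invariant under any
#' strictly monotone transform of the scores.
#'
#' @param Z Integer 0/1 outcomes (both classes present).
#' @param p Scores or probabilities.
#' @return ROC-AUC in `[0, 1]`.
#' @export
roc_auc <- function(Z, p) {
  n1 <- sum(Z == 1)
  n0 <- sum(Z == 0)
  if (n1 == 0 || n0 == 0) stop_("roc_auc needs both outcome classes")
  r <- rank(p)
  (sum(r[Z == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average-precision step rule)
#'
#' Sweeps distinct score values from high to low and accumulates
#' `(recall_k - recall_{k-1}) * precision_k` — the average-precision step
#' rule, which avoids the optimism of linear interpolation between PR
#' points. A constant scorer returns the prevalence.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `(0, 1]`.
#' @export
pr_auc <- function(Z, p) {
  P <- sum(Z == 1)
  if (P == 0 || all(Z == 1)) stop_("pr_auc needs both outcome classes")
  thr <- sort(unique(p), decreasing = TRUE)
  ap <- 0
  recall_prev <- 0
  for (t in thr) {
    sel <- p >= t
    tp <- sum(Z[sel] == 1)
    precision <- tp / sum(sel)
    recall <- tp / P
    ap <- ap + (recall - recall_prev) * precision
    recall_prev <- recall
  }
  ap
}

#' Full metrics bundle for one test fold
#'
#' @inheritParams confusion_metrics
#' @return A `metrics_bundle` with `auc` and `pr_auc` filled in.
#' @export
metrics_bundle <- function(Z, p, threshold = 0.5) {
  m <- confusion_metrics(Z, p, threshold)
  m$auc <- roc_auc(Z, p)
  m$pr_auc <- pr_auc(Z, p)
  m
}

METRIC_NAMES <- c("accuracy", "auc", "pr_auc", "sensitivity", "specificity", "f1")

#' Aggregate fold metrics with normal-approximation confidence intervals
#'
#' Mean over folds with a 95% CI of `mean +/- 1.96 * sd / sqrt(k)`,
#' truncated to `[0, 1]`.
#'
#' @param fold_metrics List of `metrics_bundle`s (>= 2 folds).
#' @param conf Confidence level.
#' @return Data frame of class `aggregated_metrics`: `metric`, `mean`,
#'   `ci_low`, `ci_high`, `k`.
#' @export
aggregate_with_ci <- function(fold_metrics, conf = 0.95) {
  k <- length(fold_metrics)
  if (k < 2) stop_("need at least 2 folds to aggregate")
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- lapply(METRIC_NAMES, function(mn) {
    v <- vapply(fold_metrics, `[[`, 0, mn)
    mu <- mean(v)
    half <- zq * sd(v) / sqrt(k)
    data.frame(metric = mn, mean = mu,
               ci_low = max(0, mu - half), ci_high = min(1, mu + half),
               k = k, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("aggregated_metrics", "data.frame"))
}
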