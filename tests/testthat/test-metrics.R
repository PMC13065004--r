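test_that("confusion metrics match hand-built confusion matrices", {
  # TP=1 FN=1 FP=1 TN=1
  m <- confusion_metrics(c(1, 1, 0, 0), c(0.9, 0.2, 0.8, 0.1))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$f1, 0.5)

  perfect <- confusion_metrics(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2))
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, f1 = 1))

  allneg <- confusion_metrics(c(1, 0, 1, 0), rep(0.1, 4))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)

  expect_error(confusion_metrics(c(1, 1), c(0.2, 0.9)), "specificity")
  expect_error(confusion_metrics(c(0, 0), c(0.2, 0.9)), "sensitivity")
})

test_that("accuracy equals the prevalence-weighted mix of sens and spec", {
  for (s in 1:5) {
    set.seed(s)
    Z <- rbinom(60, 1, 0.3)
    if (length(unique(Z)) < 2) next
    p <- runif(60)
    m <- confusion_metrics(Z, p)
    prev <- mean(Z)
    expect_equal(m$accuracy,
                 prev * m$sensitivity + (1 - prev) * m$specificity,
                 tolerance = 1e-12)
  }
})

test_that("ROC-AUC matches exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)

  pair_count_auc <- function(Z, p) {
    pos <- p[Z == 1]
    neg <- p[Z == 0]
    s <- 0
    for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
    s / (length(pos) * length(neg))
  }
  for (s in 1:10) {
    set.seed(100 + s)
    n <- sample(5:20, 1)
    Z <- c(1, 0, rbinom(n - 2, 1, 0.4))
    p <- round(runif(n), 2) # ties likely
    expect_equal(roc_auc(Z, p), pair_count_auc(Z, p), tolerance = 1e-12)
  }
})

test_that("ROC-AUC is invariant under strictly monotone transforms", {
  set.seed(42)
  Z <- rbinom(50, 1, 0.3)
  p <- runif(50)
  a <- roc_auc(Z, p)
  expect_equal(roc_auc(Z, qnorm(p * 0.98 + 0.01)), a, tolerance = 1e-12)
  expect_equal(roc_auc(Z, p^3), a, tolerance = 1e-12)
  skip_if_not_installed("pROC")
  r <- suppressMessages(pROC::roc(Z, p, levels = c(0, 1), direction = "<"))
  expect_equal(a, as.double(pROC::auc(r)), tolerance = 1e-12)
})

test_that("PR-AUC follows the average-precision step rule", {
  expect_equal(pr_auc(c(1, 0), c(0.9, 0.1)), 1.0)
  # constant scorer: PR-AUC equals the prevalence
  expect_equal(pr_auc(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)

  # independent step-rule oracle: walk thresholds with explicit confusion counts
  ap_oracle <- function(Z, p) {
    ts <- sort(unique(p), decreasing = TRUE)
    out <- 0
    r_prev <- 0
    for (t in ts) {
      tp <- sum(Z == 1 & p >= t)
      fp <- sum(Z == 0 & p >= t)
      prec <- tp / (tp + fp)
      rec <- tp / sum(Z == 1)
      out <- out + (rec - r_prev) * prec
      r_prev <- rec
    }
    out
  }
  for (s in 1:10) {
    set.seed(200 + s)
    n <- sample(6:20, 1)
    Z <- c(1, 0, rbinom(n - 2, 1, 0.3))
    p <- round(runif(n), 1)
    expect_equal(pr_auc(Z, p), ap_oracle(Z, p), tolerance = 1e-12)
  }
})

test_that("PR-AUC of a random scorer converges to the prevalence", {
  set.seed(9)
  Z <- rbinom(20000, 1, 0.25)
  p <- runif(20000)
  expect_lte(abs(pr_auc(Z, p) - 0.25), 0.02)
})

test_that("fold aggregation gives hand-checkable normal CIs", {
  aucs <- seq(0.78, 0.82, length.out = 10)
  bundles <- lapply(aucs, function(a) {
    b <- confusion_metrics(c(1, 0), c(0.9, 0.1))
    b$auc <- a
    b$pr_auc <- a
    b
  })
  agg <- aggregate_with_ci(bundles)
  row <- agg[agg$metric == "auc", ]
  expect_equal(row$mean, 0.80, tolerance = 1e-12)
  half <- 1.959964 * sd(aucs) / sqrt(10)
  expect_equal(row$ci_high - row$mean, half, tolerance = 1e-6)
  expect_true(all(agg$ci_low <= agg$mean & agg$mean <= agg$ci_high))
  expect_true(all(agg$ci_low >= 0 & agg$ci_high <= 1))

  # identical folds give a zero-width interval
  same <- aggregate_with_ci(bundles[c(1, 1, 1)])
  r <- same[same$metric == "auc", ]
  expect_equal(r$ci_low, r$ci_high)

  # permutation invariance in fold order
  agg2 <- aggregate_with_ci(rev(bundles))
  expect_equal(agg, agg2)

  expect_error(aggregate_with_ci(bundles[1]), "at least 2")
})
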