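#' Run select-then-refit on one cross-validation fold
#'
#' On the fold's training rows only: PermFIT identifies the features
#' significant at `alpha`; the learner is then refitted on the training rows
#' restricted to the selected features' columns, and predictions are made on
#' the held-out test rows, which were never seen during selection, tuning or
#' fitting. If no feature reaches significance the fold falls back to
#' refitting on all features and is flagged.
#'
#' @param cohort A `permfit_cohort`.
#' @param plan A `fold_plan` from [make_folds()].
#' @param fold_id Which fold serves as the test set.
#' @param learner_config A [learner_config()].
#' @param permfit_config List with elements `S`, `R`, `alpha` controlling
#'   the within-training-set importance test.
#' @param seed Master seed; per-fold seeds are derived from it and the fold
#'   id.
#' @return A `fold_result`: list with `fold`, `learner`, `importance`,
#'   `selected_features`, `fallback_all`, `test_idx`, `predictions`,
#'   `outcomes`, `metrics`.
#' @export
run_fold <- function(cohort, plan, fold_id, learner_config,
                     permfit_config = list(S = 5, R = 10, alpha = 0.05),
                     seed = plan$seed) {
  if (!fold_id %in% seq_len(plan$k)) stop_("fold %s does not exist", fold_id)
  test_idx <- which(plan$assignments == fold_id)
  train_idx <- which(plan$assignments != fold_id)
  train <- subset_cohort(cohort, train_idx)
  fold_seed <- derive_seed(seed, 1000L, fold_id)

  imp <- tryCatch(
    permfit(learner_config, train,
            S = permfit_config$S, R = permfit_config$R,
            alpha = permfit_config$alpha, seed = fold_seed),
    error = function(e) stop_("fold %d: %s", fold_id, conditionMessage(e))
  )
  selected <- imp$feature[imp$significant]
  fallback <- length(selected) == 0
  if (fallback) selected <- schema_names(cohort$schema)

  sub_schema <- restrict_schema(cohort$schema, selected)
  scale_cont <- learner_config$kind %in% c("dnn", "svm")
  enc_train <- encode_design(train, sub_schema, scale_continuous = scale_cont)
  cfg <- learner_config
  cfg$seed <- derive_seed(fold_seed, 2000L)
  fitted <- tryCatch(
    fit_model(cfg, enc_train, train$Z),
    error = function(e) stop_("fold %d refit: %s", fold_id, conditionMessage(e))
  )
  enc_test <- encode_design(subset_cohort(cohort, test_idx), sub_schema,
                            scaling = enc_train$scaling,
                            scale_continuous = scale_cont)
  preds <- predict_proba(fitted, enc_test)

  structure(list(fold = fold_id, learner = learner_config$kind,
                 importance = imp,
                 selected_features = if (fallback) character() else selected,
                 fallback_all = fallback,
                 test_idx = test_idx,
                 predictions = preds, outcomes = cohort$Z[test_idx],
                 metrics = metrics_bundle(cohort$Z[test_idx], preds)),
            class = "fold_result")
}

#' Run the full cross-validated select-then-refit pipeline
#'
#' One stratified fold plan is built once and shared by every learner, so
#' all learners are compared on identical splits. Each learner runs
#' [run_fold()] on each fold; fold metrics are aggregated with confidence
#' intervals, and the feature-significance frequency matrix (how many folds
#' flagged each feature, 0..k) is assembled per learner.
#'
#' @param cohort A `permfit_cohort`.
#' @param learner_kinds Character vector among `"svm"`, `"rf"`, `"xgb"`,
#'   `"dnn"`.
#' @param configs Optional named list of [learner_config()]s per kind; built
#'   from `fast` otherwise.
#' @param k Number of cross-validation folds.
#' @param seed Master seed.
#' @param permfit_config List with `S`, `R`, `alpha`.
#' @param fast Use the reduced profile when building default configs.
#' @param verbose Print per-fold progress.
#' @return A `pipeline_result`: list with `fold_plan`, `fold_results`
#'   (per-learner list of `fold_result`s), `aggregated` (per-learner
#'   [aggregate_with_ci()] tables), and `frequency` (feature x learner
#'   matrix).
#' @export
run_pipeline <- function(cohort, learner_kinds, configs = NULL, k = 10,
                         seed = 1, permfit_config = list(S = 5, R = 10, alpha = 0.05),
                         fast = FALSE, verbose = FALSE) {
  if (!length(learner_kinds)) stop_("need at least one learner kind")
  learner_kinds <- match.arg(learner_kinds, c("svm", "rf", "xgb", "dnn"),
                             several.ok = TRUE)
  if (is.null(configs)) {
    configs <- stats::setNames(
      lapply(learner_kinds, learner_config, seed = seed, fast = fast),
      learner_kinds)
  }
  plan <- make_folds(cohort, k = k, seed = seed, stratified = TRUE)

  fold_results <- lapply(learner_kinds, function(kind) {
    lapply(seq_len(k), function(f) {
      if (verbose) message(sprintf("[%s] fold %d/%d", kind, f, k))
      run_fold(cohort, plan, f, configs[[kind]], permfit_config, seed = seed)
    })
  })
  names(fold_results) <- learner_kinds

  aggregated <- lapply(fold_results, function(fr) {
    aggregate_with_ci(lapply(fr, `[[`, "metrics"))
  })

  structure(list(fold_plan = plan,
                 fold_results = fold_results,
                 aggregated = aggregated,
                 frequency = feature_frequency(fold_results,
                                               schema = cohort$schema)),
            class = "pipeline_result")
}

#' Feature-significance frequency matrix
#'
#' For each feature and learner, the number of cross-validation folds (0..k)
#' in which the feature's importance test was significant — the matrix
#' behind the frequency heatmap.
#'
#' @param fold_results Named list (per learner) of lists of `fold_result`s.
#' @param schema A `feature_schema` fixing feature order.
#' @return Integer matrix, features x learners.
#' @export
feature_frequency <- function(fold_results, schema) {
  ks <- vapply(fold_results, length, 0L)
  if (length(unique(ks)) != 1) stop_("all learners must share the fold count")
  feats <- schema_names(schema)
  out <- vapply(fold_results, function(fr) {
    rowSums(vapply(fr, function(res) {
      imp <- res$importance
      as.integer(imp$significant[match(feats, imp$feature)])
    }, integer(length(feats))))
  }, double(length(feats)))
  out <- matrix(as.integer(out), nrow = length(feats),
                dimnames = list(feats, names(fold_results)))
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline_result: %d learners, k = %d folds, n = %d test records\n",
              length(x$fold_results), x$fold_plan$k,
              length(x$fold_plan$assignments)))
  for (kind in names(x$aggregated)) {
    a <- x$aggregated[[kind]]
    cat(sprintf("  %-4s AUC %.3f (%.3f, %.3f)  PR-AUC %.3f (%.3f, %.3f)\n",
                kind,
                a$mean[a$metric == "auc"], a$ci_low[a$metric == "auc"],
                a$ci_high[a$metric == "auc"],
                a$mean[a$metric == "pr_auc"], a$ci_low[a$metric == "pr_auc"],
                a$ci_high[a$metric == "pr_auc"]))
  }
  invisible(x)
}
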