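#' Permute one feature's column block
#'
#' Applies a single uniform random permutation jointly to all columns of the
#' feature's block (so one-hot indicator rows move as units); every other
#' column is untouched.
#'
#' @param encoded An `encoded_matrix`.
#' @param feature Feature name present in the block map.
#' @param seed Integer seed for the permutation.
#' @return An `encoded_matrix` with the block permuted.
#' @export
permute_feature <- function(encoded, feature, seed) {
  cols <- encoded$block_map[[feature]]
  if (is.null(cols)) stop_("unknown feature '%s'", feature)
  perm <- with_seed(seed, sample.int(nrow(encoded$M)))
  out <- encoded
  out$M[, cols] <- encoded$M[perm, cols, drop = FALSE]
  out
}

#' Per-sample permutation importance score
#'
#' The log-likelihood contrast between the model's prediction on the intact
#' record and on the record with feature j permuted:
#' `z * log(p_orig/p_perm) + (1 - z) * log((1 - p_orig)/(1 - p_perm))`.
#' Positive on average when permuting the feature destroys information the
#' model was using. Vectorized over samples.
#'
#' @param z 0/1 outcome(s).
#' @param p_orig Predicted probability on the intact record(s).
#' @param p_perm Predicted probability with the feature permuted.
#' @return Numeric score(s), finite by the probability-clipping contract.
#' @export
per_sample_score <- function(z, p_orig, p_perm) {
  if (any(p_orig < PROB_EPS - 1e-15) || any(p_orig > 1 - PROB_EPS + 1e-15) ||
      any(p_perm < PROB_EPS - 1e-15) || any(p_perm > 1 - PROB_EPS + 1e-15)) {
    stop_("probabilities must lie within the clipping range [%g, %g]",
          PROB_EPS, 1 - PROB_EPS)
  }
  if (!all(z %in% c(0, 1))) stop_("z must be 0 or 1")
  z * log(p_orig / p_perm) + (1 - z) * log((1 - p_orig) / (1 - p_perm))
}

#' Importance estimate and hypothesis test from per-sample scores
#'
#' The feature importance estimate is the mean per-sample score; its
#' variance is estimated as the sample variance of the scores divided by n.
#' The test statistic `z = lambda_hat / sqrt(var_hat)` is compared with the
#' upper tail of the standard normal: importance is nonnegative in
#' population, so evidence against the null is a large positive mean. When
#' every score is identical the variance estimate is zero; the p-value is
#' then 0 for a positive mean and 1 otherwise, with a warning.
#'
#' @param scores Numeric vector of per-sample scores (length >= 2).
#' @param alpha Significance level.
#' @param feature Optional feature name carried into the record.
#' @return One-row data frame: `feature`, `lambda_hat`, `var_hat`, `z_stat`,
#'   `p_value`, `significant`.
#' @export
importance_from_scores <- function(scores, alpha = 0.05, feature = NA_character_) {
  n <- length(scores)
  if (n < 2) stop_("need at least 2 scores")
  lambda_hat <- mean(scores)
  var_hat <- var(scores) / n
  if (var_hat == 0) {
    warning("all per-sample scores identical; degenerate variance estimate")
    z_stat <- if (lambda_hat > 0) Inf else -Inf
    p_value <- if (lambda_hat > 0) 0 else 1
  } else {
    z_stat <- lambda_hat / sqrt(var_hat)
    p_value <- pnorm(z_stat, lower.tail = FALSE)
  }
  data.frame(feature = feature, lambda_hat = lambda_hat, var_hat = var_hat,
             z_stat = z_stat, p_value = p_value,
             significant = p_value < alpha,
             stringsAsFactors = FALSE)
}

#' Permutation feature importance test (PermFIT)
#'
#' Tests each feature's conditional contribution to a black-box risk model.
#' The cohort is split into `S` cross-fitting folds; for each fold the
#' learner is fitted on the complement and predictions are made on the
#' held-out rows, so no record is ever scored by a model that saw it. For
#' each feature, its encoded column block in the held-out design is permuted
#' `R` times (independent permutations); the per-sample log-likelihood
#' contrasts are averaged over the `R` draws. The n pooled per-sample scores
#' per feature feed the z-test of [importance_from_scores()].
#'
#' @param learner_config A [learner_config()]; for kind `"dnn"` with
#'   `ensemble = TRUE` the stable bootstrap-filtered ensemble is used.
#' @param cohort A `permfit_cohort`.
#' @param schema A `feature_schema`; defaults to the cohort's.
#' @param S Cross-fitting folds (>= 2).
#' @param R Permutations per feature averaged per sample (>= 1); `R = 1` is
#'   the literal single-permutation formulation.
#' @param alpha Significance level for the per-feature flag.
#' @param seed Integer seed controlling folds, fits and permutations.
#'
#' @return An `importance_table`: data frame with one row per schema
#'   feature (in schema order) and columns `feature`, `lambda_hat`,
#'   `var_hat`, `z_stat`, `p_value`, `significant`; attributes record the
#'   learner kind, `alpha`, `S`, `R` and `seed`.
#' @export
permfit <- function(learner_config, cohort, schema = cohort$schema,
                    S = 5, R = 10, alpha = 0.05, seed = 1) {
  if (S < 2) stop_("S must be at least 2")
  if (R < 1) stop_("R must be at least 1")
  feats <- schema_names(schema)
  p <- length(feats)
  n <- cohort$n
  scale_cont <- learner_config$kind %in% c("dnn", "svm")

  plan <- make_folds(cohort, k = S, seed = derive_seed(seed, 7L),
                     stratified = TRUE)
  scores <- matrix(NA_real_, n, p, dimnames = list(NULL, feats))

  for (s in seq_len(S)) {
    test_idx <- which(plan$assignments == s)
    train_idx <- which(plan$assignments != s)

    enc_train <- encode_design(subset_cohort(cohort, train_idx), schema,
                               scale_continuous = scale_cont)
    cfg <- learner_config
    cfg$seed <- derive_seed(seed, 11L, s)
    fitted <- tryCatch(
      fit_model(cfg, enc_train, cohort$Z[train_idx]),
      error = function(e) stop_("learner fit failed in cross-fit fold %d: %s",
                                s, conditionMessage(e))
    )

    enc_test <- encode_design(subset_cohort(cohort, test_idx), schema,
                              scaling = enc_train$scaling,
                              scale_continuous = scale_cont)
    p_orig <- predict_proba(fitted, enc_test)

    # stack all p x R permuted copies and predict once per fold
    m <- length(test_idx)
    stacks <- vector("list", p * R)
    k <- 0L
    for (j in seq_len(p)) {
      for (r in seq_len(R)) {
        k <- k + 1L
        stacks[[k]] <- permute_feature(enc_test, feats[j],
                                       seed = derive_seed(seed, 13L, s, j, r))$M
      }
    }
    big <- encoded_like(enc_test, do.call(rbind, stacks))
    p_perm_all <- predict_proba(fitted, big)

    zte <- cohort$Z[test_idx]
    k <- 0L
    for (j in seq_len(p)) {
      acc <- numeric(m)
      for (r in seq_len(R)) {
        block <- p_perm_all[(k * m + 1):((k + 1) * m)]
        acc <- acc + per_sample_score(zte, p_orig, block)
        k <- k + 1L
      }
      scores[test_idx, j] <- acc / R
    }
  }

  tab <- do.call(rbind, lapply(seq_len(p), function(j) {
    importance_from_scores(scores[, j], alpha = alpha, feature = feats[j])
  }))
  rownames(tab) <- NULL
  structure(tab,
            class = c("importance_table", "data.frame"),
            learner = learner_config$kind, alpha = alpha,
            S = S, R = R, seed = seed,
            per_sample_scores = scores,
            fold_assignments = plan$assignments)
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("PermFIT importance (learner = %s, S = %d, R = %d, alpha = %g)\n",
              attr(x, "learner"), attr(x, "S"), attr(x, "R"), attr(x, "alpha")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write an importance table to CSV or JSON
#'
#' @param table An `importance_table`.
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_importance <- function(table, path) {
  df <- as.data.frame(table)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
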