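#' Configure a learner
#'
#' Builds a configuration for one of the four supported learners with the
#' study defaults: random forest with 1000 trees and minimum node size 3;
#' XGBoost with learning rate 0.3, maximum depth 5 and up to 5 boosting
#' rounds chosen by internal cross-validation; RBF-kernel SVM with gamma and
#' cost tuned over decade grids by internal 5-fold cross-validation and
#' Platt-scaled probabilities; and a deep neural network with hidden layers
#' (50, 40, 30, 20) trained by minibatch gradient descent with adaptive
#' learning rate for 1000 epochs at batch size 30. For `kind = "dnn"`,
#' `ensemble = TRUE` requests the bootstrap-filtered stable ensemble with
#' `B` members (see [fit_stable_dnn()]); `ensemble = FALSE` fits a single
#' network.
#'
#' @param kind One of `"svm"`, `"rf"`, `"xgb"`, `"dnn"`.
#' @param seed Integer seed controlling all fitting randomness.
#' @param fast Use the reduced continuous-integration profile (100 epochs,
#'   B = 20 ensemble members, 200 trees, narrower SVM grid). The study
#'   defaults remain the full profile.
#' @param ... Overrides for individual hyperparameters (e.g. `num_trees`,
#'   `epochs`, `B`, `gamma_grid`).
#'
#' @return An object of class `learner_config`.
#' @export
learner_config <- function(kind, seed = 1, fast = FALSE, ...) {
  kind <- match.arg(kind, c("svm", "rf", "xgb", "dnn"))
  cfg <- switch(kind,
    rf = list(num_trees = 1000, min_node_size = 3),
    xgb = list(eta = 0.3, max_depth = 5, nrounds_max = 5, tune = TRUE),
    svm = list(gamma_grid = 10^(-3:3), cost_grid = 10^(-3:3),
               tune = TRUE, cv_folds = 5),
    dnn = list(hidden = c(50, 40, 30, 20), epochs = 1000, batch_size = 30,
               lr = 1e-3, weight_decay = 1e-4, dropout = 0.3,
               lr_factor = 0.5, lr_patience = 20, min_lr = 1e-5,
               ensemble = TRUE, B = 100)
  )
  if (fast) {
    cfg <- utils::modifyList(cfg, switch(kind,
      rf = list(num_trees = 200),
      xgb = list(),
      svm = list(gamma_grid = 10^(-2:1), cost_grid = 10^(-2:1), cv_folds = 3),
      dnn = list(epochs = 100, B = 20)
    ))
  }
  cfg <- utils::modifyList(cfg, list(...))
  cfg$kind <- kind
  cfg$seed <- as.integer(seed)
  cfg$fast <- fast
  structure(cfg, class = "learner_config")
}

as_design <- function(M) {
  if (inherits(M, "encoded_matrix")) M$M else as.matrix(M)
}

check_training_inputs <- function(M, Z) {
  if (!all(is.finite(M))) stop_("design matrix contains non-finite values")
  if (length(unique(Z)) < 2) stop_("outcome has a single class; cannot fit")
  if (nrow(M) != length(Z)) stop_("design and outcome lengths differ")
  invisible(TRUE)
}

#' Fit a single learner
#'
#' Fits one base learner of the configured kind on an encoded design matrix
#' and a 0/1 outcome. For `kind = "dnn"` this fits a single network; the
#' bootstrap-filtered ensemble lives in [fit_stable_dnn()].
#'
#' @param config A [learner_config()].
#' @param M An `encoded_matrix` or numeric matrix.
#' @param Z Integer 0/1 outcomes.
#' @return A fitted learner supporting [predict_proba()].
#' @export
fit_learner <- function(config, M, Z) {
  X <- as_design(M)
  check_training_inputs(X, Z)
  fit <- switch(config$kind,
                rf = fit_rf(config, X, Z),
                xgb = fit_xgb(config, X, Z),
                svm = fit_svm(config, X, Z),
                dnn = fit_dnn(config, X, Z))
  fit$config <- config
  fit$train_columns <- colnames(X)
  class(fit) <- c(paste0("permfit_", config$kind), "fitted_learner")
  fit
}

fit_rf <- function(config, X, Z) {
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  df$.outcome <- factor(Z, levels = c(0, 1))
  fit <- ranger::ranger(dependent.variable.name = ".outcome", data = df,
                        num.trees = config$num_trees,
                        min.node.size = config$min_node_size,
                        probability = TRUE, seed = config$seed,
                        num.threads = 1)
  list(fit = fit)
}

fit_xgb <- function(config, X, Z) {
  params <- list(objective = "binary:logistic", eta = config$eta,
                 max_depth = config$max_depth, nthread = 1,
                 eval_metric = "logloss")
  dtrain <- xgboost::xgb.DMatrix(X, label = Z)
  nrounds <- config$nrounds_max
  if (isTRUE(config$tune)) {
    cv <- with_seed(config$seed, xgboost::xgb.cv(
      params = params, data = dtrain, nrounds = config$nrounds_max,
      nfold = 5, verbose = 0, stratified = TRUE))
    log <- cv$evaluation_log
    nrounds <- which.min(log$test_logloss_mean)
  }
  fit <- with_seed(config$seed, xgboost::xgb.train(
    params = params, data = dtrain, nrounds = nrounds, verbose = 0))
  list(fit = fit, nrounds = nrounds)
}

fit_svm <- function(config, X, Z) {
  y <- factor(Z, levels = c(0, 1))
  gamma <- 1 / ncol(X)
  cost <- 1
  if (isTRUE(config$tune)) {
    grid <- expand.grid(gamma = config$gamma_grid, cost = config$cost_grid)
    acc <- with_seed(config$seed, apply(grid, 1, function(g) {
      cvfit <- e1071::svm(X, y, kernel = "radial", gamma = g[["gamma"]],
                          cost = g[["cost"]], cross = config$cv_folds)
      cvfit$tot.accuracy
    }))
    best <- which.max(acc)
    gamma <- grid$gamma[best]
    cost <- grid$cost[best]
  }
  fit <- with_seed(config$seed,
                   e1071::svm(X, y, kernel = "radial", gamma = gamma,
                              cost = cost, probability = TRUE))
  list(fit = fit, gamma = gamma, cost = cost)
}

#' Predict class-1 probabilities from a fitted learner
#'
#' Probabilities are clipped to `[1e-6, 1 - 1e-6]` for every learner: the
#' permutation importance score takes logarithms of these values. The column
#' layout of `M` must match the training layout.
#'
#' @param learner A fitted learner or `dnn_ensemble`.
#' @param M An `encoded_matrix` or numeric matrix.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(learner, M) UseMethod("predict_proba")

check_predict_columns <- function(learner, X) {
  if (!identical(colnames(X), learner$train_columns)) {
    stop_("prediction column layout does not match training layout")
  }
}

#' @export
predict_proba.permfit_rf <- function(learner, M) {
  X <- as_design(M)
  check_predict_columns(learner, X)
  df <- as.data.frame(X)
  names(df) <- make.names(colnames(X))
  p <- predict(learner$fit, data = df, num.threads = 1)$predictions[, "1"]
  clip_prob(unname(p))
}

#' @export
predict_proba.permfit_xgb <- function(learner, M) {
  X <- as_design(M)
  check_predict_columns(learner, X)
  clip_prob(predict(learner$fit, xgboost::xgb.DMatrix(X)))
}

#' @export
predict_proba.permfit_svm <- function(learner, M) {
  X <- as_design(M)
  check_predict_columns(learner, X)
  pr <- attr(predict(learner$fit, X, probability = TRUE), "probabilities")
  clip_prob(unname(pr[, "1"]))
}

#' @export
predict_proba.permfit_dnn <- function(learner, M) {
  X <- as_design(M)
  check_predict_columns(learner, X)
  clip_prob(as.double(.mlp_predict(learner$W, learner$b, X)))
}

# Route a config to the model the study protocol uses for that kind: the
# stable bootstrap-filtered ensemble for DNN (unless ensemble = FALSE), the
# base learner otherwise.
fit_model <- function(config, M, Z) {
  if (config$kind == "dnn" && isTRUE(config$ensemble) && config$B > 1) {
    fit_stable_dnn(M, Z, B = config$B, config = config)
  } else {
    fit_learner(config, M, Z)
  }
}
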