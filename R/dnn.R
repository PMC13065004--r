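# Single-network fit: ReLU hidden layers (50, 40, 30, 20 by default),
# sigmoid output, cross-entropy loss, minibatch Adam with decoupled weight
# decay and reduce-on-plateau learning-rate decay. Training is fully
# deterministic given config$seed.
fit_dnn <- function(config, X, Z) {
  res <- .mlp_train(X, as.double(Z), as.integer(config$hidden),
                    epochs = as.integer(config$epochs),
                    batch_size = as.integer(config$batch_size),
                    lr = config$lr, weight_decay = config$weight_decay,
                    dropout = config$dropout,
                    seed = config$seed, lr_factor = config$lr_factor,
                    lr_patience = as.integer(config$lr_patience),
                    min_lr = config$min_lr)
  list(W = res$W, b = res$b, loss_trajectory = res$loss_trajectory)
}

#' Fit a stabilized bootstrap-filtered DNN ensemble
#'
#' A single deep network on tabular data of this size is unstable under
#' random initialization. The stable ensemble fits `B` networks on bootstrap
#' resamples, scores each member by its cross-entropy on the rows it did not
#' see (out-of-bag), ranks members from best to worst, and then chooses how
#' many of the top members to keep by minimizing the cross-entropy of the
#' prefix-ensemble average on the full training sample. The ensemble
#' prediction is the arithmetic mean of the kept members' probabilities,
#' clipped to the probability bounds.
#'
#' @param M An `encoded_matrix` or numeric matrix.
#' @param Z Integer 0/1 outcomes.
#' @param B Number of bootstrap members (>= 1).
#' @param config A [learner_config()] of kind `"dnn"` supplying the network
#'   hyperparameters and master seed.
#' @return An object of class `dnn_ensemble` with the kept members (in score
#'   order; only these contribute to prediction), all fitted members and
#'   their out-of-bag scores, the prefix training losses and the selected
#'   ensemble size `k_star`.
#' @export
fit_stable_dnn <- function(M, Z, B = 100, config = learner_config("dnn")) {
  X <- as_design(M)
  check_training_inputs(X, Z)
  if (B < 1) stop_("B must be at least 1")
  n <- nrow(X)

  members <- vector("list", B)
  oob_scores <- double(B)
  train_probs <- matrix(NA_real_, n, B)
  for (bb in seq_len(B)) {
    bs <- derive_seed(config$seed, 101L, bb)
    idx <- with_seed(bs, sample.int(n, n, replace = TRUE))
    mcfg <- config
    mcfg$seed <- derive_seed(config$seed, 202L, bb)
    fit <- fit_dnn(mcfg, X[idx, , drop = FALSE], Z[idx])
    p_all <- clip_prob(as.double(.mlp_predict(fit$W, fit$b, X)))
    train_probs[, bb] <- p_all
    oob <- setdiff(seq_len(n), idx)
    # an empty out-of-bag set is essentially impossible for n >= 50; fall
    # back to in-bag scoring if it ever happens
    oob_scores[bb] <- if (length(oob)) {
      cross_entropy(Z[oob], p_all[oob])
    } else {
      cross_entropy(Z[idx], p_all[idx])
    }
    members[[bb]] <- fit
  }

  ord <- order(oob_scores)
  cum <- matrixStats_cumsum(train_probs[, ord, drop = FALSE])
  prefix_loss <- vapply(seq_len(B), function(k) {
    cross_entropy(Z, clip_prob(cum[, k] / k))
  }, 0)
  k_star <- which.min(prefix_loss)

  structure(list(members = members[ord][seq_len(k_star)],
                 member_scores = oob_scores[ord][seq_len(k_star)],
                 all_members = members[ord],
                 all_member_scores = oob_scores[ord],
                 prefix_losses = prefix_loss,
                 k_star = k_star, B = B,
                 config = config,
                 train_columns = colnames(X)),
            class = "dnn_ensemble")
}

# row-wise cumulative sums over columns
matrixStats_cumsum <- function(M) {
  if (ncol(M) == 1L) return(M)
  t(apply(M, 1, cumsum))
}

#' @export
predict_proba.dnn_ensemble <- function(learner, M) {
  X <- as_design(M)
  check_predict_columns(learner, X)
  P <- vapply(learner$members, function(m) {
    as.double(.mlp_predict(m$W, m$b, X))
  }, double(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  clip_prob(rowMeans(P))
}

#' @export
print.dnn_ensemble <- function(x, ...) {
  cat(sprintf("dnn_ensemble: kept %d of %d bootstrapped networks (prefix training loss %.4f)\n",
              x$k_star, x$B, x$prefix_losses[x$k_star]))
  invisible(x)
}
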