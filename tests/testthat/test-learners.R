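make_xy <- function(n = 200, seed = 1) {
  co <- signal_cohort(n = n, seed = seed)
  enc <- encode_design(co)
  list(co = co, enc = enc)
}

test_that("random forest separates a threshold rule perfectly in training", {
  # oracle: z = 1 iff x > 0 is exactly representable by one split
  x <- matrix(seq(-1, 1, length.out = 200), ncol = 1,
              dimnames = list(NULL, "x"))
  z <- as.integer(x[, 1] > 0)
  fit <- fit_learner(learner_config("rf", seed = 1), x, z)
  acc <- mean((predict_proba(fit, x) >= 0.5) == z)
  expect_equal(acc, 1.0)
})

test_that("every learner honors the probability clipping contract", {
  d <- make_xy(150, seed = 11)
  for (kind in c("rf", "xgb", "svm", "dnn")) {
    cfg <- fast_cfg(kind, seed = 5, ensemble = FALSE)
    fit <- fit_learner(cfg, d$enc, d$co$Z)
    p <- predict_proba(fit, d$enc)
    expect_true(all(p >= 1e-6 & p <= 1 - 1e-6), label = kind)
    expect_length(p, d$co$n)
  }
  ens <- fit_stable_dnn(d$enc, d$co$Z, B = 3,
                        config = fast_cfg("dnn", seed = 5))
  p <- predict_proba(ens, d$enc)
  expect_true(all(p >= 1e-6 & p <= 1 - 1e-6))
})

test_that("seeded refits reproduce predictions exactly", {
  d <- make_xy(200, seed = 13)
  for (kind in c("rf", "xgb", "dnn")) {
    cfg <- fast_cfg(kind, seed = 42, ensemble = FALSE)
    p1 <- predict_proba(fit_learner(cfg, d$enc, d$co$Z), d$enc)
    p2 <- predict_proba(fit_learner(cfg, d$enc, d$co$Z), d$enc)
    expect_identical(p1, p2, label = kind)
  }
})

test_that("prediction is row-wise: duplication and permutation behave", {
  d <- make_xy(120, seed = 3)
  fit <- fit_learner(fast_cfg("rf", seed = 2), d$enc, d$co$Z)
  M <- d$enc$M
  dup <- rbind(M[1, , drop = FALSE], M[1, , drop = FALSE])
  pd <- predict_proba(fit, dup)
  expect_identical(pd[1], pd[2])
  perm <- sample.int(nrow(M))
  expect_identical(predict_proba(fit, M[perm, ]), predict_proba(fit, M)[perm])
})

test_that("degenerate inputs are rejected", {
  d <- make_xy(100, seed = 6)
  expect_error(fit_learner(fast_cfg("rf"), d$enc, rep(1L, d$co$n)),
               "single class")
  bad <- d$enc$M
  bad[3, 2] <- NA
  expect_error(fit_learner(fast_cfg("xgb"), bad, d$co$Z), "non-finite")
  fit <- fit_learner(fast_cfg("xgb", seed = 1), d$enc, d$co$Z)
  expect_error(predict_proba(fit, d$enc$M[, -1]), "layout")
})

test_that("predicted risk is calibrated on a zero-effect cohort", {
  co <- null_cohort(n = 800, p = 10, seed = 31)
  enc <- encode_design(co)
  fit <- fit_learner(fast_cfg("rf", seed = 31), enc, co$Z)
  expect_lte(abs(mean(predict_proba(fit, enc)) - 0.25), 0.05)
})

test_that("SVM probabilities are a monotone link of decision values", {
  d <- make_xy(150, seed = 19)
  cfg <- fast_cfg("svm", seed = 7, tune = FALSE)
  fit <- fit_learner(cfg, d$enc, d$co$Z)
  p <- predict_proba(fit, d$enc)
  dec <- as.double(attr(predict(fit$fit, d$enc$M, decision.values = TRUE),
                        "decision.values"))
  a_p <- roc_auc(d$co$Z, p)
  a_d <- roc_auc(d$co$Z, dec)
  expect_lt(min(abs(a_p - a_d), abs(a_p - (1 - a_d))), 1e-8)
})
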