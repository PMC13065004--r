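test_that("feature permutation moves whole blocks and preserves multisets", {
  co <- generate_cohort(n = 200, seed = 15)
  enc <- encode_design(co)

  perm <- permute_feature(enc, "surgery_type", seed = 5)
  st <- enc$block_map$surgery_type
  # rows move as units: one-hot rows still sum to 1
  expect_true(all(rowSums(perm$M[, st]) == 1))
  # multiset of each permuted column preserved bit-level
  for (j in st) expect_identical(sort(perm$M[, j]), sort(enc$M[, j]))
  # all other columns untouched
  other <- setdiff(seq_len(ncol(enc$M)), st)
  expect_identical(perm$M[, other], enc$M[, other])

  # permuting a constant column changes nothing
  co2 <- co
  co2$X$hypertension <- rep(1L, co$n)
  enc2 <- encode_design(co2)
  expect_identical(permute_feature(enc2, "hypertension", seed = 3)$M, enc2$M)

  expect_error(permute_feature(enc, "nope", seed = 1), "unknown feature")
})

test_that("per-sample score matches hand evaluation", {
  expect_equal(per_sample_score(1, 0.8, 0.4), log(2), tolerance = 1e-10)
  expect_equal(per_sample_score(0, 0.2, 0.6), log(0.8 / 0.4), tolerance = 1e-10)
  # identity case: no change in prediction, no score
  expect_identical(per_sample_score(1, 0.37, 0.37), 0)
  expect_identical(per_sample_score(0, 0.37, 0.37), 0)
  # vectorized
  expect_equal(per_sample_score(c(1, 0), c(0.8, 0.2), c(0.4, 0.6)),
               c(log(2), log(2)))
  expect_error(per_sample_score(1, 0, 0.5), "clipping range")
  expect_error(per_sample_score(2, 0.5, 0.5), "0 or 1")
})

test_that("importance test matches an independent hand computation", {
  scores <- c(0.6931, 0.2231, 0.0, 0.5108)
  rec <- importance_from_scores(scores, alpha = 0.05, feature = "f")
  # oracle: explicit mean, sample variance / n, and normal tail
  n <- 4
  mu <- sum(scores) / n
  s2 <- sum((scores - mu)^2) / (n - 1)
  z <- mu / sqrt(s2 / n)
  expect_equal(rec$lambda_hat, mu, tolerance = 1e-12)
  expect_equal(rec$var_hat, s2 / n, tolerance = 1e-12)
  expect_equal(rec$z_stat, z, tolerance = 1e-12)
  expect_equal(rec$p_value, 1 - pnorm(z), tolerance = 1e-12)
  # frozen values from the hand computation
  expect_lt(abs(rec$lambda_hat - 0.35675), 1e-4)
  expect_lt(abs(rec$z_stat - 2.327205), 1e-4)
  expect_lt(abs(rec$p_value - 0.0099772), 1e-4)
  expect_true(rec$significant)
})

test_that("importance test edge cases behave as documented", {
  rec0 <- suppressWarnings(importance_from_scores(rep(0, 10)))
  expect_identical(rec0$lambda_hat, 0)
  expect_false(rec0$significant)
  expect_identical(rec0$p_value, 1)
  expect_warning(importance_from_scores(rep(0.3, 5)), "degenerate")
  # z is scale-equivariant: scaling scores by c > 0 leaves it unchanged
  sc <- c(0.2, -0.1, 0.5, 0.3, 0.05)
  expect_equal(importance_from_scores(sc)$z_stat,
               importance_from_scores(10 * sc)$z_stat, tolerance = 1e-12)
  expect_error(importance_from_scores(0.5), "at least 2")
})

test_that("pooled per-fold scores reproduce the published formulas one-pass", {
  co <- signal_cohort(n = 400, seed = 61)
  imp <- quiet_permfit(fast_cfg("xgb", seed = 61), co, S = 3, R = 2, seed = 61)
  scores <- attr(imp, "per_sample_scores")
  expect_identical(dim(scores), c(400L, 10L))
  expect_true(all(is.finite(scores)))
  for (j in c(1, 5, 10)) {
    v <- scores[, j]
    mu <- sum(v) / length(v)
    s2 <- sum((v - mu)^2) / (length(v) - 1)
    expect_equal(imp$lambda_hat[j], mu, tolerance = 1e-12)
    expect_equal(imp$var_hat[j], s2 / length(v), tolerance = 1e-12)
  }
})

test_that("permfit is deterministic and returns schema-ordered records", {
  co <- signal_cohort(n = 300, seed = 71)
  i1 <- quiet_permfit(fast_cfg("xgb", seed = 2), co, S = 3, R = 2, seed = 9)
  i2 <- quiet_permfit(fast_cfg("xgb", seed = 2), co, S = 3, R = 2, seed = 9)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
  expect_identical(i1$feature, names(co$schema$specs))
  expect_identical(nrow(i1), 10L)
  expect_identical(i1$significant, i1$p_value < 0.05)
  expect_true(all(i1$var_hat >= 0))
  expect_true(all(i1$p_value >= 0 & i1$p_value <= 1))
})

test_that("mean importance is nondecreasing in the true coefficient", {
  grid <- c(0, 0.5, 1.0, 1.5)
  lam <- vapply(grid, function(b) {
    mean(vapply(1:3, function(s) {
      co <- generate_cohort(toy_schema(6), n = 800,
                            effects = effect_spec(linear = list(c1 = b)),
                            seed = 800 + s)
      imp <- quiet_permfit(fast_cfg("xgb", seed = s), co, S = 3, R = 3,
                           seed = 900 + s)
      imp$lambda_hat[imp$feature == "c1"]
    }, 0))
  }, 0)
  expect_true(all(diff(lam) >= -1e-6))
})

test_that("importance tables export to CSV and JSON", {
  co <- signal_cohort(n = 200, seed = 81)
  imp <- quiet_permfit(fast_cfg("xgb", seed = 3), co, S = 2, R = 1, seed = 3)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_importance(imp, csv)
  write_importance(imp, js)
  back <- read.csv(csv)
  expect_identical(back$feature, imp$feature)
  js_back <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(js_back$lambda_hat, imp$lambda_hat, tolerance = 1e-12)
})
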