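test_that("intercept calibration hits the prevalence target", {
  effs <- list(
    effect_spec(),
    default_effects(),
    effect_spec(linear = list(x1 = 2, c1 = 1.5),
                interactions = list(list(a = "x1", b = "c1", coef = 1)),
                nonlinear = list(list(feature = "c2", transform = "square",
                                      coef = 0.5)))
  )
  for (i in seq_along(effs)) {
    sch <- if (i == 2) default_schema() else toy_schema(10)
    for (target in c(0.1, 0.25, 0.5)) {
      co <- generate_cohort(sch, n = 2000, effects = effs[[i]],
                            prevalence_target = target, seed = 42 + i)
      expect_lte(abs(mean(co$pi_true) - target), 0.005)
      expect_true(all(co$pi_true > 0 & co$pi_true < 1))
      expect_true(all(co$Z %in% c(0L, 1L)))
      expect_false(anyNA(co$X))
    }
  }
})

test_that("zero-effect cohort prevalence is binomially consistent with target", {
  co <- generate_cohort(toy_schema(10), n = 10000, effects = effect_spec(),
                        prevalence_target = 0.25, seed = 7)
  sd3 <- 3 * sqrt(0.25 * 0.75 / 10000)
  expect_lte(abs(mean(co$Z) - 0.25), sd3)
  # all-zero effects make every record share the same true risk
  expect_equal(stats::var(co$pi_true), 0)
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_cohort(n = 200, seed = 99)
  b <- generate_cohort(n = 200, seed = 99)
  expect_identical(a, b)
  c <- generate_cohort(n = 200, seed = 100)
  expect_false(identical(a$X, c$X))
})

test_that("empirical marginals match the schema at large n", {
  co <- generate_cohort(n = 200000, effects = effect_spec(), seed = 5)
  sch <- co$schema
  # oracle: direct frequency counts
  expect_lte(abs(mean(co$X$gender == "male") - 0.5963), 0.005)
  for (lev in sch$specs[["surgery_type"]]$levels) {
    expect_lte(abs(mean(co$X$surgery_type == lev) -
                     sch$specs[["surgery_type"]]$probs[[lev]]), 0.005)
  }
  expect_lte(abs(mean(co$X$hypertension) - 0.5828), 0.005)
  expect_lte(abs(mean(co$X$age) - 64.2), 3 * 15 / sqrt(200000))
})

test_that("effects naming unknown features are rejected", {
  expect_error(generate_cohort(toy_schema(5), n = 100,
                               effects = effect_spec(linear = list(nope = 1))),
               "nope")
})

test_that("null features are independent of the outcome across cohorts", {
  # chi-squared p-values for a null binary feature should look uniform
  pv <- vapply(1:40, function(s) {
    co <- signal_cohort(n = 400, seed = 300 + s)
    suppressWarnings(stats::chisq.test(table(co$X$x5, co$Z))$p.value)
  }, 0)
  expect_gt(suppressWarnings(stats::ks.test(pv, "punif"))$p.value, 0.01)
  expect_lt(mean(pv < 0.05), 0.2)
})

test_that("cohort CSV write/read round-trips exactly", {
  co <- generate_cohort(n = 120, seed = 17)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path, co$schema)
  expect_identical(back$Z, co$Z)
  expect_equal(back$X, co$X)
  # second round trip is bit-stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed cohort CSVs are rejected with located errors", {
  co <- generate_cohort(toy_schema(5), n = 60, effects = effect_spec(),
                        seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)

  lines <- readLines(path)
  hole <- sub("^([^,]*),[^,]*", "\\1,", lines[4])
  writeLines(c(lines[1:3], hole, lines[5:length(lines)]), path)
  expect_error(read_cohort_csv(path, co$schema), "row 3, column 'x2'")

  write_cohort_csv(co, path)
  lines <- readLines(path)
  lines[2] <- sub(",[01]$", ",2", lines[2])
  writeLines(lines, path)
  expect_error(read_cohort_csv(path, co$schema), "infection")

  write_cohort_csv(co, path)
  lines <- readLines(path)
  lines[1] <- paste0(lines[1], ",bogus")
  lines[-1] <- paste0(lines[-1], ",1")
  writeLines(lines, path)
  expect_error(read_cohort_csv(path, co$schema), "unknown column")
})
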