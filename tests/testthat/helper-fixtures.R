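# Small schemas and cohorts built in code for the test suite.

# p-feature schema: (p-2) Bernoulli(0.3) comorbidity-style indicators plus
# two continuous features.
toy_schema <- function(p = 10) {
  stopifnot(p >= 3)
  specs <- c(
    lapply(seq_len(p - 2), function(i) {
      feature_spec(paste0("x", i), "binary", prob = 0.3)
    }),
    list(feature_spec("c1", "continuous", mean = 0, sd = 1),
         feature_spec("c2", "continuous", mean = 5, sd = 2))
  )
  feature_schema(specs)
}

# all-null cohort on the toy schema
null_cohort <- function(n = 500, p = 10, seed = 1, prevalence = 0.25) {
  generate_cohort(toy_schema(p), n = n, effects = effect_spec(),
                  prevalence_target = prevalence, seed = seed)
}

# cohort with two known signals on the toy schema
signal_cohort <- function(n = 1000, seed = 1, b1 = 1.2, b2 = 1.0) {
  generate_cohort(toy_schema(10), n = n,
                  effects = effect_spec(linear = list(x1 = b1, c1 = b2)),
                  seed = seed)
}

# permfit run silencing the documented degenerate-variance warning that
# tree learners emit for features their trees never split on
quiet_permfit <- function(...) suppressWarnings(permfit(...))

fast_cfg <- function(kind, seed = 1, ...) {
  learner_config(kind, seed = seed, fast = TRUE, ...)
}
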