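#' Generate a seeded synthetic ICU surgical cohort
#'
#' Features are drawn mutually independently from the schema marginals; the
#' binary outcome (postoperative infection) follows a logistic model on the
#' linear predictor declared in `effects`. The intercept is calibrated by
#' root finding so that the mean true risk matches `prevalence_target`
#' within 0.005. The same seed reproduces the cohort bit for bit.
#'
#' @param schema A `feature_schema` (default [default_schema()]).
#' @param n Number of records (>= 50).
#' @param effects An `effect_spec` declaring the true signal
#'   (default [default_effects()]).
#' @param prevalence_target Target mean outcome probability in (0,1).
#' @param seed Integer seed.
#'
#' @return An object of class `permfit_cohort`: list with `n`, `X` (typed
#'   feature data frame), `Z` (integer 0/1 outcomes), `pi_true` (true risk),
#'   `signal_set` (features with nonzero true effect), `intercept` and
#'   `schema`.
#' @export
generate_cohort <- function(schema = default_schema(), n,
                            effects = default_effects(),
                            prevalence_target = 0.25, seed = 1) {
  stopifnot(n >= 50)
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop_("prevalence_target must lie strictly in (0,1)")
  }
  validate_effects(effects, schema)
  with_seed(seed, {
    X <- as.data.frame(lapply(schema$specs, function(s) {
      switch(s$kind,
             binary = rbinom(n, 1L, s$prob),
             categorical = factor(sample(s$levels, n, replace = TRUE, prob = s$probs),
                                  levels = s$levels),
             continuous = rnorm(n, s$mean, s$sd))
    }), stringsAsFactors = FALSE)
    names(X) <- schema_names(schema)

    eta0 <- linear_predictor(X, schema, effects)
    intercept <- calibrate_intercept(eta0, prevalence_target)
    pi_true <- stats::plogis(intercept + eta0)
    Z <- rbinom(n, 1L, pi_true)

    structure(list(n = n, X = X, Z = as.integer(Z), pi_true = pi_true,
                   signal_set = signal_features(effects),
                   intercept = intercept, schema = schema),
              class = "permfit_cohort")
  })
}

# Bisection-style root finding for the intercept making mean(plogis(c + eta))
# hit the prevalence target; errors if no root exists in a wide bracket.
calibrate_intercept <- function(eta0, target, tol = 1e-8) {
  f <- function(c0) mean(stats::plogis(c0 + eta0)) - target
  r <- tryCatch(
    uniroot(f, interval = c(-35, 35), tol = tol, maxiter = 200),
    error = function(e) stop_("intercept calibration failed: %s", conditionMessage(e))
  )
  if (abs(f(r$root)) > 0.005) {
    stop_("intercept calibration did not reach the prevalence target")
  }
  r$root
}

#' @export
print.permfit_cohort <- function(x, ...) {
  cat(sprintf("permfit_cohort: n = %d, p = %d, prevalence = %.3f\n",
              x$n, ncol(x$X), mean(x$Z)))
  if (length(x$signal_set)) {
    cat("  signal set:", paste(x$signal_set, collapse = ", "), "\n")
  }
  invisible(x)
}

# Row subset preserving truth metadata.
subset_cohort <- function(cohort, idx) {
  structure(list(n = length(idx),
                 X = cohort$X[idx, , drop = FALSE],
                 Z = cohort$Z[idx],
                 pi_true = cohort$pi_true[idx],
                 signal_set = cohort$signal_set,
                 intercept = cohort$intercept,
                 schema = cohort$schema),
            class = "permfit_cohort")
}

# Restrict a cohort and schema to a feature subset (used by select-then-refit).
restrict_schema <- function(schema, features) {
  feature_schema(unname(schema$specs[features]))
}

#' Write a cohort to CSV / read a cohort back
#'
#' The CSV holds one column per schema feature plus a final `infection`
#' column in {0,1}. Continuous values are written in full precision, so a
#' write/read round trip reproduces the cohort exactly. Missing cells and
#' unknown columns are rejected (complete-case contract); `pi_true` and
#' `signal_set` are synthetic-truth metadata and are not serialized.
#'
#' @param cohort A `permfit_cohort`.
#' @param path CSV file path.
#' @param schema A `feature_schema` the file must conform to.
#' @return `read_cohort_csv` returns a `permfit_cohort` (without `pi_true`);
#'   `write_cohort_csv` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  schema <- cohort$schema
  out <- cohort$X
  for (f in schema_names(schema)) {
    if (schema$specs[[f]]$kind == "continuous") {
      out[[f]] <- sprintf("%.17g", out[[f]])
    }
  }
  out$infection <- cohort$Z
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path, schema = default_schema()) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL)
  want <- c(schema_names(schema), "infection")
  extra <- setdiff(names(raw), want)
  if (length(extra)) stop_("unknown column(s): %s", paste(extra, collapse = ", "))
  miss <- setdiff(want, names(raw))
  if (length(miss)) stop_("missing column(s): %s", paste(miss, collapse = ", "))

  blank <- which(raw == "" | is.na(as.matrix(raw)), arr.ind = TRUE)
  if (nrow(blank)) {
    stop_("missing value at row %d, column '%s'",
          blank[1, 1], names(raw)[blank[1, 2]])
  }

  X <- raw[schema_names(schema)]
  for (f in schema_names(schema)) {
    s <- schema$specs[[f]]
    if (s$kind == "binary") {
      v <- X[[f]]
      if (!all(v %in% c("0", "1"))) {
        stop_("binary feature '%s' has values outside {0,1}", f)
      }
      X[[f]] <- as.integer(v)
    } else if (s$kind == "categorical") {
      bad <- setdiff(unique(X[[f]]), s$levels)
      if (length(bad)) {
        stop_("feature '%s' has level(s) not in schema: %s",
              f, paste(bad, collapse = ", "))
      }
      X[[f]] <- factor(X[[f]], levels = s$levels)
    } else {
      v <- suppressWarnings(as.double(X[[f]]))
      if (anyNA(v)) stop_("feature '%s' has non-numeric values", f)
      X[[f]] <- v
    }
  }
  zc <- raw$infection
  if (!all(zc %in% c("0", "1"))) {
    stop_("outcome column 'infection' must be 0 or 1")
  }
  structure(list(n = nrow(X), X = X, Z = as.integer(zc),
                 pi_true = NULL, signal_set = NULL,
                 intercept = NULL, schema = schema),
            class = "permfit_cohort")
}
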