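#' Declare the outcome-generating effects of a synthetic cohort
#'
#' The synthetic outcome follows a logistic model on a linear predictor
#' assembled from linear, pairwise-interaction and nonlinear terms.
#' Continuous features enter on the standardized scale
#' `(x - mean) / sd` using the schema's population mean and SD, so a
#' coefficient of 1 means one log-odds unit per marginal SD. Binary features
#' enter as 0/1 indicators; categorical features take a named per-level
#' coefficient vector (unnamed levels contribute 0).
#'
#' @param linear Named list/vector: feature name to coefficient (scalar for
#'   binary/continuous, named vector over levels for categorical).
#' @param interactions List of `list(a =, b =, coef =)` pairwise products of
#'   binary/continuous signal values.
#' @param nonlinear List of `list(feature =, transform =, coef =)` with
#'   `transform` one of `"square"` (standardized value squared) or
#'   `"threshold"` (indicator of standardized value above 1); continuous
#'   features only.
#' @param intercept Starting intercept; replaced by calibration in
#'   [generate_cohort()].
#'
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(linear = list(), interactions = list(),
                        nonlinear = list(), intercept = 0) {
  structure(list(linear = as.list(linear), interactions = interactions,
                 nonlinear = nonlinear, intercept = intercept),
            class = "effect_spec")
}

#' Default synthetic ground truth: two signal features among 25
#'
#' Preoperative infection (binary, logistic coefficient 1.2, odds ratio
#' about 3.3) and age (coefficient 1.0 per marginal SD). The remaining 23
#' features are null by construction.
#'
#' @return An `effect_spec`.
#' @export
default_effects <- function() {
  effect_spec(linear = list(preoperative_infection = 1.2, age = 1.0))
}

#' Features carrying a nonzero true effect
#'
#' @param effects An `effect_spec`.
#' @return Character vector of feature names in the signal set.
#' @export
signal_features <- function(effects) {
  nz <- function(x) any(unlist(x) != 0)
  out <- names(effects$linear)[vapply(effects$linear, nz, TRUE)]
  for (t in effects$interactions) if (t$coef != 0) out <- c(out, t$a, t$b)
  for (t in effects$nonlinear) if (t$coef != 0) out <- c(out, t$feature)
  unique(out)
}

validate_effects <- function(effects, schema) {
  nm <- schema_names(schema)
  used <- c(names(effects$linear),
            unlist(lapply(effects$interactions, function(t) c(t$a, t$b))),
            vapply(effects$nonlinear, `[[`, "", "feature"))
  bad <- setdiff(used, nm)
  if (length(bad)) {
    stop_("effect terms name unknown feature(s): %s", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Signal value of one feature on the scale effects are expressed in.
signal_value <- function(x, spec) {
  switch(spec$kind,
         binary = as.double(x),
         continuous = (as.double(x) - spec$mean) / spec$sd,
         stop_("feature '%s' is categorical; interaction/nonlinear terms need binary or continuous features",
               spec$name))
}

# Linear predictor (without intercept) for a raw feature table.
linear_predictor <- function(X, schema, effects) {
  eta <- numeric(nrow(X))
  for (f in names(effects$linear)) {
    spec <- schema$specs[[f]]
    co <- effects$linear[[f]]
    if (spec$kind == "categorical") {
      if (is.null(names(co))) {
        stop_("categorical feature '%s' needs a named per-level coefficient vector", f)
      }
      bad <- setdiff(names(co), spec$levels)
      if (length(bad)) stop_("unknown level(s) %s for feature '%s'",
                             paste(bad, collapse = ", "), f)
      v <- co[match(as.character(X[[f]]), names(co))]
      v[is.na(v)] <- 0
      eta <- eta + as.double(v)
    } else {
      eta <- eta + co * signal_value(X[[f]], spec)
    }
  }
  for (t in effects$interactions) {
    eta <- eta + t$coef *
      signal_value(X[[t$a]], schema$specs[[t$a]]) *
      signal_value(X[[t$b]], schema$specs[[t$b]])
  }
  for (t in effects$nonlinear) {
    spec <- schema$specs[[t$feature]]
    if (spec$kind != "continuous") {
      stop_("nonlinear transform needs a continuous feature, not '%s'", t$feature)
    }
    v <- signal_value(X[[t$feature]], spec)
    g <- switch(match.arg(t$transform, c("square", "threshold")),
                square = v^2,
                threshold = as.double(v > 1))
    eta <- eta + t$coef * g
  }
  eta
}

#' Read or write an effect specification as JSON or YAML
#'
#' @param effects An `effect_spec`.
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `read_effects` returns an `effect_spec`; `write_effects` returns
#'   `path` invisibly.
#' @export
write_effects <- function(effects, path) {
  # per-level coefficient vectors must serialize as named objects
  lin <- lapply(effects$linear, function(x) {
    if (length(x) > 1 || !is.null(names(x))) as.list(x) else x
  })
  doc <- list(linear = lin,
              interactions = effects$interactions,
              nonlinear = effects$nonlinear,
              intercept = effects$intercept)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_effects
#' @export
read_effects <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  lin <- lapply(doc$linear, function(x) if (is.list(x)) unlist(x) else x)
  effect_spec(linear = lin,
              interactions = doc$interactions %||% list(),
              nonlinear = doc$nonlinear %||% list(),
              intercept = doc$intercept %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
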