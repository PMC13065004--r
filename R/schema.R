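#' Declare a single cohort feature
#'
#' A feature specification records the feature's name, its type and its
#' marginal distribution. Binary features carry the probability of a 1,
#' categorical features a named probability per level, and continuous
#' features a mean and standard deviation.
#'
#' @param name Feature name (unique within a schema).
#' @param kind One of `"binary"`, `"categorical"`, `"continuous"`.
#' @param prob For binary features: probability of value 1.
#' @param levels For categorical features: ordered level labels.
#' @param probs For categorical features: probability per level, same order
#'   as `levels` (must sum to 1 within 1e-9).
#' @param mean,sd For continuous features: marginal mean and standard
#'   deviation (`sd > 0`).
#'
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, kind, prob = NULL, levels = NULL, probs = NULL,
                         mean = NULL, sd = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_("feature name must be a non-empty string")
  }
  kind <- match.arg(kind, c("binary", "categorical", "continuous"))
  spec <- list(name = name, kind = kind)
  if (kind == "binary") {
    if (is.null(prob) || prob < 0 || prob > 1) {
      stop_("binary feature '%s' needs prob in [0,1]", name)
    }
    spec$prob <- as.double(prob)
  } else if (kind == "categorical") {
    if (is.null(levels) || is.null(probs) || length(levels) != length(probs)) {
      stop_("categorical feature '%s' needs matching levels and probs", name)
    }
    if (any(probs < 0) || any(probs > 1) || abs(sum(probs) - 1) > 1e-9) {
      stop_("probs of feature '%s' must lie in [0,1] and sum to 1", name)
    }
    if (anyDuplicated(levels)) stop_("duplicate levels in feature '%s'", name)
    spec$levels <- as.character(levels)
    spec$probs <- stats::setNames(as.double(probs), levels)
  } else {
    if (is.null(mean) || is.null(sd) || sd <= 0) {
      stop_("continuous feature '%s' needs a mean and sd > 0", name)
    }
    spec$mean <- as.double(mean)
    spec$sd <- as.double(sd)
  }
  structure(spec, class = "feature_spec")
}

#' Assemble feature specifications into a schema
#'
#' @param specs List of [feature_spec()] objects with unique names.
#' @return An object of class `feature_schema` with elements `specs` (named
#'   list, in declaration order) and `p_features`.
#' @export
feature_schema <- function(specs) {
  if (!length(specs) || !all(vapply(specs, inherits, TRUE, "feature_spec"))) {
    stop_("specs must be a non-empty list of feature_spec objects")
  }
  nm <- vapply(specs, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop_("duplicate feature names: %s", paste(nm[duplicated(nm)], collapse = ", "))
  }
  structure(list(specs = stats::setNames(specs, nm), p_features = length(specs)),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  kinds <- vapply(x$specs, `[[`, "", "kind")
  cat(sprintf("feature_schema: %d features (%d binary, %d categorical, %d continuous)\n",
              x$p_features, sum(kinds == "binary"), sum(kinds == "categorical"),
              sum(kinds == "continuous")))
  invisible(x)
}

#' Default ICU surgical cohort schema (25 features)
#'
#' Baseline demographic, preoperative and operative features of an ICU
#' surgical cohort: age, gender, ethnicity, marital status, insurance,
#' admission type and location, surgery type, and a panel of binary
#' comorbidity/history indicators. Marginals for gender, ethnicity, marital
#' status, insurance, surgery type, hypertension, diabetes, congestive heart
#' failure and mean age reflect the published cohort description; the
#' remaining marginals (age SD, the other comorbidity prevalences, admission
#' splits) are documented assumptions typical of ICU surgical populations.
#' Five Elixhauser-style comorbidity indicators (renal failure, chronic
#' pulmonary disease, peripheral vascular disease, cardiac arrhythmia,
#' deficiency anemia) fill the feature set to 25; they are assumptions, not
#' reported facts.
#'
#' @return A `feature_schema` with exactly 25 features.
#' @export
default_schema <- function() {
  b <- function(name, p) feature_spec(name, "binary", prob = p)
  feature_schema(list(
    feature_spec("age", "continuous", mean = 64.2, sd = 15),
    feature_spec("gender", "categorical",
                 levels = c("male", "female"),
                 probs = c(0.5963, 0.4037)),
    feature_spec("ethnicity", "categorical",
                 levels = c("white", "unknown", "black", "other", "hispanic"),
                 probs = c(0.7339, 0.1323, 0.0560, 0.0484, 0.0294)),
    feature_spec("marital_status", "categorical",
                 levels = c("married", "single", "widowed",
                            "divorced_separated", "other"),
                 probs = c(0.5481, 0.2035, 0.1273, 0.0722, 0.0489)),
    feature_spec("insurance", "categorical",
                 levels = c("medicare_government", "selfpay_private", "medicaid"),
                 probs = c(0.5468, 0.3862, 0.0670)),
    feature_spec("admission_type", "categorical",
                 levels = c("emergency", "elective", "urgent"),
                 probs = c(0.60, 0.30, 0.10)),
    feature_spec("admission_location", "categorical",
                 levels = c("emergency_room", "physician_referral",
                            "hospital_transfer", "other"),
                 probs = c(0.45, 0.30, 0.20, 0.05)),
    feature_spec("surgery_type", "categorical",
                 levels = c("cardiac", "general", "neurologic", "thoracic",
                            "musculoskeletal", "circulatory", "plastic"),
                 probs = c(0.4045, 0.2270, 0.1997, 0.0568,
                           0.0470, 0.0545, 0.0105)),
    b("preoperative_infection", 0.20),
    b("obesity", 0.10),
    b("depression", 0.10),
    b("fluid_electrolyte_disorders", 0.25),
    b("coagulopathy", 0.10),
    b("liver_disease", 0.05),
    b("alcohol_abuse", 0.07),
    b("drug_abuse", 0.04),
    b("cerebrovascular_disease", 0.08),
    b("congestive_heart_failure", 0.199),
    b("hypertension", 0.5828),
    b("diabetes", 0.2654),
    # filler Elixhauser-style comorbidities (assumed marginals)
    b("renal_failure", 0.10),
    b("chronic_pulmonary_disease", 0.18),
    b("peripheral_vascular_disease", 0.07),
    b("cardiac_arrhythmia", 0.25),
    b("deficiency_anemia", 0.15)
  ))
}

schema_names <- function(schema) names(schema$specs)

#' Read or write a feature schema as JSON or YAML
#'
#' The on-disk document is a list of feature records; the format is chosen
#' by file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param schema A `feature_schema`.
#' @param path File path.
#' @return `read_schema` returns a `feature_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
write_schema <- function(schema, path) {
  recs <- lapply(schema$specs, function(s) {
    r <- list(name = s$name, kind = s$kind)
    if (s$kind == "binary") r$prob <- s$prob
    if (s$kind == "categorical") {
      r$levels <- s$levels
      r$probs <- unname(s$probs)
    }
    if (s$kind == "continuous") {
      r$mean <- s$mean
      r$sd <- s$sd
    }
    r
  })
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(unname(recs), path)
  } else {
    jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  feature_schema(lapply(recs, function(r) {
    feature_spec(r$name, r$kind,
                 prob = r$prob,
                 levels = unlist(r$levels), probs = unlist(r$probs),
                 mean = r$mean, sd = r$sd)
  }))
}
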