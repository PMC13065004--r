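#' @keywords internal
"_PACKAGE"

#' @useDynLib permfitr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm rbinom rnorm runif sd uniroot var predict
#' @importFrom utils read.csv write.csv
NULL

# Probability clipping bound shared by every learner: importance scores take
# logarithms of predicted probabilities, so predictions are confined to
# [eps, 1 - eps].
PROB_EPS <- 1e-6

clip_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user code.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and integer offsets, staying within
# 32-bit integer range. Deterministic and collision-resistant enough for
# stream separation across folds, features and bootstrap members.
derive_seed <- function(seed, ...) {
  off <- c(...)
  x <- as.double(seed) %% 2147483647
  for (o in off) {
    x <- (x * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(x)
}

# Binary cross-entropy of predicted probabilities against 0/1 outcomes.
cross_entropy <- function(z, p) {
  p <- clip_prob(p)
  -mean(z * log(p) + (1 - z) * log(1 - p))
}

stop_ <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
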