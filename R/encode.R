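#' Encode a cohort into a numeric design matrix
#'
#' Binary features become single 0/1 columns; categorical features are
#' one-hot encoded (all levels by default, giving the tree/ensemble
#' learners the full indicator block; `drop_reference = TRUE` drops the
#' first level for linear baselines); continuous features are centered and
#' scaled. Scaling constants are computed from the cohort unless supplied,
#' so test data can be encoded with training-set constants. The block map
#' records every feature's contiguous column set, which is what feature
#' permutation moves as a unit.
#'
#' @param cohort A `permfit_cohort`.
#' @param schema A `feature_schema`; defaults to the cohort's.
#' @param scaling Optional scaling table (from a previous encoding) with
#'   columns `column`, `center`, `scale`; applied to continuous columns.
#' @param scale_continuous If `FALSE`, continuous features are left raw
#'   (center 0, scale 1); tree learners receive raw values.
#' @param drop_reference Drop each categorical feature's first level.
#'
#' @return An object of class `encoded_matrix`: list with `M` (numeric
#'   matrix with column names), `block_map` (feature -> column indices),
#'   `scaling` (data frame) and the encoding flags.
#' @export
encode_design <- function(cohort, schema = cohort$schema, scaling = NULL,
                          scale_continuous = TRUE, drop_reference = FALSE) {
  n <- cohort$n
  cols <- list()
  block_map <- list()
  sc_col <- character()
  sc_center <- double()
  sc_scale <- double()

  for (f in schema_names(schema)) {
    s <- schema$specs[[f]]
    x <- cohort$X[[f]]
    if (s$kind == "binary") {
      cols[[f]] <- matrix(as.double(x), ncol = 1,
                          dimnames = list(NULL, f))
    } else if (s$kind == "categorical") {
      bad <- setdiff(unique(as.character(x)), s$levels)
      if (length(bad)) {
        stop_("feature '%s' has level(s) not in schema: %s",
              f, paste(bad, collapse = ", "))
      }
      lev <- if (drop_reference) s$levels[-1] else s$levels
      M <- vapply(lev, function(l) as.double(x == l), double(n))
      M <- matrix(M, nrow = n,
                  dimnames = list(NULL, paste0(f, "=", lev)))
      cols[[f]] <- M
    } else {
      if (!is.null(scaling) && f %in% scaling$column) {
        i <- match(f, scaling$column)
        ctr <- scaling$center[i]
        scl <- scaling$scale[i]
      } else if (scale_continuous) {
        ctr <- mean(x)
        scl <- sd(x)
        if (scl == 0) scl <- 1
      } else {
        ctr <- 0
        scl <- 1
      }
      sc_col <- c(sc_col, f)
      sc_center <- c(sc_center, ctr)
      sc_scale <- c(sc_scale, scl)
      cols[[f]] <- matrix((as.double(x) - ctr) / scl, ncol = 1,
                          dimnames = list(NULL, f))
    }
  }

  M <- do.call(cbind, cols)
  at <- 0L
  for (f in schema_names(schema)) {
    w <- ncol(cols[[f]])
    block_map[[f]] <- seq.int(at + 1L, at + w)
    at <- at + w
  }
  structure(list(M = M, block_map = block_map,
                 scaling = data.frame(column = sc_col, center = sc_center,
                                      scale = sc_scale,
                                      stringsAsFactors = FALSE),
                 scale_continuous = scale_continuous,
                 drop_reference = drop_reference),
            class = "encoded_matrix")
}

#' @export
print.encoded_matrix <- function(x, ...) {
  cat(sprintf("encoded_matrix: %d x %d (%d feature blocks)\n",
              nrow(x$M), ncol(x$M), length(x$block_map)))
  invisible(x)
}

# Replace the row set of an encoded matrix (e.g. held-out rows encoded with
# training constants) while keeping block structure.
encoded_like <- function(template, M) {
  out <- template
  out$M <- M
  out
}
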