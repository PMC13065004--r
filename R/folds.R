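#' Build a (stratified) k-fold partition
#'
#' Records are assigned to k folds whose sizes differ by at most one. With
#' stratification (the default) each outcome class is dealt to folds in
#' near-equal counts, keeping every fold's prevalence close to the overall
#' prevalence — important at 25% prevalence with k = 10. Deterministic under
#' the seed.
#'
#' @param cohort A `permfit_cohort` (only `Z` and `n` are used).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @param stratified Stratify fold assignment by outcome.
#' @return An object of class `fold_plan`: list with `k`, `assignments`
#'   (integer fold id per record), `seed`, `stratified`.
#' @export
make_folds <- function(cohort, k = 10, seed = 1, stratified = TRUE) {
  n <- cohort$n
  if (k > n) stop_("k = %d exceeds the number of records (%d)", k, n)
  if (k < 2) stop_("k must be at least 2")
  assignments <- integer(n)
  with_seed(seed, {
    if (stratified) {
      # deal each class to folds in a shared random fold order; extras from
      # the two classes continue along the same sequence so total fold sizes
      # differ by at most one
      fold_order <- sample.int(k)
      slot <- 0L
      for (cls in c(1L, 0L)) {
        idx <- sample(which(cohort$Z == cls))
        base <- length(idx) %/% k
        extra <- length(idx) %% k
        counts <- rep(base, k)
        if (extra > 0) {
          take <- ((slot + seq_len(extra) - 1L) %% k) + 1L
          counts[take] <- counts[take] + 1L
          slot <- (slot + extra) %% k
        }
        at <- 1L
        for (f in seq_len(k)) {
          cnt <- counts[f]
          if (cnt > 0) {
            assignments[idx[at:(at + cnt - 1L)]] <- fold_order[f]
            at <- at + cnt
          }
        }
      }
    } else {
      assignments <- sample(rep_len(seq_len(k), n))
    }
  })
  structure(list(k = k, assignments = assignments, seed = seed,
                 stratified = stratified),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: k = %d, %s, seed = %d; fold sizes %s\n",
              x$k, if (x$stratified) "stratified" else "unstratified",
              x$seed, paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}
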