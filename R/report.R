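#' Export pipeline results as report files
#'
#' Writes `metrics.csv` (rows = metrics, columns = learners, cells formatted
#' `mean (low, high)` at three decimals), `metrics.json` (full precision),
#' `frequency.csv` (feature x learner significance counts) and, when
#' `plots = TRUE` and the pheatmap package is available, `heatmap.png`. The
#' inputs are validated before any file is created, so a failure leaves no
#' partial output.
#'
#' @param aggregated Named list (per learner) of [aggregate_with_ci()]
#'   tables, e.g. `pipeline_result$aggregated`.
#' @param frequency Feature x learner matrix from [feature_frequency()].
#' @param out_dir Output directory (created if needed).
#' @param plots Also render the frequency heatmap.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(aggregated, frequency, out_dir, plots = FALSE) {
  if (!length(aggregated)) stop_("empty learner set; nothing to export")
  if (is.null(names(aggregated)) || any(!nzchar(names(aggregated)))) {
    stop_("aggregated must be a named list keyed by learner")
  }
  for (a in aggregated) {
    if (!inherits(a, "data.frame") ||
        !all(c("metric", "mean", "ci_low", "ci_high") %in% names(a))) {
      stop_("each aggregated element must be an aggregated_metrics table")
    }
  }
  if (!is.matrix(frequency)) stop_("frequency must be a matrix")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fmt <- function(a, mn) {
    i <- match(mn, a$metric)
    sprintf("%.3f (%.3f, %.3f)", a$mean[i], a$ci_low[i], a$ci_high[i])
  }
  tab <- data.frame(metric = METRIC_NAMES, stringsAsFactors = FALSE)
  for (kind in names(aggregated)) {
    tab[[kind]] <- vapply(METRIC_NAMES, fmt, "", a = aggregated[[kind]])
  }
  paths <- file.path(out_dir, c("metrics.csv", "metrics.json", "frequency.csv"))
  write.csv(tab, paths[1], row.names = FALSE)
  jsonlite::write_json(
    lapply(aggregated, function(a) as.data.frame(a)),
    paths[2], auto_unbox = TRUE, digits = NA)
  freq_df <- data.frame(feature = rownames(frequency), frequency,
                        check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(freq_df, paths[3], row.names = FALSE)

  if (plots && requireNamespace("pheatmap", quietly = TRUE)) {
    png_path <- file.path(out_dir, "heatmap.png")
    grDevices::png(png_path, width = 900, height = 1200, res = 150)
    pheatmap::pheatmap(frequency, cluster_rows = FALSE, cluster_cols = FALSE,
                       display_numbers = TRUE, number_format = "%d",
                       main = "Folds with significant importance (0-10)")
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}
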