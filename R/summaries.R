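RUN_METRIC_COLS <- c("sample_id", "raw_reads", "raw_bases_mb", "raw_mean_len",
                     "filt_reads", "filt_bases_mb", "filt_mean_len",
                     "pct_passed", "pct_on_target")

#' Read a per-sample sequencing run-metrics table
#'
#' TSV with columns sample_id, raw_reads, raw_bases_mb, raw_mean_len,
#' filt_reads, filt_bases_mb, filt_mean_len, pct_passed, pct_on_target —
#' the usual raw-vs-filtered read accounting of a targeted sequencing run.
#' A 12-sample example ships with the package:
#' `system.file("extdata", "table2_run_metrics.tsv", package = "multicom")`.
#'
#' @param path TSV file path.
#' @return data.table of per-sample metrics.
#' @export
read_run_metrics <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  names(dt) <- tolower(names(dt))
  miss <- setdiff(RUN_METRIC_COLS, names(dt))
  if (length(miss)) stopf("run-metrics table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  validate_run_metrics(dt)
  dt[, RUN_METRIC_COLS, with = FALSE]
}

validate_run_metrics <- function(dt) {
  if (nrow(dt) == 0L) stopf("run metrics: need at least one sample row")
  if (any(dt$filt_reads > dt$raw_reads))
    stopf("run metrics: filtered reads exceed raw reads")
  for (col in c("pct_passed", "pct_on_target")) {
    if (any(dt[[col]] < 0 | dt[[col]] > 100))
      stopf("run metrics: %s outside [0, 100]", col)
  }
  invisible(dt)
}

#' Summarize per-sample run metrics
#'
#' Totals (sums) for read and base counts; unweighted arithmetic means across
#' samples for mean read lengths and percentages. Mean lengths are rounded
#' half-up to whole bases, percentages to one decimal.
#'
#' @param rows data.table/data.frame of per-sample metrics (columns as in
#'   [read_run_metrics()]).
#' @return one-row data.table with `n_samples`, totals `raw_reads`,
#'   `raw_bases_mb`, `filt_reads`, `filt_bases_mb`, and averages
#'   `raw_mean_len`, `filt_mean_len`, `pct_passed`, `pct_on_target`.
#' @export
summarize_runs <- function(rows) {
  rows <- data.table::as.data.table(rows)
  miss <- setdiff(RUN_METRIC_COLS, names(rows))
  if (length(miss)) stopf("run metrics lack column(s): %s", paste(miss, collapse = ", "))
  validate_run_metrics(rows)
  data.table::data.table(
    n_samples = nrow(rows),
    raw_reads = sum(rows$raw_reads),
    raw_bases_mb = sum(rows$raw_bases_mb),
    raw_mean_len = round_half_up(mean(rows$raw_mean_len), 0L),
    filt_reads = sum(rows$filt_reads),
    filt_bases_mb = sum(rows$filt_bases_mb),
    filt_mean_len = round_half_up(mean(rows$filt_mean_len), 0L),
    pct_passed = round_half_up(mean(rows$pct_passed), 1L),
    pct_on_target = round_half_up(mean(rows$pct_on_target), 1L)
  )
}
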