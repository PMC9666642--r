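#' Per-sample call rate
#'
#' Fraction of targeted markers called in each sample, a marker counting
#' as called when its total depth reaches `min_dp` (default: covered by
#' at least one read).
#'
#' @param counts A `count_matrix` whose columns span the full panel.
#' @param min_dp Minimum depth for a call.
#' @return Named numeric vector in [0, 1], one value per sample.
#' @export
sample_call_rate <- function(counts, min_dp = 1L) {
  stopifnot(inherits(counts, "count_matrix"), min_dp >= 1L)
  dp <- total_depth(counts)
  rowMeans(!is.na(dp) & dp >= min_dp)
}

#' Per-marker (SNP) call rate
#'
#' Fraction of samples in which each marker was called; the column-wise
#' dual of [sample_call_rate()].
#'
#' @inheritParams sample_call_rate
#' @return Named numeric vector in [0, 1], one value per marker.
#' @export
snp_call_rate <- function(counts, min_dp = 1L) {
  stopifnot(inherits(counts, "count_matrix"), min_dp >= 1L)
  dp <- total_depth(counts)
  colMeans(!is.na(dp) & dp >= min_dp)
}

#' Markers covered by at least one read in every sample
#'
#' @param counts A `count_matrix`.
#' @return Integer count of markers with DP >= 1 in all samples.
#' @export
markers_covered_in_all <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"), nrow(counts$ref) > 0L)
  dp <- total_depth(counts)
  sum(colSums(!is.na(dp) & dp >= 1L) == nrow(dp))
}

#' Flag markers with a low call rate
#'
#' Markers strictly below the call-rate threshold are flagged, optionally
#' within a stratum of samples (e.g. only the honey-derived matrices,
#' where degraded template makes specific amplicons underperform).
#'
#' @param counts A `count_matrix`.
#' @param sheet Optional `sample_sheet`, required when stratifying.
#' @param threshold Call-rate threshold in (0, 1]; default 0.90.
#' @param stratify_by Optional character vector of `matrix_type` values;
#'   call rates are then computed over samples of those types only.
#' @param min_dp Minimum depth for a call.
#' @return Character vector of flagged marker ids (panel order).
#' @export
flag_low_call_markers <- function(counts, sheet = NULL, threshold = 0.90,
                                  stratify_by = NULL, min_dp = 1L) {
  stopifnot(threshold > 0, threshold <= 1)
  if (!is.null(stratify_by)) {
    if (is.null(sheet)) stop("stratified flagging requires a sample sheet")
    ids <- rownames(counts$ref)
    types <- sheet$matrix_type[match(ids, sheet$sample_id)]
    keep <- ids[types %in% stratify_by]
    if (length(keep) == 0L) stop("no samples in stratum: ",
                                 paste(stratify_by, collapse = ", "))
    counts <- subset_counts(counts, samples = keep)
  }
  rates <- snp_call_rate(counts, min_dp = min_dp)
  names(rates)[rates < threshold]
}

#' Full call-rate QC summary
#'
#' @param counts A `count_matrix`.
#' @param sheet Optional `sample_sheet` for stratified marker flagging.
#' @param threshold Marker call-rate threshold (default 0.90).
#' @param min_dp Minimum depth for a call.
#' @return A `qc_summary` list: `sample_call_rate`, `snp_call_rate`,
#'   `low_call_markers`, `n_markers_covered_in_all`, `min_dp`,
#'   `threshold`.
#' @export
qc_summary <- function(counts, sheet = NULL, threshold = 0.90, min_dp = 1L) {
  structure(list(
    sample_call_rate = sample_call_rate(counts, min_dp),
    snp_call_rate = snp_call_rate(counts, min_dp),
    low_call_markers = flag_low_call_markers(counts, sheet,
                                             threshold = threshold,
                                             min_dp = min_dp),
    n_markers_covered_in_all = markers_covered_in_all(counts),
    min_dp = min_dp, threshold = threshold
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("QC summary (min_dp = %d)\n", x$min_dp))
  cat(sprintf("  sample call rate: mean %.1f%%, median %.1f%%, min %.1f%%\n",
              100 * mean(x$sample_call_rate),
              100 * stats::median(x$sample_call_rate),
              100 * min(x$sample_call_rate)))
  cat(sprintf("  SNP call rate:    mean %.1f%%, median %.1f%%\n",
              100 * mean(x$snp_call_rate),
              100 * stats::median(x$snp_call_rate)))
  cat(sprintf("  markers covered by >=1 read in all samples: %d / %d\n",
              x$n_markers_covered_in_all, length(x$snp_call_rate)))
  cat(sprintf("  markers below %.0f%% call rate: %s\n", 100 * x$threshold,
              if (length(x$low_call_markers) == 0L) "none"
              else paste(x$low_call_markers, collapse = ", ")))
  invisible(x)
}
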