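#' Estimate the alternative-allele frequency of one or more cells
#'
#' The raw-ratio estimator: `100 * alt / (ref + alt)` percent, reported
#' only where total depth reaches `min_dp`. Vectorised over cells.
#'
#' @param ref,alt Non-negative integer vectors of REF/ALT supporting reads
#'   (`NA` = missing cell).
#' @param min_dp Minimum total depth for a call (default 1: a marker
#'   covered by at least one read is considered genotyped).
#' @return Numeric vector of percent frequencies, `NA` below `min_dp` or
#'   for missing cells.
#' @examples
#' estimate_af(13, 7)      # 35
#' estimate_af(3, 1, min_dp = 6)  # NA
#' @export
estimate_af <- function(ref, alt, min_dp = 1L) {
  stopifnot(min_dp >= 1L)
  dp <- ref + alt
  ifelse(!is.na(dp) & dp >= min_dp, 100 * alt / dp, NA_real_)
}

#' Element-wise allele-frequency matrix from a count matrix
#'
#' @param counts A `count_matrix`.
#' @param min_dp Minimum depth per cell (see [estimate_af()]).
#' @return Numeric samples x markers matrix of percent frequencies with
#'   provenance flag `read_count_derived`.
#' @export
af_matrix <- function(counts, min_dp = 1L) {
  stopifnot(inherits(counts, "count_matrix"))
  af <- estimate_af(counts$ref, counts$alt, min_dp = min_dp)
  dimnames(af) <- dimnames(counts$ref)
  af_matrix_checked(af, provenance = "read_count_derived")
}

#' Allele copies contributed by a sample set
#'
#' The number of chromosomal allele observations backing an allele
#' frequency estimate: `sum(ploidy * n_individuals)`. Four diploid larvae
#' contribute 8 copies, one pool of 35 diploid workers 70, ten WGS
#' reference bees 20. Honey matrices, whose number of contributing bees
#' is unknown (likely thousands), refuse this accounting rather than
#' guessing.
#'
#' @param sheet A `sample_sheet` (or subset of rows).
#' @return Integer total allele copies.
#' @export
allele_copies <- function(sheet) {
  stopifnot(is.data.frame(sheet), nrow(sheet) > 0L)
  if (anyNA(sheet$n_individuals) || anyNA(sheet$ploidy)) {
    stop("undefined copy number: sample(s) without n_individuals (honey matrices): ",
         paste(sheet$sample_id[is.na(sheet$n_individuals) | is.na(sheet$ploidy)],
               collapse = ", "))
  }
  sum(as.integer(sheet$ploidy) * as.integer(sheet$n_individuals))
}

#' Per-group sequencing depth summary
#'
#' Summarises per-sample total depth (the sum of DP over all markers,
#' missing cells contributing 0) within groups of samples, by default the
#' biological matrix type. The standard deviation is the sample s.d.
#' (denominator n-1), reported as `NA` for single-sample groups.
#'
#' @param counts A `count_matrix`.
#' @param sheet A `sample_sheet` covering the count matrix rows.
#' @param group_by Sheet column to group on (default `"matrix_type"`).
#' @return Data frame: group, n, mean, sd, median, min, max of per-sample
#'   total depth.
#' @export
depth_summary <- function(counts, sheet, group_by = "matrix_type") {
  stopifnot(inherits(counts, "count_matrix"), group_by %in% names(sheet))
  ids <- rownames(counts$ref)
  stopifnot(all(ids %in% sheet$sample_id))
  dp <- total_depth(counts)
  per_sample <- rowSums(dp, na.rm = TRUE)
  grp <- sheet[[group_by]][match(ids, sheet$sample_id)]
  groups <- unique(grp)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- per_sample[grp == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               median = stats::median(v), min = min(v), max = max(v),
               stringsAsFactors = FALSE)
  }))
  names(out)[1L] <- group_by
  rownames(out) <- NULL
  out
}

# internal: pick the retained aliquot of each duplicate group.
# Rule: highest call rate; tie -> most total reads; tie -> lexicographically
# smallest sample_id. Returns sample ids to keep (all rows of `af`, minus
# the dropped aliquots).
retained_samples <- function(af, sheet, counts = NULL) {
  ids <- rownames(af)
  sub <- sheet[match(ids, sheet$sample_id), ]
  keep <- rep(TRUE, length(ids))
  call_rate <- rowMeans(!is.na(af))
  reads <- if (!is.null(counts)) {
    rowSums(total_depth(counts), na.rm = TRUE)[ids]
  } else stats::setNames(rep(0, length(ids)), ids)
  for (g in unique(stats::na.omit(sub$duplicate_group))) {
    members <- which(sub$duplicate_group %in% g)
    ord <- order(-call_rate[members], -reads[members], ids[members])
    keep[members[-ord[1L]]] <- FALSE
  }
  ids[keep]
}

#' Per-marker mean allele frequency by sample group
#'
#' Means are taken over non-missing cells. When duplicates are excluded,
#' each duplicate group is represented by the aliquot with the highest
#' call rate (ties broken by total read count, then by sample id).
#'
#' @param af An AF matrix (percent).
#' @param sheet A `sample_sheet` covering its rows.
#' @param group_by Sheet column defining the groups (e.g. `"subspecies"`,
#'   `"matrix_type"`).
#' @param include_duplicates Keep both aliquots of each duplicate group?
#' @param counts Optional `count_matrix` backing the read-count tie-break.
#' @return Numeric markers x groups matrix of mean percent frequencies
#'   (`NA` where a group has no data at a marker).
#' @export
group_mean_af <- function(af, sheet, group_by = "subspecies",
                          include_duplicates = TRUE, counts = NULL) {
  stopifnot(is.matrix(af), group_by %in% names(sheet))
  if (!include_duplicates) {
    af <- af[retained_samples(af, sheet, counts), , drop = FALSE]
  }
  ids <- rownames(af)
  grp <- sheet[[group_by]][match(ids, sheet$sample_id)]
  groups <- unique(grp[!is.na(grp)])
  if (length(groups) == 0L) stop("no non-missing groups in column ", group_by)
  out <- vapply(groups, function(g) {
    rows <- af[which(grp %in% g), , drop = FALSE]
    if (nrow(rows) == 0L) stop("group with zero samples: ", g)
    v <- colMeans(rows, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(ncol(af)))
  dimnames(out) <- list(colnames(af), groups)
  out
}
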