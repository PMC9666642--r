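#' Intraclass correlation coefficient, two-way absolute agreement, single
#' measurement
#'
#' Agreement between two allele-frequency vectors measured on the same
#' markers (e.g. two aliquots of one DNA extraction). Unlike Pearson
#' correlation, the ICC penalises systematic shifts between the two
#' measurement sets: two perfectly correlated vectors that differ by a
#' constant offset agree imperfectly. The variant computed is McGraw &
#' Wong's ICC(A,1) with k = 2 raters (aliquots) and the n shared markers
#' as targets:
#' \deqn{\frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with mean squares from the standard two-way ANOVA decomposition
#' (rows = markers, columns = aliquots).
#'
#' @param x,y Numeric vectors of equal length; markers missing in either
#'   vector are dropped pairwise before computation.
#' @return The ICC, a real number no greater than 1.
#' @examples
#' icc_agreement(c(0, 50, 100), c(10, 60, 110))  # < 1 despite Pearson r = 1
#' @export
icc_agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairwise-complete markers, got ", n)
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  if (all(dat == grand)) {
    message("both vectors constant and equal; ICC = 1 by convention")
    return(1)
  }
  ms_r <- k * sum((row_means - grand)^2) / (n - 1)
  ms_c <- n * sum((col_means - grand)^2) / (k - 1)
  resid <- dat - outer(row_means, rep(1, k)) -
    outer(rep(1, n), col_means) + grand
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

#' Concordance of duplicate-aliquot pairs
#'
#' For every duplicate group in the sample sheet (DNA extracted twice from
#' the same source and sequenced independently), computes the ICC,
#' Pearson's r and Spearman's rho of the two allele-frequency vectors on
#' pairwise-complete markers, and lists outlier markers whose frequency
#' differs by more than `outlier_delta` percentage points between the two
#' aliquots.
#'
#' @param af An AF matrix (percent) covering the duplicate samples.
#' @param sheet A `sample_sheet`; every duplicate group must have exactly
#'   two members present in `af`.
#' @param outlier_delta Outlier threshold on |AF difference| in
#'   percentage points (default 20).
#' @return Data frame with one row per pair: `pair_id`, `sample_a`,
#'   `sample_b`, `icc`, `pearson_r`, `spearman_rho`, `n_markers_used`,
#'   `n_outliers`, `outlier_markers` (comma-joined ids).
#' @export
duplicate_concordance <- function(af, sheet, outlier_delta = 20) {
  stopifnot(is.matrix(af))
  groups <- unique(stats::na.omit(sheet$duplicate_group))
  if (length(groups) == 0L) stop("sample sheet contains no duplicate groups")
  out <- lapply(groups, function(g) {
    members <- sheet$sample_id[sheet$duplicate_group %in% g]
    members <- members[members %in% rownames(af)]
    if (length(members) != 2L) {
      stop("duplicate group '", g, "' must have exactly 2 members in the ",
           "AF matrix, found ", length(members))
    }
    x <- af[members[1L], ]; y <- af[members[2L], ]
    ok <- !is.na(x) & !is.na(y)
    outliers <- colnames(af)[ok & abs(x - y) > outlier_delta]
    data.frame(
      pair_id = g, sample_a = members[1L], sample_b = members[2L],
      icc = icc_agreement(x, y),
      pearson_r = stats::cor(x[ok], y[ok]),
      spearman_rho = stats::cor(x[ok], y[ok], method = "spearman"),
      n_markers_used = sum(ok),
      n_outliers = length(outliers),
      outlier_markers = paste(outliers, collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Correlation between two allele-frequency datasets
#'
#' Pearson's product-moment and Spearman's rank correlation (average
#' ranks for ties) between two group-level mean AF vectors on their
#' shared non-missing markers, e.g. larvae-derived versus honey-derived
#' frequencies for the same subspecies.
#'
#' @param x,y Numeric AF vectors aligned on the same markers.
#' @return List: `pearson_r`, `spearman_rho`, `n` (markers used). A
#'   constant vector makes the correlations undefined; they are returned
#'   as `NA` with a warning.
#' @export
dataset_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 shared non-missing markers, got ", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(pearson_r = NA_real_, spearman_rho = NA_real_, n = n))
  }
  list(pearson_r = stats::cor(x, y),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       n = n)
}
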