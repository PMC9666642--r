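#' Construct a samples x markers allele-depth matrix
#'
#' Holds the per-cell REF and ALT supporting read counts. A missing cell
#' (marker not covered / not reported for a sample) is `NA` in both layers;
#' a cell reported with zero coverage is a genuine `(0, 0)`.
#'
#' @param ref,alt Integer matrices of identical dimension and dimnames
#'   (rows = sample ids, cols = marker ids in panel order). `NA` patterns
#'   must agree between the two layers.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(ref, alt) {
  stopifnot(is.matrix(ref), is.matrix(alt),
            identical(dim(ref), dim(alt)),
            identical(dimnames(ref), dimnames(alt)))
  if (is.null(rownames(ref)) || is.null(colnames(ref))) {
    stop("count matrix requires sample rownames and marker colnames")
  }
  if (anyDuplicated(rownames(ref))) stop("duplicate sample ids in count matrix")
  mode(ref) <- "integer"
  mode(alt) <- "integer"
  if (!identical(is.na(ref), is.na(alt))) {
    stop("ref and alt missingness patterns disagree")
  }
  if (any(ref < 0L, na.rm = TRUE) || any(alt < 0L, na.rm = TRUE)) {
    stop("read counts must be non-negative")
  }
  structure(list(ref = ref, alt = alt), class = "count_matrix")
}

#' Assemble a count matrix from per-sample depth rows
#'
#' @param rows Named list of per-sample rows as returned by
#'   [read_allele_depths()] or [simulate_counts()]: each element a list with
#'   `ref` and `alt` named integer vectors over the panel's markers.
#' @param panel A `bee_panel` fixing the column order.
#' @return A `count_matrix` with one row per input sample, in list order.
#' @export
bind_count_rows <- function(rows, panel) {
  stopifnot(length(rows) > 0L, !is.null(names(rows)))
  ids <- panel$marker_id
  ref <- t(vapply(rows, function(r) as.integer(r$ref[ids]), integer(length(ids))))
  alt <- t(vapply(rows, function(r) as.integer(r$alt[ids]), integer(length(ids))))
  dimnames(ref) <- dimnames(alt) <- list(names(rows), ids)
  count_matrix(ref, alt)
}

#' Per-cell total sequencing depth (DP = REF + ALT reads)
#'
#' @param counts A `count_matrix`.
#' @return Integer matrix of the same shape; `NA` where the cell is missing.
#' @export
total_depth <- function(counts) {
  stopifnot(inherits(counts, "count_matrix"))
  counts$ref + counts$alt
}

#' @export
dim.count_matrix <- function(x) dim(x$ref)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$ref)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d markers (%.1f%% cells populated)\n",
              nrow(x$ref), ncol(x$ref), 100 * mean(!is.na(x$ref))))
  invisible(x)
}

#' Subset a count matrix by sample and/or marker
#'
#' @param counts A `count_matrix`.
#' @param samples,markers Character or index vectors; `NULL` keeps all.
#' @return A `count_matrix`.
#' @export
subset_counts <- function(counts, samples = NULL, markers = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (is.null(samples)) samples <- rownames(counts$ref)
  if (is.null(markers)) markers <- colnames(counts$ref)
  count_matrix(counts$ref[samples, markers, drop = FALSE],
               counts$alt[samples, markers, drop = FALSE])
}
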