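#' Assemble the combined allele-frequency matrix for ancestry analysis
#'
#' Concatenates allele-frequency matrices from multiple sources (GBS
#' samples, reference genotype sets, WGS-derived genotypes), restricts
#' columns to the panel's ancestry-informative markers, and imputes
#' missing cells with the column (marker) mean computed over all rows so
#' the downstream distance computation sees a complete matrix. A column
#' missing in every row carries no information and is dropped with a
#' warning.
#'
#' @param sources List of AF matrices (percent) sharing the panel's
#'   marker universe; each must contain every ancestry marker column.
#' @param panel A `bee_panel`.
#' @param category Marker subset to keep (default `"ancestry"`).
#' @return Numeric matrix (all source rows x ancestry markers), complete
#'   after imputation; attribute `n_imputed` records how many cells were
#'   filled.
#' @export
assemble_matrix <- function(sources, panel, category = "ancestry") {
  stopifnot(is.list(sources), length(sources) > 0L,
            inherits(panel, "bee_panel"))
  cols <- panel$marker_id[panel$category == category]
  if (length(cols) == 0L) stop("panel has no markers of category ", category)
  mats <- lapply(seq_along(sources), function(i) {
    m <- sources[[i]]
    missing_cols <- setdiff(cols, colnames(m))
    if (length(missing_cols) > 0L) {
      stop("source ", i, " lacks ", length(missing_cols),
           " ancestry marker column(s), e.g. ", missing_cols[1L])
    }
    m[, cols, drop = FALSE]
  })
  combined <- do.call(rbind, mats)
  dup <- duplicated(rownames(combined))
  if (any(dup)) {
    stop("duplicate sample_id across sources: ",
         paste(unique(rownames(combined)[dup]), collapse = ", "))
  }
  all_missing <- colSums(!is.na(combined)) == 0L
  if (any(all_missing)) {
    warning("dropping ", sum(all_missing),
            " marker(s) missing in every sample: ",
            paste(colnames(combined)[all_missing], collapse = ", "))
    combined <- combined[, !all_missing, drop = FALSE]
  }
  n_imputed <- sum(is.na(combined))
  if (n_imputed > 0L) {
    col_means <- colMeans(combined, na.rm = TRUE)
    idx <- which(is.na(combined), arr.ind = TRUE)
    combined[idx] <- col_means[idx[, 2L]]
  }
  attr(combined, "n_imputed") <- n_imputed
  combined
}

# internal: fix the reflection indeterminacy of an eigenvector axis so
# outputs are bit-reproducible: the largest-magnitude coordinate is made
# positive; among magnitude ties the entry with the largest row index wins.
fix_axis_sign <- function(v, tol = 1e-12) {
  a <- abs(v)
  i <- max(which(a >= max(a) - tol))
  if (v[i] < 0) -v else v
}

#' Classical (Torgerson) multidimensional scaling of an AF matrix
#'
#' Computes Euclidean distances between sample rows on the percent scale,
#' double-centres the squared-distance matrix and eigendecomposes it (the
#' classical MDS of R's `cmdscale`), returning coordinates scaled by the
#' square roots of the leading eigenvalues. Negative eigenvalues are
#' truncated at zero for the variance-explained shares. Each axis's
#' reflection is fixed deterministically (largest-magnitude coordinate
#' positive) so repeated runs agree bit-for-bit.
#'
#' @param af Complete numeric matrix (samples x markers), typically from
#'   [assemble_matrix()].
#' @param k Number of dimensions (default 2).
#' @return An `mds_result` list: `coordinates` (samples x k, centred),
#'   `eigenvalues` (all n - 1, non-increasing), `variance_explained`
#'   (per retained dimension, over the positive spectrum).
#' @export
classical_mds <- function(af, k = 2L) {
  stopifnot(is.matrix(af), k >= 1L)
  if (anyNA(af)) stop("MDS input must be complete; impute first")
  n <- nrow(af)
  if (n < k + 1L) stop("need at least k + 1 samples")
  d <- stats::dist(af)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  eig <- fit$eig
  if (sum(eig > 1e-8 * max(abs(eig))) < k) {
    stop("k = ", k, " exceeds the number of positive eigenvalues")
  }
  coords <- fit$points
  for (j in seq_len(ncol(coords))) coords[, j] <- fix_axis_sign(coords[, j])
  colnames(coords) <- paste0("dim", seq_len(k))
  pos <- pmax(eig, 0)
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 variance_explained = pos[seq_len(k)] / sum(pos)),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("classical MDS: %d samples, %d dimensions\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign query samples to evolutionary lineages by nearest centroid
#'
#' Reference samples (rows whose `matrix_type` is a reference type and
#' whose lineage label is set) define one centroid per lineage in MDS
#' space; every other sample is assigned to the nearest centroid by
#' Euclidean distance. The ratio of nearest to second-nearest centroid
#' distance measures how decisively a sample sits in one cluster: ratios
#' above `tau` flag a sample as potentially admixed (intermediate
#' position between clusters).
#'
#' @param mds An `mds_result` whose coordinate rows carry sample ids.
#' @param sheet A `sample_sheet` covering those ids.
#' @param tau Admixture flag threshold on the distance ratio (default
#'   0.8).
#' @return Data frame, one row per query sample: `sample_id`,
#'   `assigned_lineage`, `distance_to_assigned`, `distance_ratio`,
#'   `admixture_flag`.
#' @export
assign_lineage <- function(mds, sheet, tau = 0.8) {
  stopifnot(inherits(mds, "mds_result"), tau > 0, tau <= 1)
  coords <- mds$coordinates
  ids <- rownames(coords)
  info <- sheet[match(ids, sheet$sample_id), ]
  is_ref <- info$matrix_type %in% REFERENCE_MATRIX_TYPES & !is.na(info$lineage)
  if (!any(is_ref)) stop("no reference samples with lineage labels")
  ref_lineages <- sort(unique(info$lineage[is_ref]))
  empty <- setdiff(unique(stats::na.omit(info$lineage)), ref_lineages)
  if (length(empty) > 0L) {
    warning("lineage(s) without reference samples excluded from assignment: ",
            paste(empty, collapse = ", "))
  }
  if (length(ref_lineages) < 2L) {
    stop("need reference samples for at least 2 lineages")
  }
  centroids <- t(vapply(ref_lineages, function(lin) {
    colMeans(coords[which(is_ref & info$lineage == lin), , drop = FALSE])
  }, numeric(ncol(coords))))
  queries <- which(!is_ref)
  out <- do.call(rbind, lapply(queries, function(i) {
    d <- sqrt(colSums((t(centroids) - coords[i, ])^2))
    ord <- order(d, names(d))   # ties broken by lexicographic lineage label
    if (length(d) > 1L && d[ord[1L]] == d[ord[2L]]) {
      warning("sample ", ids[i], " equidistant from lineages ",
              names(d)[ord[1L]], " and ", names(d)[ord[2L]],
              "; assigned lexicographically")
    }
    ratio <- if (d[ord[2L]] == 0) 1 else d[ord[1L]] / d[ord[2L]]
    data.frame(sample_id = ids[i],
               assigned_lineage = names(d)[ord[1L]],
               distance_to_assigned = unname(d[ord[1L]]),
               distance_ratio = unname(ratio),
               admixture_flag = unname(ratio > tau),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Default mapping from mitotype labels to nuclear lineages
#' @export
DEFAULT_MITO_LINEAGE_MAP <- c(C1 = "C", A = "A", M = "M", O = "O")

#' Cross-check lineage assignments against recorded mitotypes
#'
#' The mitochondrial haplotype is maternally inherited and assayed
#' independently of the nuclear panel, so agreement between the two is a
#' powerful consistency check: a sample assigned to lineage M whose
#' mitotype maps to lineage C signals maternal introgression.
#'
#' @param assignment Data frame from [assign_lineage()].
#' @param sheet A `sample_sheet` carrying `mitotype` labels (comma-joined
#'   sets allowed for bulk honey from mixed apiaries).
#' @param mito_lineage_map Named map mitotype label -> lineage label;
#'   must cover every observed mitotype.
#' @return The assignment data frame with a `mito_status` column:
#'   `concordant` (every recorded mitotype maps to the assigned lineage),
#'   `discordant` (a single mismatching mitotype), `mixed` (multiple
#'   distinct mitotypes recorded), `unavailable` (no mitotype).
#' @export
mito_concordance <- function(assignment, sheet,
                             mito_lineage_map = DEFAULT_MITO_LINEAGE_MAP) {
  stopifnot(is.data.frame(assignment), "assigned_lineage" %in% names(assignment))
  mito <- sheet$mitotype[match(assignment$sample_id, sheet$sample_id)]
  status <- vapply(seq_along(mito), function(i) {
    if (is.na(mito[i])) return("unavailable")
    labels <- unique(trimws(strsplit(mito[i], ",", fixed = TRUE)[[1L]]))
    unmapped <- setdiff(labels, names(mito_lineage_map))
    if (length(unmapped) > 0L) {
      stop("unmapped mitotype label: ", paste(unmapped, collapse = ", "))
    }
    if (length(labels) > 1L) return("mixed")
    if (identical(unname(mito_lineage_map[[labels]]),
                  assignment$assigned_lineage[i])) "concordant" else "discordant"
  }, character(1))
  assignment$mito_status <- status
  assignment
}
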