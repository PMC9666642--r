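#' Biological matrix types handled by the pipeline
#'
#' `larva` and `worker_pool` are DNA extracted directly from bees (single
#' diploid larvae, pools of 35 workers); `honeycomb_honey` and `bulk_honey`
#' are environmental DNA from honey (one honeycomb vs several colonies of
#' the same apiary); `wgs_reference` and `genotype_reference` are external
#' reference individuals entering only the ancestry analysis.
#'
#' @export
MATRIX_TYPES <- c("larva", "worker_pool", "honeycomb_honey", "bulk_honey",
                  "wgs_reference", "genotype_reference")

#' Matrix types for which the number of contributing individuals is undefined
#' @export
HONEY_MATRIX_TYPES <- c("honeycomb_honey", "bulk_honey")

#' Matrix types acting as ancestry references
#' @export
REFERENCE_MATRIX_TYPES <- c("wgs_reference", "genotype_reference")

SHEET_COLUMNS <- c("sample_id", "matrix_type", "subspecies", "lineage",
                   "duplicate_group", "n_individuals", "ploidy", "mitotype")

#' Construct and validate a sample sheet
#'
#' @param df Data frame with columns `sample_id`, `matrix_type`,
#'   `subspecies`, `lineage`, `duplicate_group`, `n_individuals`, `ploidy`,
#'   `mitotype`. Missing optional fields may be `NA` or empty strings.
#' @return A validated `sample_sheet` data frame (row order preserved; it is
#'   the canonical row order of count/AF matrices).
#' @export
sample_sheet <- function(df) {
  missing_cols <- setdiff(SHEET_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, SHEET_COLUMNS, drop = FALSE]
  for (col in c("sample_id", "matrix_type", "subspecies", "lineage",
                "duplicate_group", "mitotype")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[col]] <- v
  }
  df$n_individuals <- suppressWarnings(as.integer(df$n_individuals))
  df$ploidy <- suppressWarnings(as.integer(df$ploidy))

  if (anyNA(df$sample_id)) stop("sample_id must not be missing")
  dup <- duplicated(df$sample_id)
  if (any(dup)) {
    stop("duplicate sample_id: ", paste(unique(df$sample_id[dup]), collapse = ", "))
  }
  bad_type <- is.na(df$matrix_type) | !(df$matrix_type %in% MATRIX_TYPES)
  if (any(bad_type)) {
    stop("unknown matrix_type '", df$matrix_type[bad_type][1L],
         "'; expected one of: ", paste(MATRIX_TYPES, collapse = ", "))
  }
  bad_lin <- !is.na(df$lineage) & !(df$lineage %in% c("A", "C", "M", "O", "Y", "unknown"))
  if (any(bad_lin)) {
    stop("unknown lineage label: ", paste(unique(df$lineage[bad_lin]), collapse = ", "))
  }
  # n_individuals is undefined exactly for honey-derived matrices
  honey <- df$matrix_type %in% HONEY_MATRIX_TYPES
  if (any(honey & !is.na(df$n_individuals))) {
    stop("n_individuals must be absent for honey matrices: ",
         paste(df$sample_id[honey & !is.na(df$n_individuals)], collapse = ", "))
  }
  if (any(!honey & is.na(df$n_individuals))) {
    stop("n_individuals required for non-honey samples: ",
         paste(df$sample_id[!honey & is.na(df$n_individuals)], collapse = ", "))
  }
  if (any(!is.na(df$n_individuals) & df$n_individuals < 1L)) {
    stop("n_individuals must be positive")
  }
  grp <- df$duplicate_group[!is.na(df$duplicate_group)]
  singleton <- names(which(table(grp) < 2L))
  if (length(singleton) > 0L) {
    stop("duplicate_group with fewer than 2 members: ",
         paste(singleton, collapse = ", "))
  }
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Load a sample sheet from a TSV file
#'
#' Empty strings encode absent optional fields. See [sample_sheet()] for the
#' column contract and validation rules.
#'
#' @param path Path to a tab-separated sample sheet.
#' @return A `sample_sheet` data frame.
#' @export
load_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, na.strings = character(0))
  sample_sheet(df)
}

#' Write a sample sheet to TSV (absent fields as empty strings)
#'
#' @param sheet A `sample_sheet`.
#' @param path Output path.
#' @export
write_sample_sheet <- function(sheet, path) {
  out <- as.data.frame(sheet)
  for (col in names(out)) {
    v <- as.character(out[[col]])
    v[is.na(v)] <- ""
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an allele-frequency matrix to TSV
#'
#' Cells are alternative-allele frequencies in percent; missing cells are
#' written as `NA`. The first column is `sample_id`, remaining columns are
#' marker ids in panel order.
#'
#' @param af Numeric matrix (samples x markers) with `NA` for missing.
#' @param path Output path.
#' @export
write_af_table <- function(af, path) {
  stopifnot(is.matrix(af), !is.null(rownames(af)), !is.null(colnames(af)))
  out <- data.frame(sample_id = rownames(af), check.names = FALSE,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(af, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an allele-frequency matrix written by [write_af_table()]
#'
#' Round-trips exactly: `read_af_table(write_af_table(x))` reproduces `x`
#' including missing cells.
#'
#' @param path Path to the TSV.
#' @param provenance Row provenance flag recorded on the result:
#'   `"read_count_derived"` (frequencies estimated from read counts) or
#'   `"genotype_derived"` (individual genotypes encoded 0/50/100).
#' @return Numeric matrix with `sample_id` rownames and marker colnames.
#' @export
read_af_table <- function(path, provenance = c("read_count_derived",
                                               "genotype_derived")) {
  provenance <- match.arg(provenance)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, na.strings = "NA")
  if (names(df)[1L] != "sample_id") stop("AF table must start with sample_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df$sample_id)
  af_matrix_checked(m, provenance = provenance)
}

# internal: validate an AF matrix's value contract
af_matrix_checked <- function(m, provenance = "read_count_derived") {
  vals <- m[!is.na(m)]
  if (length(vals) > 0L && (any(vals < 0) || any(vals > 100))) {
    stop("allele frequencies must lie in [0, 100] percent")
  }
  if (identical(provenance, "genotype_derived") &&
      length(vals) > 0L && !all(vals %in% c(0, 50, 100))) {
    stop("genotype-derived rows must only contain 0, 50 or 100")
  }
  attr(m, "provenance") <- provenance
  m
}
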