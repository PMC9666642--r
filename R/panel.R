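#' Marker categories recognised in a genotyping panel
#'
#' The targeted SNP panel mixes ancestry-informative markers (used for
#' lineage assignment) with markers associated to colony traits: calmness,
#' gentleness, and resistance to \emph{Varroa destructor}.
#'
#' @export
PANEL_CATEGORIES <- c("ancestry", "calmness", "gentleness", "varroa_resistance")

#' Expected per-category marker counts of the default 121-SNP panel
#'
#' @export
DEFAULT_PANEL_COUNTS <- c(
  ancestry = 97L, calmness = 3L, gentleness = 3L, varroa_resistance = 18L
)

new_panel <- function(df, expected_counts = DEFAULT_PANEL_COUNTS) {
  required <- c("marker_id", "chrom", "pos", "ref", "alt", "category")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, required, drop = FALSE]
  if (nrow(df) == 0L) stop("empty panel")
  df$marker_id <- as.character(df$marker_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$category <- as.character(df$category)

  bad_nt <- !(df$ref %in% c("A", "C", "G", "T")) | !(df$alt %in% c("A", "C", "G", "T"))
  if (any(bad_nt)) {
    stop("non-ACGT allele for marker(s): ",
         paste(df$marker_id[bad_nt], collapse = ", "))
  }
  same <- df$ref == df$alt
  if (any(same)) {
    stop("identical ref and alt allele for marker(s): ",
         paste(df$marker_id[same], collapse = ", "))
  }
  dup_id <- duplicated(df$marker_id)
  if (any(dup_id)) {
    stop("duplicate marker_id: ", paste(unique(df$marker_id[dup_id]), collapse = ", "))
  }
  site <- paste(df$chrom, df$pos, sep = ":")
  dup_site <- duplicated(site)
  if (any(dup_site)) {
    stop("duplicate genomic position: ", paste(unique(site[dup_site]), collapse = ", "))
  }
  bad_cat <- !(df$category %in% PANEL_CATEGORIES)
  if (any(bad_cat)) {
    stop("unknown category '", df$category[bad_cat][1L], "'; expected one of: ",
         paste(PANEL_CATEGORIES, collapse = ", "))
  }
  rownames(df) <- NULL
  attr(df, "expected_counts") <- expected_counts
  class(df) <- c("bee_panel", "data.frame")
  df
}

#' Construct a panel from a data frame
#'
#' Programmatic counterpart of [load_panel()]: validates alleles,
#' uniqueness of marker ids and genomic positions, and category labels.
#'
#' @param df Data frame with columns `marker_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `category`.
#' @param expected_counts Named integer vector of expected markers per
#'   category.
#' @return A `bee_panel` data frame.
#' @export
bee_panel <- function(df, expected_counts = DEFAULT_PANEL_COUNTS) {
  new_panel(df, expected_counts = expected_counts)
}

#' Load a SNP panel definition from a TSV file
#'
#' The panel file defines the targeted biallelic SNPs, one per row, in the
#' order that fixes the canonical column order of all count and allele
#' frequency matrices downstream. Positions are 1-based (VCF convention).
#'
#' @param path Path to a tab-separated file with columns
#'   `marker_id`, `chrom`, `pos`, `ref`, `alt`, `category`.
#' @param expected_counts Named integer vector of expected markers per
#'   category, used by [validate_panel_composition()]. Defaults to the
#'   97/3/3/18 composition of the 121-SNP assay.
#' @return A `bee_panel` data frame preserving file row order.
#' @export
load_panel <- function(path, expected_counts = DEFAULT_PANEL_COUNTS) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          check.names = FALSE, na.strings = character(0))
  if (nrow(df) == 0L) stop("empty panel")
  new_panel(df, expected_counts = expected_counts)
}

#' Check a panel against its expected per-category composition
#'
#' @param panel A `bee_panel`.
#' @return A list with `observed` and `expected` per-category counts, the
#'   observed `total`, a logical `pass`, and `failures` naming categories
#'   whose counts differ from expectation.
#' @examples
#' panel <- synthetic_panel()
#' validate_panel_composition(panel)$pass
#' @export
validate_panel_composition <- function(panel) {
  stopifnot(inherits(panel, "bee_panel"))
  expected <- attr(panel, "expected_counts")
  observed <- vapply(names(expected),
                     function(cat) sum(panel$category == cat), integer(1))
  failures <- names(expected)[observed != expected]
  structure(
    list(observed = observed, expected = expected,
         total = sum(observed), pass = length(failures) == 0L,
         failures = failures),
    class = "panel_composition"
  )
}

#' @export
print.panel_composition <- function(x, ...) {
  cat("Panel composition check\n")
  for (cat_ in names(x$expected)) {
    cat(sprintf("  %-18s %3d (expected %3d)%s\n", cat_,
                x$observed[[cat_]], x$expected[[cat_]],
                if (cat_ %in% x$failures) "  <-- FAIL" else ""))
  }
  cat(sprintf("  total %d markers: %s\n", x$total, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Marker ids of a panel subset
#'
#' @param panel A `bee_panel`.
#' @param subset One of `"all"`, `"ancestry"` (the ancestry-informative
#'   markers) or `"trait"` (everything else: calmness, gentleness and
#'   varroa-resistance markers).
#' @return Character vector of marker ids in panel order.
#' @export
marker_subset <- function(panel, subset = c("all", "ancestry", "trait")) {
  subset <- match.arg(subset)
  switch(subset,
    all = panel$marker_id,
    ancestry = panel$marker_id[panel$category == "ancestry"],
    trait = panel$marker_id[panel$category != "ancestry"]
  )
}

#' Build the package's synthetic stand-in for the 121-SNP assay panel
#'
#' Generates a panel with the published category composition (97 ancestry,
#' 3 calmness, 3 gentleness, 18 varroa-resistance markers) on synthetic
#' coordinates: the real assay coordinates are not redistributed here, so
#' markers are placed deterministically along 16 chromosome-style contigs.
#' Marker naming follows the assay's scheme (`bee_snp_*`, `bee_calm_*`,
#' `bee_gent_*`, `Var_res_*`) so that the fragile-marker defaults of
#' [sim_config()] refer to real panel members.
#'
#' @param expected_counts Named integer vector, per-category marker counts.
#' @return A `bee_panel`.
#' @export
synthetic_panel <- function(expected_counts = DEFAULT_PANEL_COUNTS) {
  prefix <- c(ancestry = "bee_snp_", calmness = "bee_calm_",
              gentleness = "bee_gent_", varroa_resistance = "Var_res_")
  # varroa ids count from 4: the assay's varroa markers come from a longer
  # published candidate list, so their id space extends past the panel size
  # (and includes the fragile default Var_res_21 of sim_config())
  offset <- c(ancestry = 0L, calmness = 0L, gentleness = 0L,
              varroa_resistance = 3L)
  ids <- unlist(lapply(names(expected_counts), function(cat_) {
    paste0(prefix[[cat_]], seq_len(expected_counts[[cat_]]) + offset[[cat_]])
  }), use.names = FALSE)
  cats <- rep(names(expected_counts), times = expected_counts)
  n <- length(ids)
  # deterministic placement and alleles; 16 contigs mirror the bee karyotype
  chrom <- paste0("NC_", sprintf("%03d", (seq_len(n) - 1L) %% 16L + 1L))
  pos <- 10000L + ((seq_len(n) - 1L) %/% 16L) * 50000L + (seq_len(n) - 1L) %% 16L
  nts <- c("A", "C", "G", "T")
  ref <- nts[(seq_len(n) - 1L) %% 4L + 1L]
  alt <- nts[(seq_len(n)) %% 4L + 1L]
  new_panel(
    data.frame(marker_id = ids, chrom = chrom, pos = pos,
               ref = ref, alt = alt, category = cats,
               stringsAsFactors = FALSE),
    expected_counts = expected_counts
  )
}

#' Write a panel to its TSV form
#'
#' @param panel A `bee_panel`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
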