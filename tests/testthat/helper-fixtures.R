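# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately take a different computational route from the
# package implementation they check.

# small panel: n markers per category, deterministic coordinates
tiny_panel <- function(n_ancestry = 4, n_calm = 1, n_gent = 1, n_varroa = 2) {
  synthetic_panel(expected_counts = c(
    ancestry = n_ancestry, calmness = n_calm,
    gentleness = n_gent, varroa_resistance = n_varroa
  ))
}

# count matrix from plain integer matrices (adds dimnames if absent)
make_counts <- function(ref, alt, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(ref)))
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(ref)))
  dimnames(ref) <- dimnames(alt) <- list(samples, markers)
  count_matrix(ref, alt)
}

# minimal sample sheet for k non-honey samples
flat_sheet <- function(ids, matrix_type = "worker_pool", lineage = NA,
                       subspecies = NA, duplicate_group = NA,
                       n_individuals = 35L, mitotype = NA) {
  honey <- matrix_type %in% HONEY_MATRIX_TYPES
  sample_sheet(data.frame(
    sample_id = ids, matrix_type = matrix_type,
    subspecies = as.character(subspecies), lineage = as.character(lineage),
    duplicate_group = as.character(duplicate_group),
    n_individuals = ifelse(honey, NA_integer_, as.integer(n_individuals)),
    ploidy = 2L, mitotype = as.character(mitotype),
    stringsAsFactors = FALSE
  ))
}

# write a VCF from explicit record fields (for malformed/edge fixtures)
write_vcf_fixture <- function(path, sample_id, chrom, pos, id, ref, alt,
                              gt_field) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- paste(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT:AD:DP",
                gt_field, sep = "\t")
  writeLines(c(header, body), path)
  path
}

# independent ICC(A,1) oracle: mean squares extracted from a stats::aov
# two-way fit (markers and raters as factors), not from closed forms
oracle_icc_a1 <- function(x, y) {
  n <- length(x)
  k <- 2
  d <- data.frame(value = c(x, y),
                  target = factor(rep(seq_len(n), 2)),
                  rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ target + rater, data = d))[[1]][["Mean Sq"]]
  ms_r <- ms[1]; ms_c <- ms[2]; ms_e <- ms[3]
  (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + (k / n) * (ms_c - ms_e))
}

# independent Torgerson oracle: explicit double centering + eigen, no cmdscale
oracle_cmds <- function(X, k) {
  D2 <- as.matrix(stats::dist(X))^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen(B, symmetric = TRUE)
  e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(k)]), k)
}
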