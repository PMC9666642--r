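#' Read per-marker allele depths for one sample from a VCF
#'
#' Extracts REF/ALT supporting read counts (FORMAT `AD`) for every panel
#' marker from a single-sample VCF. Marker matching is exact on
#' (chrom, pos, ref, alt): a site whose alleles are swapped relative to the
#' panel is treated as missing with a warning, never auto-flipped, because a
#' silent allele flip corrupts the frequency estimate. In multi-allelic
#' records only the depth of the panel's alternative allele is used; depths
#' of other alternative alleles contribute to neither count.
#'
#' @param vcf_path Path to a VCF 4.x file with one genotyped sample and a
#'   per-allele depth (`AD`) FORMAT field.
#' @param panel A `bee_panel`.
#' @return A list with `ref` and `alt`: named integer vectors over
#'   `panel$marker_id`, `NA` where the marker is absent from the VCF or has
#'   no usable depth information.
#' @export
read_allele_depths <- function(vcf_path, panel) {
  stopifnot(inherits(panel, "bee_panel"))
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", vcf_path, "': ",
                             conditionMessage(e))
  )
  n <- nrow(panel)
  ref_out <- alt_out <- rep(NA_integer_, n)
  names(ref_out) <- names(alt_out) <- panel$marker_id

  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(list(ref = ref_out, alt = alt_out))
  }
  if (!any(fix[, "CHROM"] %in% panel$chrom)) {
    warning("no VCF chromosome matches any panel marker in '", vcf_path,
            "'; returning an all-missing row")
    return(list(ref = ref_out, alt = alt_out))
  }
  if (ncol(vcf@gt) < 2L) stop("VCF '", vcf_path, "' carries no sample column")
  ad <- vcfR::extract.gt(vcf, element = "AD")[, 1L]

  site_key <- paste(fix[, "CHROM"], fix[, "POS"], sep = ":")
  panel_key <- paste(panel$chrom, panel$pos, sep = ":")
  hit <- match(panel_key, site_key)
  for (i in which(!is.na(hit))) {
    j <- hit[i]
    vref <- unname(fix[j, "REF"])
    valts <- strsplit(unname(fix[j, "ALT"]), ",", fixed = TRUE)[[1L]]
    if (!identical(vref, panel$ref[i])) {
      if (identical(vref, panel$alt[i]) && panel$ref[i] %in% valts) {
        warning("ref/alt swapped at ", panel_key[i], " (marker ",
                panel$marker_id[i], ") in '", vcf_path,
                "'; treating as missing, not flipping")
      }
      next
    }
    k <- match(panel$alt[i], valts)
    if (is.na(k)) next
    depths <- suppressWarnings(
      as.integer(strsplit(ad[j], ",", fixed = TRUE)[[1L]])
    )
    if (length(depths) < k + 1L || is.na(depths[1L]) || is.na(depths[k + 1L])) next
    ref_out[i] <- depths[1L]
    alt_out[i] <- depths[k + 1L]
  }
  list(ref = ref_out, alt = alt_out)
}

#' Read allele depths for a cohort of single-sample VCFs
#'
#' @param vcf_paths Named character vector: names are sample ids, values VCF
#'   paths.
#' @param panel A `bee_panel`.
#' @return A `count_matrix` with one row per VCF, in input order.
#' @export
read_cohort_depths <- function(vcf_paths, panel) {
  stopifnot(length(vcf_paths) > 0L, !is.null(names(vcf_paths)))
  rows <- lapply(vcf_paths, read_allele_depths, panel = panel)
  bind_count_rows(rows, panel)
}

#' Tally off-target variants detected by the amplicons
#'
#' Targeted amplicons routinely reveal variants beyond the panel's SNPs.
#' This counts distinct non-panel variants observed in at least a given
#' fraction of samples, split by class: SNP (both alleles single bases),
#' indel (allele length change) or complex (equal-length multi-base).
#' Multi-allelic records are decomposed per alternative allele.
#'
#' @param vcf_paths Character vector of single-sample VCF paths (one sample
#'   each).
#' @param panel A `bee_panel`; exact (chrom, pos, ref, alt) matches are
#'   on-target and excluded.
#' @param fraction_thresholds Numeric vector of sample fractions in (0, 1].
#' @return A data frame with one row per threshold: columns `threshold`,
#'   `SNP`, `indel`, `complex`, `total`.
#' @export
tally_offtarget_variants <- function(vcf_paths, panel,
                                     fraction_thresholds = c(0.05, 0.50, 0.90)) {
  stopifnot(inherits(panel, "bee_panel"))
  if (length(vcf_paths) == 0L) stop("empty VCF collection")
  if (any(fraction_thresholds <= 0) || any(fraction_thresholds > 1)) {
    stop("fraction thresholds must lie in (0, 1]")
  }
  panel_key <- paste(panel$chrom, panel$pos, panel$ref, panel$alt, sep = ":")

  per_sample_keys <- lapply(vcf_paths, function(p) {
    vcf <- vcfR::read.vcfR(p, verbose = FALSE)
    fix <- vcf@fix
    if (is.null(fix) || nrow(fix) == 0L) return(character(0))
    keys <- unlist(lapply(seq_len(nrow(fix)), function(j) {
      alts <- strsplit(fix[j, "ALT"], ",", fixed = TRUE)[[1L]]
      paste(fix[j, "CHROM"], fix[j, "POS"], fix[j, "REF"], alts, sep = ":")
    }), use.names = FALSE)
    unique(setdiff(keys, panel_key))
  })

  all_keys <- unique(unlist(per_sample_keys, use.names = FALSE))
  n_samples <- length(vcf_paths)
  out <- data.frame(threshold = fraction_thresholds,
                    SNP = 0L, indel = 0L, complex = 0L, total = 0L)
  if (length(all_keys) > 0L) {
    frac <- vapply(all_keys, function(k) {
      sum(vapply(per_sample_keys, function(s) k %in% s, logical(1))) / n_samples
    }, numeric(1))
    parts <- strsplit(all_keys, ":", fixed = TRUE)
    cls <- vapply(parts, function(p) {
      ref <- p[[3L]]; alt <- p[[4L]]
      if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
      else if (nchar(ref) != nchar(alt)) "indel"
      else "complex"
    }, character(1))
    for (i in seq_along(fraction_thresholds)) {
      keep <- frac >= fraction_thresholds[i]
      out$SNP[i] <- sum(keep & cls == "SNP")
      out$indel[i] <- sum(keep & cls == "indel")
      out$complex[i] <- sum(keep & cls == "complex")
    }
    out$total <- out$SNP + out$indel + out$complex
  }
  out
}

#' Write a single-sample VCF of per-marker allele depths
#'
#' Emits a minimal VCF 4.2 with `GT:AD:DP` FORMAT fields, one record per
#' covered marker (markers with `NA` counts are omitted, matching the
#' upstream caller's behaviour of not reporting uncovered amplicons).
#'
#' @param path Output path.
#' @param sample_id Sample column name.
#' @param panel A `bee_panel` supplying coordinates and alleles.
#' @param ref_reads,alt_reads Named integer vectors over `panel$marker_id`.
#' @return `path`, invisibly.
#' @export
write_sample_vcf <- function(path, sample_id, panel, ref_reads, alt_reads) {
  stopifnot(inherits(panel, "bee_panel"))
  ref_reads <- ref_reads[panel$marker_id]
  alt_reads <- alt_reads[panel$marker_id]
  keep <- !is.na(ref_reads) & !is.na(alt_reads)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=honeyGBS-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (any(keep)) {
    idx <- which(keep)
    dp <- ref_reads[idx] + alt_reads[idx]
    gt <- ifelse(alt_reads[idx] == 0L, "0/0",
                 ifelse(ref_reads[idx] == 0L, "1/1", "0/1"))
    body <- paste(panel$chrom[idx], panel$pos[idx], panel$marker_id[idx],
                  panel$ref[idx], panel$alt[idx], ".", "PASS", ".",
                  "GT:AD:DP",
                  paste0(gt, ":", ref_reads[idx], ",", alt_reads[idx], ":", dp),
                  sep = "\t")
    # VCF requires positional sorting within chromosome
    ord <- order(panel$chrom[idx], panel$pos[idx])
    body <- body[ord]
  }
  writeLines(c(header, body), path)
  invisible(path)
}
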