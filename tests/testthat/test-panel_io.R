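test_that("a well-formed panel file loads with order and composition intact", {
  panel <- synthetic_panel()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  reloaded <- load_panel(path)
  expect_s3_class(reloaded, "bee_panel")
  expect_equal(nrow(reloaded), 121L)
  expect_identical(reloaded$marker_id, panel$marker_id)
  comp <- validate_panel_composition(reloaded)
  expect_true(comp$pass)
  expect_identical(comp$total, 121L)
  expect_identical(unname(comp$observed), c(97L, 3L, 3L, 18L))
})

test_that("malformed panels are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("marker_id\tchrom\tpos\tref\talt\tcategory", path)
  expect_error(load_panel(path), "empty panel")
  expect_error(load_panel(withr::local_tempfile()), "not found")

  base <- data.frame(marker_id = c("m1", "m2"), chrom = "c1",
                     pos = c(10L, 10L), ref = "A", alt = "G",
                     category = "ancestry")
  expect_error(bee_panel(base), "c1:10")

  bad_allele <- base; bad_allele$pos <- c(10L, 20L); bad_allele$alt <- c("G", "N")
  expect_error(bee_panel(bad_allele), "non-ACGT.*m2")

  same <- base; same$pos <- c(10L, 20L); same$ref <- "A"; same$alt <- c("A", "G")
  expect_error(bee_panel(same), "identical ref and alt.*m1")

  dup <- base; dup$pos <- c(10L, 20L); dup$marker_id <- "m1"
  expect_error(bee_panel(dup), "duplicate marker_id")
})

test_that("composition validation reports per-category failures and honours overrides", {
  panel <- tiny_panel(4, 1, 1, 2)
  expect_true(validate_panel_composition(panel)$pass)

  off <- synthetic_panel()
  off <- off[-nrow(off), ]  # drop one varroa marker: 120 total
  attr(off, "expected_counts") <- DEFAULT_PANEL_COUNTS
  class(off) <- c("bee_panel", "data.frame")
  comp <- validate_panel_composition(off)
  expect_false(comp$pass)
  expect_identical(comp$total, 120L)
  expect_identical(comp$failures, "varroa_resistance")

  # custom expectation matching a custom panel passes
  custom <- synthetic_panel(expected_counts = c(
    ancestry = 10L, calmness = 1L, gentleness = 1L, varroa_resistance = 2L))
  expect_true(validate_panel_composition(custom)$pass)
})

test_that("sample sheets validate duplicate groups, matrix types and honey copy rules", {
  sheet <- flat_sheet(c("a", "b"))
  expect_s3_class(sheet, "sample_sheet")

  expect_error(flat_sheet(c("a", "b"), duplicate_group = c("g1", NA)),
               "fewer than 2 members")
  expect_error(flat_sheet(c("a", "b"), matrix_type = "pollen"),
               "unknown matrix_type")
  expect_error(flat_sheet(c("a", "a")), "duplicate sample_id")
  # honey must not carry n_individuals; bees must
  expect_error(sample_sheet(data.frame(
    sample_id = "h", matrix_type = "bulk_honey", subspecies = NA,
    lineage = NA, duplicate_group = NA, n_individuals = 35L, ploidy = 2L,
    mitotype = NA)), "absent for honey")
  expect_error(sample_sheet(data.frame(
    sample_id = "w", matrix_type = "worker_pool", subspecies = NA,
    lineage = NA, duplicate_group = NA, n_individuals = NA, ploidy = 2L,
    mitotype = NA)), "required for non-honey")
})

test_that("a study-composition sheet has 61 records and survives a round trip", {
  panel <- tiny_panel()
  cohort <- simulate_study_cohort(panel, seed = 11)
  expect_equal(nrow(cohort$sheet), 61L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_sheet(cohort$sheet, path)
  reloaded <- load_sample_sheet(path)
  expect_identical(as.data.frame(reloaded), as.data.frame(cohort$sheet))
})

test_that("AF tables round-trip exactly, including missing cells", {
  af <- matrix(c(0, 50.5, 100, NA, 33 + 1 / 3, 12.25), nrow = 2,
               dimnames = list(c("s1", "s2"), c("m1", "m2", "m3")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_af_table(af, path)
  back <- read_af_table(path)
  expect_equal(unclass(back)[, ], af)
  expect_identical(attr(back, "provenance"), "read_count_derived")
  expect_error(read_af_table(path, provenance = "genotype_derived"),
               "0, 50 or 100")
})

test_that("allele depths read from a VCF equal the VCF's depth fields exactly", {
  panel <- tiny_panel()
  # complete VCF: every populated cell must match, no invented counts
  ref_reads <- stats::setNames(seq_len(nrow(panel)) * 10L, panel$marker_id)
  alt_reads <- stats::setNames(seq_len(nrow(panel)) * 3L, panel$marker_id)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_sample_vcf(path, "s1", panel, ref_reads, alt_reads)
  row <- read_allele_depths(path, panel)
  expect_identical(row$ref, ref_reads)
  expect_identical(row$alt, alt_reads)

  # dropout: one marker absent -> exactly that cell missing
  drop <- ref_reads; drop[["bee_snp_2"]] <- NA_integer_
  drop_alt <- alt_reads; drop_alt[["bee_snp_2"]] <- NA_integer_
  write_sample_vcf(path, "s1", panel, drop, drop_alt)
  row <- read_allele_depths(path, panel)
  expect_true(is.na(row$ref[["bee_snp_2"]]))
  expect_equal(sum(!is.na(row$ref)), nrow(panel) - 1L)
})

test_that("swapped alleles are warned about and never silently flipped", {
  panel <- tiny_panel()
  p1 <- panel[1L, ]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, "s1", p1$chrom, p1$pos, p1$marker_id,
                    ref = p1$alt, alt = p1$ref,   # swapped
                    gt_field = "0/1:40,60:100")
  expect_warning(row <- read_allele_depths(path, panel), "swapped")
  expect_true(all(is.na(row$ref)))
  expect_true(all(is.na(row$alt)))
})

test_that("multi-allelic records use only the panel alt allele's depth", {
  panel <- tiny_panel()
  p1 <- panel[1L, ]
  other <- setdiff(c("A", "C", "G", "T"), c(p1$ref, p1$alt))[1L]
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, "s1", p1$chrom, p1$pos, p1$marker_id,
                    ref = p1$ref, alt = paste(other, p1$alt, sep = ","),
                    gt_field = "0/2:70,9,21:100")
  row <- read_allele_depths(path, panel)
  expect_identical(row$ref[[p1$marker_id]], 70L)
  expect_identical(row$alt[[p1$marker_id]], 21L)
})

test_that("a VCF on foreign chromosomes yields an all-missing row with a warning", {
  panel <- tiny_panel()
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, "s1", "chrUn", 5, ".", "A", "G", "0/1:10,10:20")
  expect_warning(row <- read_allele_depths(path, panel), "all-missing")
  expect_true(all(is.na(row$ref)))
})

test_that("off-target tallies respect thresholds, classes and monotonicity", {
  panel <- tiny_panel()
  dir <- withr::local_tempdir()
  # 5 samples; one off-target SNP in 3 of 5; an indel in 1; panel sites in all
  p1 <- panel[1L, ]
  paths <- character(5)
  for (s in 1:5) {
    recs_chrom <- p1$chrom; recs_pos <- p1$pos; recs_id <- p1$marker_id
    recs_ref <- p1$ref; recs_alt <- p1$alt; recs_gt <- "0/1:10,10:20"
    if (s <= 3) {  # off-target SNP at a non-panel site
      recs_chrom <- c(recs_chrom, "NC_010"); recs_pos <- c(recs_pos, 999)
      recs_id <- c(recs_id, "."); recs_ref <- c(recs_ref, "T")
      recs_alt <- c(recs_alt, "C"); recs_gt <- c(recs_gt, "0/1:5,5:10")
    }
    if (s == 1) {  # off-target indel
      recs_chrom <- c(recs_chrom, "NC_011"); recs_pos <- c(recs_pos, 123)
      recs_id <- c(recs_id, "."); recs_ref <- c(recs_ref, "A")
      recs_alt <- c(recs_alt, "AT"); recs_gt <- c(recs_gt, "0/1:5,5:10")
    }
    paths[s] <- write_vcf_fixture(file.path(dir, paste0("s", s, ".vcf")),
                                  paste0("s", s), recs_chrom, recs_pos,
                                  recs_id, recs_ref, recs_alt, recs_gt)
  }
  tab <- tally_offtarget_variants(paths, panel, c(0.05, 0.50, 0.90))
  # 3/5 = 0.60: the SNP counts at 0.05 and 0.50, not 0.90
  expect_equal(tab$SNP, c(1L, 1L, 0L))
  # 1/5 = 0.20: the indel counts only at 0.05, classified indel
  expect_equal(tab$indel, c(1L, 0L, 0L))
  expect_equal(tab$complex, c(0L, 0L, 0L))
  expect_equal(tab$total, c(2L, 1L, 0L))
  # counts never increase with the threshold
  expect_true(all(diff(tab$total) <= 0))

  # panel-only VCFs -> all zeros
  only <- withr::local_tempfile(fileext = ".vcf")
  write_sample_vcf(only, "s1", panel,
                   stats::setNames(rep(10L, nrow(panel)), panel$marker_id),
                   stats::setNames(rep(5L, nrow(panel)), panel$marker_id))
  zero <- tally_offtarget_variants(only, panel)
  expect_true(all(zero$total == 0L))
  expect_error(tally_offtarget_variants(character(0), panel), "empty")
})
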