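# All simulator tests run under fixed seeds chosen up front; stochastic
# assertions use tolerances derived from the sampling distributions.

test_that("lineage profiles are reproducible and respect the Balding-Nichols moments", {
  panel <- synthetic_panel()
  p1 <- make_lineage_profiles(panel, F = 0.1, seed = 99)
  p2 <- make_lineage_profiles(panel, F = 0.1, seed = 99)
  expect_identical(p1, p2)
  expect_true(all(p1$lineage_freq >= 0 & p1$lineage_freq <= 1))
  expect_error(make_lineage_profiles(panel, F = 0), "in \\(0, 1\\)")
  expect_error(make_lineage_profiles(panel, F = 1), "in \\(0, 1\\)")

  # F -> 0: per-marker variance p(1-p)F collapses; lineage freqs hug the
  # ancestral values
  tight <- make_lineage_profiles(panel, F = 0.001, seed = 7)
  dev <- abs(sweep(tight$lineage_freq, 2, tight$ancestral_freq))
  expect_gte(mean(dev <= 0.05), 0.99)

  # Beta mean = ancestral p: average over many markers
  big <- bee_panel(data.frame(
    marker_id = paste0("x", 1:10000), chrom = "c1", pos = 1:10000,
    ref = "A", alt = "G", category = "ancestry"),
    expected_counts = c(ancestry = 10000L, calmness = 0L, gentleness = 0L,
                        varroa_resistance = 0L))
  prof <- make_lineage_profiles(big, lineages = "C", F = 0.2, seed = 13)
  expect_lt(abs(mean(prof$lineage_freq["C", ]) - mean(prof$ancestral_freq)),
            0.01)
})

test_that("colony founding follows haplodiploid structure and recomputes truth", {
  panel <- tiny_panel(20, 1, 1, 2)
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 3)
  col <- found_colony(prof, "C", n_drones = 10, n_workers = 200, seed = 4)
  # truth is the realised mean worker dosage over 2, exactly
  expect_identical(col$true_colony_af, colMeans(col$worker_dosage) / 2)
  expect_true(all(col$queen_genotype %in% 0:2))
  expect_true(all(col$drone_haplotypes %in% 0:1))
  expect_identical(col$mitotype, "C1")
  expect_error(found_colony(prof, "Z"), "unknown lineage")

  # one diploid worker: colony AF can only be 0, 0.5 or 1
  solo <- found_colony(prof, "M", n_workers = 1, seed = 5)
  expect_true(all(solo$true_colony_af %in% c(0, 0.5, 1)))

  # determinism
  expect_identical(found_colony(prof, "A", seed = 8, n_workers = 50),
                   found_colony(prof, "A", seed = 8, n_workers = 50))
})

test_that("mean colony AF tracks the maternal lineage frequency without admixture", {
  panel <- tiny_panel(10, 1, 1, 2)
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 21)
  afs <- vapply(seq_len(400), function(i) {
    found_colony(prof, "M", alpha = 0, n_workers = 60, n_drones = 12,
                 seed = 5000 + i)$true_colony_af
  }, numeric(nrow(panel)))
  mean_af <- rowMeans(afs)
  target <- prof$lineage_freq["M", ]
  # Monte-Carlo s.e. per marker ~ sqrt(0.146 p(1-p) / 400) < 0.01
  expect_lt(max(abs(mean_af - target)), 0.035)
})

test_that("simulated counts conserve depth and obey the error model edge cases", {
  panel <- tiny_panel()
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 31)
  col <- found_colony(prof, "C", n_workers = 35, seed = 32)
  cfg <- sim_config()
  row <- simulate_counts(col, "worker_pool", cfg, seed = 33)
  # conservation: populated cells carry ref + alt = DP >= 0
  ok <- !is.na(row$ref)
  expect_true(all(row$ref[ok] >= 0L & row$alt[ok] >= 0L))
  expect_identical(row, simulate_counts(col, "worker_pool", cfg, seed = 33))
  expect_error(simulate_counts(col, "royal_jelly", cfg), "no depth tier")

  # zero error and a fixed-alt colony: every covered marker is pure ALT
  fixed <- col
  fixed$true_colony_af[] <- 1
  cfg0 <- sim_config(base_error_rate = 0)
  r <- simulate_counts(fixed, "worker_pool", cfg0, seed = 34)
  ok <- !is.na(r$ref)
  expect_true(all(r$ref[ok] == 0L))
})

test_that("estimated AF at deep fixed coverage concentrates around truth", {
  panel <- tiny_panel(1, 1, 1, 1)
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 41)
  col <- found_colony(prof, "C", n_workers = 4, seed = 42)
  col$true_colony_af[] <- 0.5
  # near-deterministic depth 10,000: binomial 95% interval is +/- 0.98 pp
  cfg <- sim_config(depth_tier_mean = c(worker_pool = 10000),
                    depth_dispersion = 1e9, base_error_rate = 0)
  hits <- vapply(seq_len(400), function(i) {
    r <- simulate_counts(col, "worker_pool", cfg, seed = 9000 + i)
    af <- estimate_af(r$ref, r$alt)
    mean(abs(af - 50) <= 2, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(hits), 0.95)
})

test_that("duplicate aliquots share truth and concord tier-dependently", {
  panel <- synthetic_panel()
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 51)
  col <- found_colony(prof, "C", n_workers = 35, seed = 52)
  cfg <- sim_config()
  expect_error(simulate_duplicate(col, "worker_pool", cfg, 7, 7),
               "seeds must differ")

  pool_icc <- vapply(seq_len(20), function(i) {
    dup <- simulate_duplicate(col, "worker_pool", cfg,
                              seed_a = 2 * i, seed_b = 2 * i + 1)
    icc_agreement(estimate_af(dup$a$ref, dup$a$alt),
                  estimate_af(dup$b$ref, dup$b$alt))
  }, numeric(1))
  honey_col <- found_colony(prof, "C", n_workers = 1000, seed = 53)
  honey_icc <- vapply(seq_len(20), function(i) {
    dup <- simulate_duplicate(honey_col, "bulk_honey", cfg,
                              seed_a = 2 * i, seed_b = 2 * i + 1)
    icc_agreement(estimate_af(dup$a$ref, dup$a$alt),
                  estimate_af(dup$b$ref, dup$b$alt))
  }, numeric(1))
  expect_gt(median(pool_icc), 0.99)
  # degraded honey tier agrees less well than deep worker pools
  expect_lt(median(honey_icc), median(pool_icc))
})

test_that("reference panels encode diploid genotypes as 0/50/100 with binomial means", {
  panel <- tiny_panel(6, 1, 1, 2)
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 61)
  # published composition: 68+22+9+10+24+28 WGS references = 161
  refs <- simulate_reference_panel(
    prof, c(A = 68, C = 22, O = 9, C = 10, M = 24, A = 28), seed = 62,
    matrix_type = "wgs_reference")
  expect_equal(nrow(refs$af), 161L)
  expect_true(all(refs$af %in% c(0, 50, 100)))
  expect_identical(attr(refs$af, "provenance"), "genotype_derived")
  expect_equal(nrow(refs$sheet), 161L)

  # a degenerate lineage frequency of 0 fixes every individual at 0
  prof0 <- prof
  prof0$lineage_freq["A", ] <- 0
  zero <- simulate_reference_panel(prof0, c(A = 30), seed = 63)
  expect_true(all(zero$af == 0))

  # empirical mean of encoded/100 approaches the lineage frequency
  many <- simulate_reference_panel(prof, c(C = 800), seed = 64)
  emp <- colMeans(many$af) / 100
  se <- sqrt(prof$lineage_freq["C", ] * (1 - prof$lineage_freq["C", ]) / 1600)
  expect_true(all(abs(emp - prof$lineage_freq["C", ]) < 5 * se + 0.01))
})

test_that("AF estimation recovers colony truth with unit slope at pool depth", {
  panel <- synthetic_panel()
  prof <- make_lineage_profiles(panel, F = 0.2, seed = 71)
  cfg <- sim_config()
  est <- c(); truth <- c()
  for (i in seq_len(50)) {
    col <- found_colony(prof, "C", n_workers = 35, seed = 300 + i)
    r <- simulate_counts(col, "worker_pool", cfg, seed = 600 + i)
    af <- estimate_af(r$ref, r$alt) / 100
    ok <- !is.na(af)
    est <- c(est, af[ok]); truth <- c(truth, col$true_colony_af[ok])
  }
  slope <- stats::coef(stats::lm(est ~ truth))[["truth"]]
  expect_gte(slope, 0.98)
  expect_lte(slope, 1.02)
})

test_that("the study cohort reproduces the validation design composition", {
  panel <- synthetic_panel()
  cohort <- simulate_study_cohort(panel, seed = 81)
  sheet <- cohort$sheet
  expect_equal(nrow(sheet), 61L)
  expect_equal(sum(sheet$matrix_type == "larva"), 4L)
  expect_equal(sum(sheet$matrix_type == "worker_pool"), 5L)
  expect_equal(sum(sheet$matrix_type == "honeycomb_honey"), 38L)
  expect_equal(sum(sheet$matrix_type == "bulk_honey"), 14L)
  dups <- table(stats::na.omit(sheet$duplicate_group))
  expect_equal(length(dups), 8L)          # eight duplicate pairs
  expect_true(all(dups == 2L))            # sixteen sequenced aliquots
  # every duplicated sample pair shares one colony truth
  for (g in names(dups)) {
    members <- sheet$sample_id[sheet$duplicate_group %in% g]
    expect_identical(cohort$colony_of[[members[1]]],
                     cohort$colony_of[[members[2]]])
  }
  # determinism of the full cohort
  again <- simulate_study_cohort(panel, seed = 81)
  expect_identical(cohort$counts, again$counts)
  expect_identical(as.data.frame(cohort$sheet), as.data.frame(again$sheet))
})
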