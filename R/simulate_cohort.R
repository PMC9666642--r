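# Study-style cohort: 61 GBS samples across four biological matrices with
# eight duplicate-aliquot pairs, mirroring the composition of the assay's
# validation design (4 larvae; 3 worker pools + 2 duplicates; 32 + 1 + 1
# honeycomb samples + 4 duplicates; 2 + 10 bulk honey samples + 2
# duplicates).

# deterministic stream of sub-seeds below 2^31, derived from one base seed
seed_stream <- function(seed) {
  i <- 0
  function() {
    i <<- i + 1
    as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)
  }
}

#' Simulate a full GBS validation cohort
#'
#' Builds a 61-sample cohort with the composition of the assay's real
#' validation design: 4 single \emph{A. m. ligustica} larvae, 3 worker
#' pools of 35 bees (+2 duplicate aliquots), 34 honeycomb honey samples
#' (+4 duplicates) and 12 bulk honey samples (+2 duplicates), spread over
#' \emph{A. m. ligustica} (lineage C), \emph{A. m. mellifera} (lineage M)
#' and \emph{A. m. siciliana} (lineage A) colonies. The
#' \emph{A. m. mellifera} colonies carry an introgressed maternal line:
#' their recorded mitotype is C1 while their nuclear gene pool is
#' predominantly M — the classic discordance signal of maternal
#' introgression from \emph{A. m. ligustica}. Two \emph{A. m. siciliana}
#' bulk-honey apiaries are admixed (half the drone fathers of lineage C)
#' and record a mixed "A,C1" mitotype set.
#'
#' @param panel A `bee_panel`.
#' @param profiles A `lineage_profiles` over the panel (default: fresh
#'   profiles at `F = 0.2` under `seed`).
#' @param cfg A `sim_config`.
#' @param seed Integer base seed; every colony and sequencing draw uses a
#'   sub-seed derived deterministically from it.
#' @param out_dir Optional directory; when given, writes one VCF per
#'   sample under `<out_dir>/vcf/`, plus `sample_sheet.tsv` and
#'   `truth.tsv` (colony_id, marker_id, true_af).
#' @return List: `sheet` (a `sample_sheet`, canonical row order),
#'   `counts` (a `count_matrix`), `truth` (long data frame of true colony
#'   allele frequencies), `colonies` (named list of `colony_model`s),
#'   `colony_of` (named map sample_id -> colony_id), and `paths` when
#'   `out_dir` was given.
#' @export
simulate_study_cohort <- function(panel, profiles = NULL, cfg = sim_config(),
                                  seed = 1L, out_dir = NULL) {
  stopifnot(inherits(panel, "bee_panel"))
  if (is.null(profiles)) {
    profiles <- make_lineage_profiles(panel, F = 0.2, seed = seed)
  }
  next_seed <- seed_stream(seed)
  colonies <- list()
  rows <- list()
  sheet_rows <- list()
  colony_of <- character(0)

  new_colony <- function(id, maternal, paternal = maternal, alpha = 0,
                         n_workers = 1000L) {
    col <- found_colony(profiles, maternal, paternal, alpha,
                        n_workers = n_workers, seed = next_seed(),
                        colony_id = id)
    colonies[[id]] <<- col
    col
  }
  add_sample <- function(sample_id, colony, matrix_type, subspecies, lineage,
                         duplicate_group = NA, n_individuals = NA,
                         mitotype = colony$mitotype) {
    rows[[sample_id]] <<- simulate_counts(colony, matrix_type, cfg,
                                          seed = next_seed())
    colony_of[[sample_id]] <<- colony$colony_id
    sheet_rows[[sample_id]] <<- data.frame(
      sample_id = sample_id, matrix_type = matrix_type,
      subspecies = subspecies, lineage = lineage,
      duplicate_group = as.character(duplicate_group),
      n_individuals = as.integer(n_individuals), ploidy = 2L,
      mitotype = as.character(mitotype), stringsAsFactors = FALSE)
  }

  # (i) four individually genotyped ligustica larvae, one colony each
  for (i in 1:4) {
    col <- new_colony(sprintf("lig_larva_col_%d", i), "C", n_workers = 1L)
    add_sample(sprintf("larva_%d", i), col, "larva", "A_m_ligustica", "C",
               n_individuals = 1L)
  }
  # (ii) three DNA pools of 35 workers; pools 1-2 sequenced in duplicate
  for (i in 1:3) {
    col <- new_colony(sprintf("lig_pool_col_%d", i), "C", n_workers = 35L)
    dg <- if (i <= 2) sprintf("dup_pool_%d", i) else NA
    add_sample(sprintf("pool_%d", i), col, "worker_pool", "A_m_ligustica",
               "C", duplicate_group = dg, n_individuals = 35L)
    if (i <= 2) {
      add_sample(sprintf("pool_%d_dup", i), col, "worker_pool",
                 "A_m_ligustica", "C", duplicate_group = dg,
                 n_individuals = 35L)
    }
  }
  # (iii) honeycomb honey: 32 ligustica (first 4 in duplicate), 1
  # introgressed mellifera, 1 siciliana
  for (i in 1:32) {
    col <- new_colony(sprintf("lig_comb_col_%d", i), "C")
    dg <- if (i <= 4) sprintf("dup_comb_%d", i) else NA
    add_sample(sprintf("comb_lig_%d", i), col, "honeycomb_honey",
               "A_m_ligustica", "C", duplicate_group = dg)
    if (i <= 4) {
      add_sample(sprintf("comb_lig_%d_dup", i), col, "honeycomb_honey",
                 "A_m_ligustica", "C", duplicate_group = dg)
    }
  }
  # mellifera with C1 mitotype: maternal line introgressed from ligustica,
  # nuclear gene pool mostly M (recorded mitotype overrides the colony map)
  col <- new_colony("mel_comb_col_1", "M", paternal = "C", alpha = 0.3)
  add_sample("comb_mel_1", col, "honeycomb_honey", "A_m_mellifera", "M",
             mitotype = "C1")
  col <- new_colony("sic_comb_col_1", "A")
  add_sample("comb_sic_1", col, "honeycomb_honey", "A_m_siciliana", "A")
  # (iv) bulk honey: 2 mellifera (one heavily admixed), 10 siciliana of
  # which two admixed apiaries with mixed mitotypes; first two siciliana
  # sequenced in duplicate
  col <- new_colony("mel_bulk_col_1", "M", paternal = "C", alpha = 0.3)
  add_sample("honey_mel_1", col, "bulk_honey", "A_m_mellifera", "M",
             mitotype = "C1")
  col <- new_colony("mel_bulk_col_2", "M", paternal = "C", alpha = 0.8)
  add_sample("honey_mel_2", col, "bulk_honey", "A_m_mellifera", "M",
             mitotype = "C1")
  for (i in 1:10) {
    admixed <- i %in% c(9, 10)
    col <- new_colony(sprintf("sic_bulk_col_%d", i), "A",
                      paternal = if (admixed) "C" else "A",
                      alpha = if (admixed) 0.5 else 0)
    dg <- if (i <= 2) sprintf("dup_honey_%d", i) else NA
    add_sample(sprintf("honey_sic_%d", i), col, "bulk_honey",
               "A_m_siciliana", "A", duplicate_group = dg,
               mitotype = if (admixed) "A,C1" else "A")
    if (i <= 2) {
      add_sample(sprintf("honey_sic_%d_dup", i), col, "bulk_honey",
                 "A_m_siciliana", "A", duplicate_group = dg, mitotype = "A")
    }
  }

  sheet <- sample_sheet(do.call(rbind, sheet_rows))
  counts <- bind_count_rows(rows[sheet$sample_id], panel)
  truth <- do.call(rbind, lapply(colonies, function(col) {
    data.frame(colony_id = col$colony_id,
               marker_id = names(col$true_colony_af),
               true_af = unname(col$true_colony_af),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL

  out <- list(sheet = sheet, counts = counts, truth = truth,
              colonies = colonies, colony_of = colony_of,
              profiles = profiles)
  if (!is.null(out_dir)) {
    vcf_dir <- file.path(out_dir, "vcf")
    dir.create(vcf_dir, recursive = TRUE, showWarnings = FALSE)
    vcf_paths <- stats::setNames(
      file.path(vcf_dir, paste0(sheet$sample_id, ".vcf")), sheet$sample_id)
    for (sid in sheet$sample_id) {
      write_sample_vcf(vcf_paths[[sid]], sid, panel,
                       counts$ref[sid, ], counts$alt[sid, ])
    }
    sheet_path <- file.path(out_dir, "sample_sheet.tsv")
    truth_path <- file.path(out_dir, "truth.tsv")
    write_sample_sheet(sheet, sheet_path)
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- list(vcf = vcf_paths, sheet = sheet_path, truth = truth_path)
  }
  out
}
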