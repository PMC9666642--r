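#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' tunable at its documented default. Fields can be overridden by the
#' `overrides` list (or by a YAML file via `load_pipeline_config()`).
#'
#' @param overrides Named list of fields to override.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    # input paths (all NULL when simulating)
    panel = NULL, sample_sheet = NULL, vcf_dir = NULL,
    out_dir = "pipeline_out",
    # analysis tunables
    min_dp = 1L, call_rate_threshold = 0.90, outlier_delta = 20,
    mds_k = 2L, tau = 0.8, group_by = "subspecies",
    # simulation block: set simulate = TRUE to generate the cohort; the
    # reference set sizes default to the published composition
    simulate = FALSE,
    divergence_F = 0.2,
    n_genotype_reference = c(C = 10, M = 406, C = 34),
    n_wgs_reference = c(A = 68, C = 22, O = 9, C = 10, M = 24, A = 28),
    seed = 1L
  )
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()] fields.
#' @return A `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  for (nm in c("n_genotype_reference", "n_wgs_reference")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  pipeline_config(raw)
}

pipeline_log <- function(...) message("[honeyGBS] ", ...)

#' Run the full honey-GBS analysis pipeline
#'
#' Orchestrates the stages in analysis order: (simulate or load inputs)
#' -> allele-frequency matrix -> call-rate QC -> duplicate concordance ->
#' combined-matrix MDS and lineage assignment with mitotype cross-check
#' -> trait-marker report. Every emitted file is listed in a manifest
#' with its MD5 content hash; identical config + seed reproduce identical
#' hashes.
#'
#' @param config A `pipeline_config`, a list of overrides, or a YAML
#'   path.
#' @return Invisibly, a list with `manifest` (data frame of file, md5),
#'   `out_dir`, and the main in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  stopifnot(config$min_dp >= 1L, config$tau > 0, config$tau <= 1,
            config$call_rate_threshold > 0, config$call_rate_threshold <= 1)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emitted <- character(0)
  emit <- function(path) { emitted <<- c(emitted, path); path }

  # --- stage: inputs -------------------------------------------------
  if (isTRUE(config$simulate)) {
    pipeline_log("stage simulate: generating cohort (seed ", config$seed, ")")
    panel <- synthetic_panel()
    emit(write_panel(panel, file.path(out_dir, "panel.tsv")))
    profiles <- make_lineage_profiles(panel, F = config$divergence_F,
                                      seed = config$seed)
    cohort <- simulate_study_cohort(panel, profiles, sim_config(),
                                    seed = config$seed, out_dir = out_dir)
    for (p in cohort$paths$vcf) emit(p)
    emit(cohort$paths$sheet); emit(cohort$paths$truth)
    sheet <- cohort$sheet
    counts <- cohort$counts
  } else {
    if (is.null(config$panel) || !file.exists(config$panel)) {
      stop("stage config: panel path missing or not found")
    }
    if (is.null(config$sample_sheet) || !file.exists(config$sample_sheet)) {
      stop("stage config: sample sheet path missing or not found")
    }
    if (is.null(config$vcf_dir) || !dir.exists(config$vcf_dir)) {
      stop("stage config: vcf_dir missing or not found")
    }
    panel <- load_panel(config$panel)
    sheet <- load_sample_sheet(config$sample_sheet)
    vcf_paths <- stats::setNames(
      file.path(config$vcf_dir, paste0(sheet$sample_id, ".vcf")),
      sheet$sample_id)
    absent <- vcf_paths[!file.exists(vcf_paths)]
    if (length(absent) > 0L) {
      stop("stage inputs: missing VCF(s): ", paste(absent, collapse = ", "))
    }
    pipeline_log("stage inputs: reading ", length(vcf_paths), " VCFs")
    counts <- read_cohort_depths(vcf_paths, panel)
    profiles <- NULL
  }
  comp <- validate_panel_composition(panel)
  pipeline_log("stage panel: ", comp$total, " markers, composition ",
               if (comp$pass) "OK" else "MISMATCH")
  pipeline_log("stage inputs: ", nrow(sheet), " samples x ", nrow(panel),
               " markers")

  # --- stage: allele frequencies -------------------------------------
  af <- af_matrix(counts, min_dp = config$min_dp)
  emit(write_af_table(af, file.path(out_dir, "af_matrix.tsv")))
  pipeline_log("stage afmatrix: ", sum(!is.na(af)), " called cells")

  # --- stage: QC -----------------------------------------------------
  qc <- qc_summary(counts, sheet, threshold = config$call_rate_threshold,
                   min_dp = config$min_dp)
  utils::write.table(
    data.frame(sample_id = names(qc$sample_call_rate),
               call_rate = qc$sample_call_rate),
    emit(file.path(out_dir, "qc_samples.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(marker_id = names(qc$snp_call_rate),
               call_rate = qc$snp_call_rate,
               low_call = names(qc$snp_call_rate) %in% qc$low_call_markers),
    emit(file.path(out_dir, "qc_markers.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  depth_tab <- depth_summary(counts, sheet)
  utils::write.table(depth_tab, emit(file.path(out_dir, "depth_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log("stage qc: mean sample call rate ",
               sprintf("%.1f%%", 100 * mean(qc$sample_call_rate)), "; ",
               qc$n_markers_covered_in_all, " markers covered in all samples")

  # --- stage: concordance --------------------------------------------
  conc <- NULL
  if (any(!is.na(sheet$duplicate_group))) {
    conc <- duplicate_concordance(af, sheet,
                                  outlier_delta = config$outlier_delta)
    utils::write.table(conc, emit(file.path(out_dir, "concordance.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pipeline_log("stage concordance: ", nrow(conc), " duplicate pairs, ",
                 "median ICC ", sprintf("%.4f", stats::median(conc$icc)))
  } else {
    pipeline_log("stage concordance: no duplicate groups, skipped")
  }

  # --- stage: ancestry (MDS + assignment) ----------------------------
  sources <- list(af)
  full_sheet <- sheet
  if (isTRUE(config$simulate)) {
    refs_g <- simulate_reference_panel(
      profiles, config$n_genotype_reference,
      seed = config$seed + 101L, matrix_type = "genotype_reference",
      id_prefix = "geno_ref",
      markers = marker_subset(panel, "ancestry"))
    refs_w <- simulate_reference_panel(
      profiles, config$n_wgs_reference,
      seed = config$seed + 202L, matrix_type = "wgs_reference",
      id_prefix = "wgs_ref",
      markers = marker_subset(panel, "ancestry"))
    sources <- c(sources, list(refs_g$af, refs_w$af))
    full_sheet <- sample_sheet(rbind(as.data.frame(sheet),
                                     as.data.frame(refs_g$sheet),
                                     as.data.frame(refs_w$sheet)))
  }
  combined <- assemble_matrix(sources, panel)
  mds <- classical_mds(combined, k = config$mds_k)
  coord_tab <- data.frame(sample_id = rownames(mds$coordinates),
                          mds$coordinates, check.names = FALSE)
  utils::write.table(coord_tab, emit(file.path(out_dir, "mds_coordinates.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  assignment <- tryCatch(
    mito_concordance(assign_lineage(mds, full_sheet, tau = config$tau),
                     full_sheet),
    error = function(e) {
      pipeline_log("stage assign: skipped (", conditionMessage(e), ")")
      NULL
    })
  if (!is.null(assignment)) {
    utils::write.table(assignment, emit(file.path(out_dir, "assignments.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    pipeline_log("stage assign: ", nrow(assignment), " queries; ",
                 sum(assignment$admixture_flag), " flagged admixed; ",
                 sum(assignment$mito_status == "discordant"),
                 " mito-discordant")
  }
  pipeline_log("stage mds: combined matrix ", nrow(combined), " x ",
               ncol(combined), "; variance explained ",
               paste(sprintf("%.1f%%", 100 * mds$variance_explained),
                     collapse = ", "))

  # --- stage: trait report -------------------------------------------
  trait_ids <- marker_subset(panel, "trait")
  fix <- fixation_report(af, sheet, trait_ids, group_by = config$group_by)
  trait_tab <- trait_af_table(af, sheet, trait_ids,
                              group_by = config$group_by,
                              include_duplicates = FALSE, counts = counts)
  utils::write.table(
    data.frame(marker_id = rownames(trait_tab), trait_tab,
               check.names = FALSE),
    emit(file.path(out_dir, "trait_af.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(marker_id = rownames(fix$status), fix$status,
               check.names = FALSE),
    emit(file.path(out_dir, "trait_fixation.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log("stage report: ", fix$n_fixed_ref_all_groups, " of ",
               length(trait_ids),
               " trait markers fixed for the reference allele in all groups")

  # --- manifest ------------------------------------------------------
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", emitted),
                         md5 = unname(tools::md5sum(emitted)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log("done: ", nrow(manifest), " artifacts in ", out_dir)
  invisible(list(manifest = manifest, out_dir = out_dir, panel = panel,
                 sheet = sheet, counts = counts, af = af, qc = qc,
                 concordance = conc, mds = mds, assignment = assignment,
                 fixation = fix, trait_af = trait_tab))
}
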