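#!/usr/bin/env Rscript
# Stage 4: ancestry analysis.
#
# Assembles the 672 x 97 combined matrix (61 GBS samples + 450 reference
# genotypes + 161 WGS-derived genotypes, ancestry markers only), runs
# classical MDS, assigns each GBS sample to the nearest lineage centroid,
# and cross-checks assignments against the recorded mitotypes.

suppressMessages(library(honeyGBS))

SEED <- 20260924L   # must match stage 1 so profiles regenerate identically
panel <- load_panel("results/cohort/panel.tsv")
sheet <- load_sample_sheet("results/cohort/sample_sheet.tsv")
af <- read_af_table("results/af_matrix.tsv")
profiles <- make_lineage_profiles(panel, F = 0.2, seed = SEED)
anc <- marker_subset(panel, "ancestry")

# reference sets with the published composition: 10 + 406 + 34 previously
# genotyped bees and 68 + 22 + 9 + 10 + 24 + 28 WGS individuals
geno <- simulate_reference_panel(profiles, c(C = 10, M = 406, C = 34),
                                 seed = SEED + 101L, id_prefix = "geno_ref",
                                 markers = anc)
wgs <- simulate_reference_panel(profiles,
                                c(A = 68, C = 22, O = 9, C = 10, M = 24, A = 28),
                                seed = SEED + 202L,
                                matrix_type = "wgs_reference",
                                id_prefix = "wgs_ref", markers = anc)

combined <- assemble_matrix(list(af, geno$af, wgs$af), panel)
cat(sprintf("combined matrix: %d samples x %d ancestry markers (%d cells imputed)\n",
            nrow(combined), ncol(combined), attr(combined, "n_imputed")))

mds <- classical_mds(combined, k = 3L)
print(mds)
write.table(data.frame(sample_id = rownames(mds$coordinates),
                       mds$coordinates, check.names = FALSE),
            "results/mds_coordinates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

full_sheet <- sample_sheet(rbind(as.data.frame(sheet),
                                 as.data.frame(geno$sheet),
                                 as.data.frame(wgs$sheet)))
asg <- mito_concordance(assign_lineage(mds, full_sheet, tau = 0.8), full_sheet)
write.table(asg, "results/assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\nassigned lineage by recorded subspecies:\n")
print(table(sheet$subspecies[match(asg$sample_id, sheet$sample_id)],
            asg$assigned_lineage))
cat("\nmitotype cross-check:\n")
print(table(asg$mito_status))
cat(sprintf("\nadmixture-flagged samples (distance ratio > 0.8): %d\n",
            sum(asg$admixture_flag)))
disc <- asg[asg$mito_status == "discordant", c("sample_id", "assigned_lineage")]
if (nrow(disc) > 0) {
  cat("mito-discordant (maternal introgression signal):",
      paste(disc$sample_id, collapse = ", "), "\n")
}
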