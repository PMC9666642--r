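#!/usr/bin/env Rscript
# Stage 1: generate the synthetic validation cohort.
#
# Emulates the assay's validation design on a synthetic 121-SNP panel:
# 61 samples (4 larvae, 3+2 worker pools, 32+4+1+1 honeycomb honey,
# 2+10+2 bulk honey) over lineages C, M and A, with eight duplicate-
# aliquot pairs, written as one single-sample VCF each plus the sample
# sheet and the colony truth table.

suppressMessages(library(honeyGBS))

SEED <- 20260924L
out_dir <- "results/cohort"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

panel <- synthetic_panel()
write_panel(panel, file.path(out_dir, "panel.tsv"))
comp <- validate_panel_composition(panel)
print(comp)

profiles <- make_lineage_profiles(panel, F = 0.2, seed = SEED)
cohort <- simulate_study_cohort(panel, profiles, sim_config(), seed = SEED,
                                out_dir = out_dir)

cat(sprintf("\ncohort: %d samples, %d duplicate pairs, %d colonies\n",
            nrow(cohort$sheet),
            length(unique(na.omit(cohort$sheet$duplicate_group))),
            length(cohort$colonies)))
print(table(cohort$sheet$matrix_type))
cat("\nVCFs, sample sheet and truth written under", out_dir, "\n")
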