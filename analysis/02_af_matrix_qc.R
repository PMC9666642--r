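#!/usr/bin/env Rscript
# Stage 2: allele-frequency estimation and call-rate QC.
#
# Reads the per-sample VCFs back through the panel_io interface (exact
# (chrom, pos, ref, alt) matching, no allele flipping), estimates the
# alternative-allele frequency of every called cell, and summarises
# sample/marker call rates and sequencing depth by biological matrix.

suppressMessages(library(honeyGBS))

in_dir <- "results/cohort"
panel <- load_panel(file.path(in_dir, "panel.tsv"))
sheet <- load_sample_sheet(file.path(in_dir, "sample_sheet.tsv"))
vcfs <- setNames(file.path(in_dir, "vcf", paste0(sheet$sample_id, ".vcf")),
                 sheet$sample_id)
counts <- read_cohort_depths(vcfs, panel)

af <- af_matrix(counts, min_dp = 1L)
write_af_table(af, "results/af_matrix.tsv")

qc <- qc_summary(counts, sheet, threshold = 0.90)
print(qc)

cat("\nDepth by matrix (per-sample total DP):\n")
print(depth_summary(counts, sheet), digits = 4)

honey_flags <- flag_low_call_markers(counts, sheet, threshold = 0.90,
                                     stratify_by = HONEY_MATRIX_TYPES)
cat("\nmarkers below 90% call rate within the honey matrices:",
    paste(honey_flags, collapse = ", "), "\n")

write.table(data.frame(sample_id = names(qc$sample_call_rate),
                       call_rate = qc$sample_call_rate),
            "results/qc_samples.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(marker_id = names(qc$snp_call_rate),
                       call_rate = qc$snp_call_rate,
                       low_call_honey = names(qc$snp_call_rate) %in% honey_flags),
            "results/qc_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nAF matrix and QC tables written under results/\n")
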