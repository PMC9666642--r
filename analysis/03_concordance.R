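#!/usr/bin/env Rscript
# Stage 3: duplicate-aliquot concordance.
#
# Each duplicate group is one DNA source extracted and sequenced twice.
# Agreement of the two allele-frequency vectors is measured with the
# two-way absolute-agreement ICC (a plain correlation would ignore
# systematic shifts), alongside Pearson/Spearman and outlier markers.

suppressMessages(library(honeyGBS))

sheet <- load_sample_sheet("results/cohort/sample_sheet.tsv")
af <- read_af_table("results/af_matrix.tsv")

conc <- duplicate_concordance(af, sheet, outlier_delta = 20)
write.table(conc, "results/concordance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(conc[, c("pair_id", "icc", "pearson_r", "spearman_rho",
               "n_markers_used", "n_outliers")], digits = 5)

cat(sprintf("\npairs with ICC > 0.99: %d of %d; pool pairs agree above honey pairs\n",
            sum(conc$icc > 0.99), nrow(conc)))

# cross-dataset check for the ligustica samples: worker-pool means vs
# honeycomb-honey means over all markers
lig <- sheet$sample_id[!is.na(sheet$subspecies) &
                         sheet$subspecies == "A_m_ligustica"]
by_type <- group_mean_af(af[rownames(af) %in% lig, , drop = FALSE],
                         sheet, group_by = "matrix_type")
ds <- dataset_correlation(by_type[, "worker_pool"],
                          by_type[, "honeycomb_honey"])
cat(sprintf("pools vs honeycomb honey (ligustica): r = %.3f, rho = %.3f, n = %d\n",
            ds$pearson_r, ds$spearman_rho, ds$n))
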