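#!/usr/bin/env Rscript
# Stage 5: trait-associated marker report.
#
# Mean alternative-allele frequencies of the 24 trait markers (calmness,
# gentleness, varroa resistance) per subspecies, on the 0-1 scale, with
# and without duplicate aliquots, plus fixation classification.

suppressMessages(library(honeyGBS))

panel <- load_panel("results/cohort/panel.tsv")
sheet <- load_sample_sheet("results/cohort/sample_sheet.tsv")
af <- read_af_table("results/af_matrix.tsv")
trait_ids <- marker_subset(panel, "trait")

fix <- fixation_report(af, sheet, trait_ids, group_by = "subspecies")
print(fix)

with_dup <- trait_af_table(af, sheet, trait_ids, group_by = "subspecies",
                           include_duplicates = TRUE)
no_dup <- trait_af_table(af, sheet, trait_ids, group_by = "subspecies",
                         include_duplicates = FALSE)
cat(sprintf("\nlargest |mean AF| change from dropping duplicates: %.4f\n",
            max(abs(with_dup - no_dup), na.rm = TRUE)))

write.table(data.frame(marker_id = rownames(with_dup),
                       round(with_dup, 4), check.names = FALSE),
            "results/trait_af_with_duplicates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(marker_id = rownames(no_dup),
                       round(no_dup, 4), check.names = FALSE),
            "results/trait_af_unique.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(marker_id = rownames(fix$status), fix$status,
                       check.names = FALSE),
            "results/trait_fixation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("trait tables written under results/\n")
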