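#!/usr/bin/env Rscript
# Step 2: preprocessing.
#
# Matches samples across the three expression layers, drops samples with
# tumor purity <= 0.8, and removes genes that are lowly expressed (< 1 log2
# in more than 70% of samples) or insufficiently variable (log2 IQR <= 0.58).
# Writes the filtered matrices and the per-stage tallies.

library(lncperturb)

cohort <- read_cohort("results/cohort")
pp <- preprocess_layers(list(lnc = cohort$lnc_layer, mir = cohort$mir_layer,
                             mrna = cohort$mrna_layer),
                        purity = cohort$purity)
print(pp$counts)

dir.create("results/preprocessed", showWarnings = FALSE)
write_expression_matrix(pp$lnc, "results/preprocessed/lnc_expression.tsv")
write_expression_matrix(pp$mir, "results/preprocessed/mir_expression.tsv")
write_expression_matrix(pp$mrna, "results/preprocessed/mrna_expression.tsv")
write.table(pp$counts, "results/preprocessed/filter_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/preprocessed\n")
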