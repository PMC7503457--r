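#!/usr/bin/env Rscript
# Step 3: candidate triplets.
#
# Builds lncRNA-miRNA-mRNA candidates from the interaction table via the
# hypergeometric shared-miRNA test (BH FDR < 0.05 over all lncRNA-mRNA pairs
# sharing a miRNA), then keeps candidates whose miRNA-mRNA pair shows a
# negative all-sample Spearman correlation (R < 0, p < 0.05).

library(lncperturb)

cohort <- read_cohort("results/cohort")
layers <- list(
  lnc = read_expression_matrix("results/preprocessed/lnc_expression.tsv",
                               "lncRNA"),
  mir = read_expression_matrix("results/preprocessed/mir_expression.tsv",
                               "miRNA"),
  mrna = read_expression_matrix("results/preprocessed/mrna_expression.tsv",
                                "mRNA"))

cands <- build_candidates(cohort$interactions, layers)
cat("candidates after shared-miRNA FDR screen:", nrow(cands), "\n")
neg <- negative_pair_filter(cands, layers)
cat("candidates after negative-correlation gate:", nrow(neg), "\n")

dir.create("results", showWarnings = FALSE)
write.table(cands, "results/candidates_fdr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(neg, "results/candidates_negative.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/candidates_fdr.tsv and results/candidates_negative.tsv\n")
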