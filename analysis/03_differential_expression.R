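#!/usr/bin/env Rscript
# Differential-expression screens: negative-binomial Wald for the unpaired
# basal-vs-control contrast, per-subject log-ratios with the exact Wilcoxon
# signed-rank for the paired post-tx-vs-basal contrast.
suppressPackageStartupMessages(library(evsmallrna))

counts <- read_count_matrix("results/data/counts_filtered.tsv")
metadata <- read_metadata("results/data/metadata_filtered.csv")

de_u <- wald_test_unpaired(counts, metadata, c("basal", "control"))
write_table(de_u, "results/diffexp_basal_vs_control.tsv")
de_p <- paired_test(counts, metadata, c("post_tx", "basal"))
write_table(de_p, "results/diffexp_post_tx_vs_basal.tsv")

for (nm in c("basal_vs_control", "post_tx_vs_basal")) {
  de <- if (nm == "basal_vs_control") de_u else de_p
  sig <- de[de$p < 0.05 & de$testable, ]
  cat(nm, ": ", nrow(sig), " features at p < 0.05 (",
      sum(sig$lfc > 0), " up, ", sum(sig$lfc < 0), " down)\n", sep = "")
}
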