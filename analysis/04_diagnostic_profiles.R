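#!/usr/bin/env Rscript
# Per-feature ROC profiling and the candidate filter: AUC > 0.75 AND
# baseMean > 10 AND p < 0.05, per contrast.
suppressPackageStartupMessages(library(evsmallrna))

counts <- read_count_matrix("results/data/counts_filtered.tsv")
metadata <- read_metadata("results/data/metadata_filtered.csv")

for (nm in c("basal_vs_control", "post_tx_vs_basal")) {
  contrast <- strsplit(nm, "_vs_")[[1]]
  de <- read.delim(paste0("results/diffexp_", nm, ".tsv"),
                   stringsAsFactors = FALSE)
  prof <- diagnostic_profiles(counts, metadata, contrast)
  tab <- candidate_filter(de, prof)
  write_table(tab, paste0("results/candidates_", nm, ".tsv"))
  cand <- tab[tab$candidate, ]
  cat(nm, ":", nrow(cand), "candidates\n")
  if (nrow(cand) > 0)
    print(cand[, c("feature", "fc_signed", "p", "auc", "sn", "sp",
                   "ppv", "npv")], digits = 3)
}
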