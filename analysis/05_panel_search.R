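#!/usr/bin/env Rscript
# Pairwise biomarker panels: LOOCV linear-SVM decision scores pooled into one
# cross-validated ROC per candidate pair, plus SVM-RFE ranking.
suppressPackageStartupMessages(library(evsmallrna))

counts <- read_count_matrix("results/data/counts_filtered.tsv")
metadata <- read_metadata("results/data/metadata_filtered.csv")

for (nm in c("basal_vs_control", "post_tx_vs_basal")) {
  contrast <- strsplit(nm, "_vs_")[[1]]
  tab <- read.delim(paste0("results/candidates_", nm, ".tsv"),
                    stringsAsFactors = FALSE)
  feats <- head(tab$feature[tab$candidate], 8)
  if (length(feats) < 2) {
    cat(nm, ": fewer than two candidates, no pair search\n")
    next
  }
  M <- suppressWarnings(all_pairs_matrix(counts, metadata, feats, contrast))
  write_table(data.frame(feature = rownames(M), M, check.names = FALSE),
              paste0("results/pair_auc_", nm, ".tsv"))
  best <- attr(M, "best_pair")
  bres <- loocv_pair_auc(counts, metadata, best, contrast, ci = TRUE,
                         seed = 20260921L)
  rfe <- svm_rfe_rank(counts, metadata, feats, contrast)
  cat(nm, ": best pair", paste(best, collapse = " + "),
      sprintf("(cv AUC %.3f, 95%% CI %.3f-%.3f)\n", attr(M, "best_auc"),
              bres$cv_auc_ci[1], bres$cv_auc_ci[2]))
  cat("  SVM-RFE ranking (top last):", paste(rfe, collapse = " < "), "\n")
}
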