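#!/usr/bin/env Rscript
# qPCR normalizer selection: among features with |signed FC| < 1.2 in the
# unpaired contrast, rank by highest mean expression, lowest SD and CV
# (log2 normalized scale) and pick the best composite rank.
suppressPackageStartupMessages(library(evsmallrna))

counts <- read_count_matrix("results/data/counts_filtered.tsv")
metadata <- read_metadata("results/data/metadata_filtered.csv")
de <- read.delim("results/diffexp_basal_vs_control.tsv",
                 stringsAsFactors = FALSE)

stab <- select_reference(counts, metadata, de, window = 1.2)
stability_report(stab, "results/reference_stability.tsv")

truth_ref <- readLines("results/data/truth_reference.txt")
cat("selected reference:", stab$feature[1], "\n")
print(head(stab), digits = 3)
cat("matches the planted housekeeper:", stab$feature[1] == truth_ref, "\n")
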