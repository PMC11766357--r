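#!/usr/bin/env Rscript
# Generate the synthetic discovery cohort: 16 controls, 26 basal/post-tx
# subject pairs, 3 technical negative controls, 800 small RNAs with ~4%
# planted regulation per contrast and a designated let-7a-like housekeeper.
suppressPackageStartupMessages(library(evsmallrna))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260921L)
sim <- simulate_counts(cfg)

write_count_matrix(sim$counts, file.path(out, "counts.tsv"))
write_metadata(sim$metadata, file.path(out, "metadata.csv"))
write_table(sim$truth$features, file.path(out, "truth_features.tsv"))
writeLines(sim$truth$reference_feature,
           file.path(out, "truth_reference.txt"))

cat("cohort:", ncol(sim$counts), "samples x", nrow(sim$counts), "features\n")
cat("planted basal-vs-control features:",
    sum(sim$truth$features$lfc_basal_vs_control != 0), "\n")
cat("planted post-tx-vs-basal features:",
    sum(sim$truth$features$lfc_post_vs_basal != 0), "\n")
cat("designated reference:", sim$truth$reference_feature, "\n")
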