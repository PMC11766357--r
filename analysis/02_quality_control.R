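#!/usr/bin/env Rscript
# Sample QC: flag samples whose global profile clusters with the technical
# negative controls (correlation dominance) or whose library is too shallow;
# write the report and the filtered cohort.
suppressPackageStartupMessages(library(evsmallrna))

counts <- read_count_matrix("results/data/counts.tsv")
metadata <- read_metadata("results/data/metadata.csv")

report <- qc_report(counts, metadata, libsize_min_fraction = 0.1)
write_table(report, "results/qc_report.tsv")

flt <- apply_qc(counts, metadata, report)
write_count_matrix(flt$counts, "results/data/counts_filtered.tsv")
write_metadata(flt$metadata, "results/data/metadata_filtered.csv")

cat("excluded", sum(report$excluded), "of", nrow(report), "samples:\n")
print(table(report$reason[report$excluded]))
cat("analyzed samples by condition:\n")
print(table(flt$metadata$condition))
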