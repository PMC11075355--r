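#!/usr/bin/env Rscript
# Gene-impact classification of the QC-passed catalog: one call per
# overlapping (SV, gene) pair across the 15 categories plus intergenic,
# allele-count frequency classes, and the per-genome category summaries.

suppressMessages(library(svcat))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42

res <- run_pipeline(sim_config(seed = seed), stages = "classify",
                    out_dir = "results/impact")

cat("SV and gene counts per category:\n")
print(res$classify$counts[res$classify$counts$n_sv > 0, ])
cat("frequency classes:\n")
print(table(res$classify$freq$class))
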