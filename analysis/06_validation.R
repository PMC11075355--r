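#!/usr/bin/env Rscript
# Validate the QC-passed short-read catalog against the synthetic
# assembly-comparison SV set: >= 1 bp overlap matching, best-match
# selection by reciprocal overlap, and validation rates by count and
# length with the >98% length-consistency fraction.

suppressMessages(library(svcat))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42

res <- run_pipeline(sim_config(seed = seed), stages = "validate",
                    out_dir = "results/validation")

r <- res$validate$rates
cat(sprintf("validated %d of %d SVs: %.2f%% by count, %.2f%% by length\n",
            r$n_validated, r$n_query, 100 * r$rate_by_count,
            100 * r$rate_by_length))
cat(sprintf("%.1f%% of best-matched pairs exceed 98%% length consistency\n",
            100 * r$frac_high_consistency))
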