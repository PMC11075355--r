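#!/usr/bin/env Rscript
# Overlap enrichment of the catalog against genomic annotations: genic
# partition and repeat-class folds (chi-squared vs the whole-genome
# background), chromatin-state overlap proportions with tests against the
# quiescent state, regulator location ratios, QTL enrichment with the
# >2-fold + Bonferroni rule, and the cross-population ANOVA on
# per-individual QTL folds.

suppressMessages(library(svcat))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42

res <- run_pipeline(sim_config(seed = seed), stages = "enrich",
                    out_dir = "results/enrichment")

cat("genic partition enrichment:\n")
print(res$enrich$genic[, c("label", "fold", "p_adj", "significant")])
cat("repeat-class enrichment:\n")
print(res$enrich$repeats[, c("label", "fold", "p_adj", "significant")])
q <- res$enrich$qtl
cat(sprintf("QTLs kept after the 1 Mb cap: %d (%d traits); %.1f%% of QTLs and %.1f%% of traits overlap SVs\n",
            q$n_qtl_kept, q$n_trait_kept,
            100 * q$tallies$frac_qtl_overlapped,
            100 * q$tallies$frac_trait_overlapped))
cat(sprintf("traits with cross-population ANOVA signal (adj p<0.01, CV>1): %d\n",
            sum(res$enrich$anova$reported)))
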