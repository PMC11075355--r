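#!/usr/bin/env Rscript
# Build the seeded synthetic study: genome + annotation tracks, the
# multi-population SV catalog with evidence annotations, the SNP panel, the
# windowed copy-number matrix with planted bad bins, and the
# functional-variant catalog. Writes the standard-format inputs that the
# later steps consume and a summary of what was planted.

suppressMessages(library(svcat))
seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 42
dir.create("results/inputs", showWarnings = FALSE, recursive = TRUE)

sim <- simulate_study(sim_config(seed = seed))

write_sv_vcf(sim$catalog, "results/inputs/sv_catalog.vcf", sim$tracks$genome)
write_snp_vcf(sim$snps, "results/inputs/snps.vcf")
write_gff3(sim$tracks$genes, "results/inputs/genes.gff3")
write_feature_track(sim$tracks$repeats, "results/inputs/repeats.bed")
write_feature_track(sim$tracks$states, "results/inputs/chromatin_states.bed")
write_feature_track(sim$tracks$qtls, "results/inputs/qtls.bed")
write_population_map(sim$pop_map, "results/inputs/populations.tsv")
write_tables(list(ground_truth_impact = sim$truth$impact,
                  ground_truth_specific = sim$truth$specific,
                  ground_truth_qc_failures = sim$truth$qc_fail),
             "results/inputs")

cat(sprintf("seed %d: %d SVs x %d samples, %d genes, %d SNPs\n",
            seed, n_svs(sim$catalog), length(sim$catalog$samples),
            length(sim$tracks$genes), nrow(sim$snps$gt)))
cat(sprintf("planted: %d impact SVs, %d group-specific SVs, %d bad bins, %d QC failures\n",
            nrow(sim$truth$impact), nrow(sim$truth$specific),
            length(sim$tracks$bad_bins$ranges), nrow(sim$truth$qc_fail)))
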