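# svcat

Population-scale structural variant (SV) catalogs — hundreds of genomes,
tens of thousands of deletions (DEL), mobile element insertions (MEI),
duplications (DUP), inversions (INV) and breakends (BND) with per-sample
genotypes — need a characterization pipeline before any biology can be
read off them: evidence-based quality control, functional annotation
against gene models and chromatin tracks, enrichment statistics,
population differentiation, and linkage to functional small variants.
`svcat` implements that pipeline for R users working with VCF/GFF3/BED
inputs, and ships a synthetic-data generator with known ground truth so
every stage is testable end to end without any external download.

## What it computes

**Quality control.** The genome is tiled into 100-bp windows; a window
whose copy number exceeds 10 (five times diploid) in at least 90% of
samples is a *bad bin*, and SVs overlapping bad bins or assembly gaps by
at least 1 bp are removed, as are events under 50 bp. Type-specific
evidence filters follow the standard short-read rules: DEL/MEI need mean
sample quality MSQ > 100 (DELs ≤ 1 kb additionally need split-read
support in ≥ 1 sample), INVs need MSQ > 150 plus ≥ 10% read support,
BNDs need MSQ > 250. DEL/MEI genotypes are maskable per sample, and
samples with > 15% missing genotypes or too few SVs are flagged.

**Annotation.** A DEL becomes an MEI when repeats cover more than 90% of
its length. Each overlapping (SV, gene) pair gets one of 15 impact
categories — whole-gene `WlGnDel`/`WlGnDup`/`WlGnInv`; coding `pLoF`
(DEL/MEI), `CpGn` (DUP), `codInv`, `codBnd`; regulatory `Rglt5`/`Rglt3`;
`intron`; `noncoding` — with strong/weak (`St`/`Wk`) calls at 20% of the
SV's own length. Frequency classes are allele-count based: singleton
(AC = 1), rare (1 < AC ≤ 10), common (AC > 10).

**Statistics.** Fold enrichment of an annotation class in SV space is

```
fold = (class bp in merged SV set / SV bp) / (class bp / genome bp)
```

tested with Pearson's chi-squared (no continuity correction) and
Bonferroni correction; QTLs (≤ 1 Mb) are *enriched* at fold > 2 and
adjusted p < 0.01. Group comparisons use the pooled-variance Student's
t-test; cross-population signals use a one-way ANOVA with a CV > 1 rule.
Pairwise FST is the Weir–Cockerham (1984) θ̂ with the multi-locus
ratio-of-sums ("weighted") estimate alongside, and the top 1% of values
flag candidate differentiated SVs. SV–SNP linkage is dosage r² within
1 Mb, with nested tiers: linked (r² ≥ 0.2), tagged (≥ 0.5),
highly-tagged (≥ 0.8); functional SNPs (e/sQTLs, GWAS loci at
p ≤ 5 × 10⁻⁸) and TWAS genes (FDR ≤ 0.05, also e/sGenes) join SVs in a
network with ±5 kb gene-body extension. Assembly validation matches SV
sets on ≥ 1 bp overlap and scores min/max length consistency.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over the package and writes its tables under `results/`.
Running it at seed 42:

```sh
Rscript analysis/01_simulate.R 42
# seed 42: 309 SVs x 114 samples, 120 genes, 1500 SNPs
# planted: 30 impact SVs, 20 group-specific SVs, 5 bad bins, 14 QC failures

Rscript analysis/02_qc.R 42
#            filter n_input n_removed n_retained
# 1 bad_bin_overlap     309         2        307
# 2     gap_overlap     307         2        305
# 3      min_length     305         2        303
# 4    type_filters     303         8        295
# planted bad bins detected: 5 merged regions

Rscript analysis/05_popgen_ld.R 42
# group-specific SV status:
# AS-specific EU-specific      shared
#          10          12         273
# multi-locus weighted FST (AS vs EU): 0.0681; top-1% threshold: 0.3429 (2 SVs)
# LD tier counts (SV-SNP pairs within 1 Mb):
# highly_tagged        linked          none        tagged
#            27            32         51914            18

Rscript analysis/06_validation.R 42
# validated 183 of 295 SVs: 62.03% by count, 68.79% by length
# 89.1% of best-matched pairs exceed 98% length consistency
```

Reading the numbers: the 14 planted QC failures are exactly the 14
records the filter stack removes (2 + 2 + 2 + 8); the 10 planted
AS-specific SVs are all recovered (the 2 extra EU-specific calls are
background SVs that happen to be carried only by European samples — at
these sample sizes that is expected); FST between the Asian and European
ancestral groups reflects the generator's per-population Balding–Nichols
drift; and the three LD tiers are populated by SNPs coupled to SVs at
fidelities 0.98/0.85/0.60. The same computations are exposed as
functions (`run_qc()`, `classify_catalog()`, `fold_enrichment()`,
`weir_cockerham_fst()`, `ld_r2_window()`, `match_sv_sets()`, …) and the
whole flow as `run_pipeline(sim_config(seed = 42))`, which also scores
recovery of the planted ground truth. The methods vignette
(`vignettes/sv-catalog-characterization.Rmd`) documents the model
choices, conventions and limitations.

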