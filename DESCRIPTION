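Package: svcat
Title: Quality Control, Functional Annotation, and Population Genetics of
    Structural Variant Catalogs
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for characterizing a population-scale structural variant
    (SV) catalog: evidence-based quality control (copy-number "bad bin"
    detection, assembly-gap and minimum-length filters, per-type quality
    filters, per-sample genotype masking), reclassification of deletions as
    mobile element insertions by repeat coverage, a 15-category gene-impact
    classifier with strong/weak calls, interval-overlap enrichment statistics
    against genomic backgrounds (genes, chromatin states, regulatory elements,
    trait QTLs), population differentiation (group-specific SVs and
    Weir-Cockerham FST with top-percentile calls), SV-SNP linkage
    disequilibrium tiers with a functional-variant network, and validation
    against assembly-derived SV sets. A synthetic-data module generates
    multi-population SV and SNP panels under the Balding-Nichols model with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    GenomeInfoDb,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
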