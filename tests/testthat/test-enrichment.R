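test_that("fold enrichment reproduces the defining ratio", {
  genome <- genome_model(c(chr1 = 1e6))
  # feature = 5% of the genome, laid out so 10% of SV bp falls inside it
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50000))
  svs <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(40001, 200001),
                                                 c(50000, 290000)))
  r <- fold_enrichment(svs, feat, genome)
  expect_equal(r$fold, (10000 / 100000) / (50000 / 1e6))  # = 2
  expect_equal(r$fold, 2)

  # feature = whole genome: fold 1, p 1
  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e6))
  r2 <- fold_enrichment(svs, whole, genome)
  expect_equal(r2$fold, 1)
  expect_equal(r2$p, 1)

  expect_error(fold_enrichment(GenomicRanges::GRanges(), feat, genome),
               "empty SV set")
})

test_that("the chi-squared statistic matches the textbook formula", {
  expect_equal(unname(svcat:::pearson_chi2_2x2(100, 900, 50, 950)$statistic),
               unname(oracle_chi2(100, 900, 50, 950)), tolerance = 1e-10)
  set.seed(3)
  for (i in 1:100) {
    cells <- sample(10:2000, 4)
    mine <- svcat:::pearson_chi2_2x2(cells[1], cells[2], cells[3],
                                     cells[4])$statistic
    expect_equal(unname(mine),
                 unname(oracle_chi2(cells[1], cells[2], cells[3], cells[4])),
                 tolerance = 1e-10)
  }
})

test_that("merging makes enrichment invariant to duplicated SV records", {
  genome <- genome_model(c(chr1 = 1e5))
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 5000))
  svs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2000, 30000),
                                                         c(4000, 40000)))
  dup <- c(svs, svs, svs[1])
  expect_equal(fold_enrichment(svs, feat, genome)$fold,
               fold_enrichment(dup, feat, genome)$fold)
})

test_that("bp accounting is consistent with the feature complement", {
  genome <- genome_model(c(chr1 = 1e5))
  feat <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 30999))
  comp <- GenomicRanges::setdiff(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1e5)), feat)
  svs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(500, 50000),
                                                         c(2500, 60000)))
  a <- fold_enrichment(svs, feat, genome)
  b <- fold_enrichment(svs, comp, genome)
  expect_equal(a$feature_bp + b$feature_bp, genome_bp(genome))
  expect_equal(a$bp_in_sv + b$bp_in_sv, a$sv_bp)
})

test_that("genic partition enrichment behaves on constructed layouts", {
  sim <- shared_sim()
  genes <- sim$tracks$genes
  genome <- sim$tracks$genome
  part <- genic_partition(genes, genome)
  # the partition tiles the genome exactly
  expect_equal(reduced_bp(part$ranges), genome_bp(genome))

  # SVs placed only in intergenic space: intergenic fold = 1/fraction
  inter <- track_ranges(part, label = "intergenic")
  big <- inter[GenomicRanges::width(inter) > 5000]
  svs <- GenomicRanges::resize(big[1:20], 2000, fix = "center")
  r <- genic_partition_enrichment(svs, genes, genome)
  inter_frac <- reduced_bp(inter) / genome_bp(genome)
  expect_equal(r$fold[r$label == "intergenic"], 1 / inter_frac,
               tolerance = 1e-6)
  expect_equal(r$bp_in_sv[r$label == "CDS"], 0)
})

test_that("uniformly placed SVs show no genic enrichment signal", {
  sim <- shared_sim()
  set.seed(17)
  genome <- sim$tracks$genome
  start <- sort(sample.int(4.9e6, 1200))
  svs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(start, start + 999))
  r <- genic_partition_enrichment(svs, sim$tracks$genes, genome)
  # folds hover around 1; tiny partitions (UTRs of a few kb) are too noisy
  # for a tight bound, so judge only partitions with enough genomic bp
  big <- r$feature_bp >= 5e4
  expect_true(any(big))
  expect_true(all(abs(r$fold[big] - 1) < 0.35))
})

test_that("singleton-proportion t-tests flag only shifted categories", {
  set.seed(7)
  n <- 50
  mk <- function(cat, mu, sd = 0.02)
    data.frame(sample_id = paste0("S", 1:n), category = cat,
               n_carried = 10, singleton_prop = pmin(1, pmax(0,
                 rnorm(n, mu, sd))))
  summaries <- rbind(mk("intergenic", 0.3), mk("same", 0.3),
                     mk("shifted", 0.6))
  r <- singleton_proportion_tests(summaries)
  expect_false(r$significant[r$category == "same"])
  expect_true(r$significant[r$category == "shifted"])
  # the t statistic matches stats::t.test (pooled)
  tt <- t.test(summaries$singleton_prop[summaries$category == "shifted"],
               summaries$singleton_prop[summaries$category == "intergenic"],
               var.equal = TRUE)
  expect_equal(r$t[r$category == "shifted"], unname(tt$statistic))

  # identical constant distributions -> undefined test, never significant
  same <- rbind(mk("intergenic", 0.3, 0), mk("flat", 0.3, 0))
  r2 <- singleton_proportion_tests(same)
  expect_false(isTRUE(r2$significant[r2$category == "flat"]))
  expect_false(r2$defined[r2$category == "flat"])

  # one sample only -> undefined, flagged
  one <- rbind(mk("intergenic", 0.3), mk("tiny", 0.4)[1, ])
  r3 <- singleton_proportion_tests(one)
  expect_false(r3$defined[r3$category == "tiny"])
})

test_that("chromatin-state proportions match a per-base oracle", {
  states <- feature_track("st", rep("chr1", 4),
                          c(1, 1001, 2001, 3001), c(1000, 2000, 3000, 4000),
                          c("EnhA", "Qui", "EnhA", "Qui"),
                          tissue = c("t1", "t1", "t2", "t2"))
  svs <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  r <- chromatin_state_overlap(states, svs)
  p <- r$proportions
  expect_equal(p$proportion[p$tissue == "t1" & p$state == "EnhA"], 1.0)
  expect_equal(p$proportion[p$tissue == "t2" & p$state == "EnhA"], 0.0)

  # random layout equals brute force
  sim <- shared_sim()
  svs2 <- sv_ranges(sim$catalog)[1:50]
  st <- sim$tracks$states
  r2 <- chromatin_state_overlap(st, svs2)
  k <- which(r2$proportions$state == "TssA" &
               r2$proportions$tissue == "tissue1")
  gr <- track_ranges(st, label = "TssA", tissue = "tissue1")
  num <- sum(vapply(seq_along(gr), function(i)
    oracle_overlap_bp(as.character(GenomeInfoDb::seqnames(gr))[i],
                      GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i],
                      GenomicRanges::reduce(svs2)), 0))
  expect_equal(r2$proportions$proportion[k], num / reduced_bp(gr))
})

test_that("regulator location ratios hit the boundary cases", {
  sim <- shared_sim()
  genes <- sim$tracks$genes
  els <- sim$tracks$enhancers
  # all elements overlapped -> ratio 1 everywhere
  r1 <- regulator_location_ratios(els, els$ranges, genes)
  expect_true(all(r1$ratios$ratio == 1))
  # no overlap (SVs on a chromosome the track never touches) -> 0
  far <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10))
  r0 <- suppressWarnings(regulator_location_ratios(els, far, genes))
  expect_true(all(r0$ratios$ratio == 0))
  # mixed case matches direct enumeration
  svs <- sv_ranges(sim$catalog)[1:80]
  r <- regulator_location_ratios(els, svs, genes)
  total_in <- sum(GenomicRanges::countOverlaps(
    els$ranges, GenomicRanges::reduce(svs)) > 0)
  expect_equal(sum(r$ratios$n_in_sv), total_in)
  expect_equal(sum(r$ratios$n_total), length(els$ranges))
})

test_that("QTL enrichment drops >1 Mb intervals and applies the 2x rule", {
  genome <- genome_model(c(chr1 = 1e7))
  qtls <- feature_track("q", rep("chr1", 4),
                        c(1, 2e6, 4e6, 6e6),
                        c(1.2e6, 2e6 + 5e5 - 1, 4e6 + 1e4 - 1, 6e6 + 1e4 - 1),
                        c("tA", "tA", "tB", "tC"))
  # trait tB fully tiled by SVs; genome is ~1% SV
  svs <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(4e6, 8e6),
                                                 c(4e6 + 1e4 - 1, 8e6 + 9e4)))
  r <- qtl_enrichment(qtls, svs, genome)
  expect_equal(r$n_qtl_kept, 3L)          # the 1.2 Mb QTL is excluded
  ptB <- r$per_trait[r$per_trait$label == "tB", ]
  sv_frac <- reduced_bp(GenomicRanges::reduce(svs)) / 1e7
  expect_equal(ptB$fold, 1 / sv_frac)     # fully covered trait
  expect_true(ptB$significant)
  # overlap tallies by hand: tA's kept QTL and tC have no overlap
  expect_equal(r$tallies$n_qtl_overlapped, 1L)
  expect_equal(r$tallies$frac_trait_overlapped, 1 / 3)
})

test_that("cross-population ANOVA flags shifted traits with CV > 1", {
  pops <- rep(c("ASD", "EUC", "EUD"), each = 10)
  pm <- population_map(paste0("S", 1:30), pops)
  set.seed(21)
  base <- data.frame(sample_id = paste0("S", 1:30), trait = "flat",
                     log2_fold = rnorm(30, 1, 0.1))
  shifted <- data.frame(sample_id = paste0("S", 1:30), trait = "shift",
                        log2_fold = c(rnorm(10, 0.05, 0.05),
                                      rnorm(10, 2, 0.05),
                                      rnorm(10, 0.05, 0.05)))
  r <- population_anova(rbind(base, shifted), pm)
  expect_false(r$reported[r$trait == "flat"])
  expect_true(r$reported[r$trait == "shift"])
  # F statistic equals stats::aov on the same data
  dd <- shifted; dd$population <- pops
  ref <- summary(aov(log2_fold ~ population, data = dd))[[1]]
  expect_equal(r$f[r$trait == "shift"], ref$`F value`[1])

  # all groups identical -> p = 1, CV = 0
  const <- data.frame(sample_id = paste0("S", 1:30), trait = "const",
                      log2_fold = 1)
  r2 <- population_anova(const, pm)
  expect_equal(r2$p, 1)
  expect_equal(r2$cv, 0)

  # fewer than two groups is an error
  pm1 <- population_map(paste0("S", 1:30), rep("ASD", 30))
  expect_error(population_anova(base, pm1), "2 populations")
})

test_that("per-individual QTL folds are finite and respond to carriage", {
  sim <- shared_sim()
  qtls <- sim$tracks$qtls
  folds <- qtl_individual_fold(sim$catalog, qtls, sim$tracks$genome)
  expect_true(all(is.finite(folds$log2_fold)))
  expect_equal(sort(unique(folds$trait)),
               sort(unique(S4Vectors::mcols(qtls$ranges)$label)))
})
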