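toy_gene <- function(gene_id = "g1", chrom = "chr1", strand = "+",
                     biotype = "protein_coding") {
  # exon1 2001-2400 (UTR5 2001-2100, CDS 2101-2400), exon2 3001-3400 (CDS),
  # exon3 4001-4400 (CDS 4001-4300, UTR3 4301-4400)
  gene_model(gene_id, chrom, strand, biotype, list(
    t1 = list(exons = data.frame(start = c(2001, 3001, 4001),
                                 end = c(2400, 3400, 4400)),
              cds = data.frame(start = c(2101, 3001, 4001),
                               end = c(2400, 3400, 4300)),
              utr5 = data.frame(start = 2001, end = 2100),
              utr3 = data.frame(start = 4301, end = 4400))))
}

test_that("DEL-to-MEI reclassification requires strictly >90% repeat cover", {
  mk <- function(rep_ranges) feature_track("rep",
                                           rep("chr1", length(rep_ranges$s)),
                                           rep_ranges$s, rep_ranges$e,
                                           rep("SINE", length(rep_ranges$s)))
  cat0 <- make_catalog(data.frame(chrom = "chr1", start = 1001, end = 1300,
                                  svtype = "DEL"))
  # 280 of 300 bp covered (93.3%) -> MEI
  r1 <- reclassify_del_to_mei(cat0, mk(list(s = 1010, e = 1289)))
  expect_equal(r1$variants$svtype, "MEI")
  # exactly 270 of 300 (90.0%) -> stays DEL (strict >)
  r2 <- reclassify_del_to_mei(cat0, mk(list(s = 1016, e = 1285)))
  expect_equal(r2$variants$svtype, "DEL")
  # two overlapping repeats whose union covers 95% -> MEI, and the union
  # equals a per-base oracle
  track <- mk(list(s = c(1001, 1100), e = c(1200, 1285)))
  covered <- oracle_overlap_bp("chr1", 1001, 1300, track$ranges)
  expect_equal(covered, 285)
  r3 <- reclassify_del_to_mei(cat0, track)
  expect_equal(r3$variants$svtype, "MEI")
  # coordinates never change
  expect_equal(r3$variants$start, cat0$variants$start)
  expect_equal(r3$variants$end, cat0$variants$end)
})

test_that("single-gene classification follows the category precedence", {
  g <- toy_gene()
  cls <- function(start, end, svtype)
    classify_sv_gene(list(chrom = "chr1", start = start, end = end,
                          svtype = svtype, length = end - start + 1), g)
  # DEL engulfing the whole gene body
  expect_equal(cls(1500, 5000, "DEL")$category, "WlGnDel")
  expect_equal(cls(1500, 5000, "DUP")$category, "WlGnDup")
  expect_equal(cls(1500, 5000, "INV")$category, "WlGnInv")
  # fractions agree with the per-base oracle
  r <- cls(2251, 3250, "DEL")
  expect_equal(oracle_overlap_bp("chr1", 2251, 3250,
                                 GenomicRanges::GRanges("chr1", g$cds)), 400)
  expect_equal(unname(r$cds_fraction), 0.4)
  expect_equal(r$category, "pLoF_St")
  # DEL fully inside CDS
  expect_equal(cls(2151, 2250, "DEL")$category, "pLoF_St")
  # 950 bp DEL overlapping only 50 bp of CDS (5.3%) -> weak pLoF
  r_wk <- cls(2101 - 900, 2150, "DEL")
  expect_lt(r_wk$cds_fraction, 0.2)
  expect_equal(r_wk$category, "pLoF_Wk")
  # 1000 bp DUP overlapping 250 bp of CDS (25%) -> strong copy gain
  r_dup <- classify_sv_gene(list(chrom = "chr1", start = 2851, end = 3850,
                                 svtype = "DUP", length = 1000), g)
  expect_equal(unname(r_dup$cds_fraction), 0.4)
  expect_equal(r_dup$category, "CpGn_St")
  # MEI fully inside the 3'UTR -> strong 3' regulatory
  r_mei <- cls(4310, 4390, "MEI")
  expect_equal(r_mei$category, "Rglt3_St")
  expect_equal(unname(r_mei$utr3_fraction), 1)
  # DEL entirely within one intron
  expect_equal(cls(2500, 2700, "DEL")$category, "intron")
  # INV/BND in CDS carry no strong/weak suffix
  expect_equal(cls(3001, 3100, "INV")$category, "codInv")
  expect_equal(cls(3001, 3100, "BND")$category, "codBnd")
})

test_that("the 20% strong/weak boundary is inclusive for strong", {
  g <- toy_gene()
  # SV of 500 bp with exactly 100 bp CDS overlap = 20% -> strong
  r <- classify_sv_gene(list(chrom = "chr1", start = 2601, end = 3100,
                             svtype = "DEL", length = 500), g)
  expect_equal(unname(r$cds_fraction), 0.2)
  expect_equal(r$category, "pLoF_St")
})

test_that("classification is invariant to transcript ordering", {
  tx <- list(
    t1 = list(exons = data.frame(start = c(100, 500), end = c(200, 700)),
              cds = data.frame(start = c(150, 500), end = c(200, 650)),
              utr5 = data.frame(start = 100, end = 149),
              utr3 = data.frame(start = 651, end = 700)),
    t2 = list(exons = data.frame(start = 100, end = 200),
              cds = data.frame(start = 150, end = 200),
              utr5 = data.frame(start = 100, end = 149),
              utr3 = NULL))
  g1 <- gene_model("g", "chr1", "+", "protein_coding", tx)
  g2 <- gene_model("g", "chr1", "+", "protein_coding", rev(tx))
  sv <- list(chrom = "chr1", start = 120, end = 620, svtype = "DEL",
             length = 501)
  expect_identical(classify_sv_gene(sv, g1), classify_sv_gene(sv, g2))
})

test_that("catalog classification emits one call per (SV, gene) pair", {
  g1 <- toy_gene("gA")
  g2 <- gene_model("gB", "chr1", "+", "protein_coding", list(
    t1 = list(exons = data.frame(start = c(6001, 7001), end = c(6400, 7400)),
              cds = data.frame(start = c(6001, 7001), end = c(6400, 7400)))))
  genes <- gene_model_set(list(g1, g2))
  cat0 <- make_catalog(data.frame(chrom = "chr1",
                                  start = c(4350, 9000),
                                  end = c(6200, 9400),
                                  svtype = c("DEL", "DEL")))
  calls <- classify_catalog(cat0, genes)
  sv1 <- calls[calls$sv_id == cat0$variants$id[1], ]
  expect_equal(nrow(sv1), 2L)          # hits both genes
  expect_setequal(sv1$gene_id, c("gA", "gB"))
  expect_true("intergenic" %in% calls$category[calls$sv_id ==
                                                 cat0$variants$id[2]])
  cc <- category_counts(calls)
  expect_equal(sum(cc$n_sv[cc$category == "intergenic"]), 1L)

  # empty gene set: everything intergenic
  calls0 <- classify_catalog(cat0, gene_model_set(list()))
  expect_true(all(calls0$category == "intergenic"))
})

test_that("classifier equals the per-base oracle on a seeded simulation", {
  sim <- shared_sim()
  set.seed(99)
  idx <- sample(n_svs(sim$catalog), 120)
  cat0 <- subset_svs(sim$catalog, sort(idx))
  calls <- classify_catalog(cat0, sim$tracks$genes)
  v <- cat0$variants
  for (k in seq_len(nrow(calls))) {
    if (calls$category[k] == "intergenic") next
    g <- sim$tracks$genes$genes[[calls$gene_id[k]]]
    i <- match(calls$sv_id[k], v$id)
    expect_equal(calls$category[k], oracle_classify(v[i, ], g),
                 info = paste(calls$sv_id[k], calls$gene_id[k]))
  }
})

test_that("frequency classes split at AC = 1, 10, 11", {
  fc <- frequency_class(c(1, 10, 11, 0, 2), 100)
  expect_identical(fc$class, c("singleton", "rare", "common", "absent", "rare"))
  expect_equal(fc$af, c(1, 10, 11, 0, 2) / 200)
  # partition: classes cover the whole catalog
  sim <- shared_sim()
  ac <- allele_counts(sim$catalog)
  fc2 <- frequency_class(ac$ac, ac$an / 2)
  expect_equal(sum(table(fc2$class)), n_svs(sim$catalog))
  expect_equal(sum(fc2$class == "singleton"), sum(ac$ac == 1))
})

test_that("regulator relation distinguishes overlapped/flanking/none", {
  sv <- list(chrom = "chr1", start = 10000, end = 20000)
  els <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(15000, 23000, 26001, 4999),
                                                 c(15400, 23400, 26400, 5300)))
  rel <- regulator_relation(sv, els)
  expect_identical(rel, c("overlapped", "flanking", "none", "flanking"))
  # overlapped takes precedence over flanking
  el2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(19990, 21000))
  expect_identical(regulator_relation(sv, el2), "overlapped")
})
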