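test_that("SV identifiers parse with inclusive-coordinate lengths", {
  cases <- list(
    list(id = "1:119154722-119155024:DEL", len = 303),
    list(id = "8:130924619–130980283:DUP", len = 55665),  # en-dash
    list(id = "2:9513511-9513561:DEL", len = 51),
    list(id = "1:100-100:DEL", len = 1))
  for (cs in cases) {
    p <- parse_sv_identifier(cs$id)
    expect_equal(p$length, cs$len, info = cs$id)
    expect_equal(p$end - p$start + 1, cs$len)
  }
  expect_error(parse_sv_identifier("1:100-200"), "malformed")
  expect_error(parse_sv_identifier("1:100-200:FOO"), "FOO")
  expect_error(parse_sv_identifier("1:300-200:DEL"), "start > end")
})

test_that("identifier parse/serialize round trip holds for all SV types", {
  for (svt in SV_TYPES) {
    id <- sv_id("chr2", 1234, 9876, svt)
    p <- parse_sv_identifier(id)
    expect_identical(sv_id(p$chrom, p$start, p$end, p$svtype), id)
    if (svt != "BND") expect_equal(p$length, 9876 - 1234 + 1)
    else expect_equal(p$length, 9876 - 1234)
  }
})

test_that("genome model validates gap intervals against chromosome bounds", {
  g <- genome_model(c(chr1 = 1000, chr2 = 2000),
                    data.frame(chrom = "chr1", start = 10, end = 20))
  expect_equal(genome_bp(g), 3000)
  expect_error(genome_model(c(chr1 = 1000),
                            data.frame(chrom = "chr1", start = 990, end = 1010)),
               "bounds")
  expect_error(genome_model(c(chr1 = 1000),
                            data.frame(chrom = "chrX", start = 1, end = 5)),
               "unknown")
  expect_error(genome_model(c(chr1 = -5)), "> 0")
})

test_that("BED input converts to 1-based inclusive and back losslessly", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100\tSINE", bed)
  tr <- read_feature_track(bed, "repeats")
  expect_equal(GenomicRanges::start(tr$ranges), 1)
  expect_equal(GenomicRanges::end(tr$ranges), 100)
  out <- tempfile(fileext = ".bed")
  write_feature_track(tr, out)
  tr2 <- read_feature_track(out, "repeats")
  expect_equal(GenomicRanges::start(tr2$ranges), 1)
  expect_equal(GenomicRanges::end(tr2$ranges), 100)
  expect_identical(S4Vectors::mcols(tr2$ranges)$label, "SINE")
})

test_that("feature tracks reject out-of-vocabulary labels naming offenders", {
  expect_error(feature_track("t", "chr1", 1, 10, "WEIRD",
                             vocabulary = c("SINE", "LINE")),
               "WEIRD")
})

test_that("SV VCF write/read round trip is identity for all five types", {
  sim <- shared_sim()
  idx <- unlist(lapply(SV_TYPES, function(t)
    utils::head(which(sim$catalog$variants$svtype == t), 2)))
  cat0 <- subset_svs(sim$catalog, idx)
  path <- tempfile(fileext = ".vcf")
  write_sv_vcf(cat0, path, sim$tracks$genome)
  cat1 <- read_sv_vcf(path)
  expect_identical(cat1$variants$id, cat0$variants$id)
  expect_identical(cat1$variants$svtype, cat0$variants$svtype)
  expect_equal(cat1$variants$start, cat0$variants$start)
  expect_equal(cat1$variants$end, cat0$variants$end)
  expect_equal(cat1$variants$msq, cat0$variants$msq, tolerance = 1e-6)
  expect_identical(unname(cat1$genotypes), unname(cat0$genotypes))
  expect_equal(unname(cat1$sr_support), unname(cat0$sr_support))
  expect_equal(unname(cat1$allele_balance), unname(cat0$allele_balance),
               tolerance = 1e-5)
})

test_that("a DEL with END = POS + 302 has length 303 and matches its id", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t119154722\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=119155024\tGT\t0/1",
               "1\t500\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=600\tGT\t./."),
             vcf)
  cat1 <- read_sv_vcf(vcf)
  expect_equal(cat1$variants$length[1], 303)
  p <- parse_sv_identifier(cat1$variants$id[1])
  expect_equal(p$length, 303)
  # dosage conventions
  expect_identical(unname(cat1$genotypes[, 1]), c(1L, NA_integer_))
})

test_that("inconsistent END/SVLEN and missing SVTYPE are handled", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"l\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=199;SVLEN=50\tGT\t0/1"),
             vcf)
  expect_error(read_sv_vcf(vcf), "inconsistent")
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=END,Number=1,Type=Integer,Description=\"e\">",
               "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
               "1\t100\t.\tN\t<DEL>\t.\tPASS\tEND=199\tGT\t0/1",
               "1\t300\t.\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=400\tGT\t0/1"),
             vcf)
  expect_message(cat1 <- read_sv_vcf(vcf), "without SVTYPE")
  expect_equal(nrow(cat1$variants), 1L)
})

test_that("gene models read from GFF3 apply the retired/unplaced filter", {
  sim <- shared_sim()
  sub <- gene_model_set(sim$tracks$genes$genes[1:5])
  gff <- tempfile(fileext = ".gff3")
  write_gff3(sub, gff)
  ids <- names(sub$genes)
  gm <- read_gene_models(gff, retired_ids = ids[1],
                         placed_chroms = "chr1")
  unplaced <- sum(vapply(sub$genes[-1], function(g) g$chrom != "chr1", TRUE))
  fc <- attr(gm, "filter_counts")
  expect_equal(unname(fc["total"]), 5L)
  expect_equal(unname(fc["retired"]), 1L)
  expect_equal(unname(fc["retained"]), 4L - unplaced)
  # round trip of structure for a retained gene
  gid <- names(gm$genes)[1]
  expect_equal(as.data.frame(gm$genes[[gid]]$cds),
               as.data.frame(sub$genes[[gid]]$cds))
  expect_equal(gm$genes[[gid]]$biotype, sub$genes[[gid]]$biotype)
})

test_that("the printed gene-filter arithmetic reproduces the retained total", {
  expect_equal(31908 - 934 - 1448, 29526)
})

test_that("empty GFF yields an empty model set with a warning", {
  gff <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", gff)
  expect_warning(gm <- read_gene_models(gff), "empty")
  expect_equal(length(gm), 0L)
})

test_that("population map round-trips and checks roster coverage", {
  pm <- population_map(c("a", "b", "c"), c("ASW", "EUC", "OTG"))
  expect_identical(pm$ancestral, c("AS", "EU", "other"))
  path <- tempfile(fileext = ".tsv")
  write_population_map(pm, path)
  pm2 <- read_population_map(path, samples = c("a", "b", "c"))
  expect_identical(pm2$population, pm$population)
  expect_error(read_population_map(path, samples = c("a", "zzz")), "zzz")
  expect_error(population_map("a", "XX"), "unknown")
})

test_that("invalid gene models (CDS outside exons) are excluded", {
  expect_error(gene_model("g1", "chr1", "+", "protein_coding",
                          list(t1 = list(exons = data.frame(start = 1, end = 100),
                                         cds = data.frame(start = 90, end = 150)))),
               "CDS outside")
})
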