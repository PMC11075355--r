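make_cn <- function(cn_values, window = 100L) {
  n <- nrow(cn_values)
  g <- genome_model(c(chr1 = n * window))
  cn_window_matrix(tile_genome(g, window), cn_values, window)
}

test_that("bad-bin detection uses strict CN > 10 in >= ceil(0.9 n) samples", {
  cn <- matrix(2, 5, 10)
  cn[3, 1:9] <- 12                       # 9 of 10 samples: flagged
  cn[4, ] <- 10.0                        # exactly 10 everywhere: not flagged
  bb <- detect_bad_bins(make_cn(cn), merge = FALSE)
  expect_equal(GenomicRanges::start(bb$ranges), 201)
  expect_equal(GenomicRanges::end(bb$ranges), 300)

  cn[3, 9] <- 2                          # only 8 of 10: below ceil(0.9*10)
  expect_length(detect_bad_bins(make_cn(cn))$ranges, 0L)
})

test_that("diploid background copy number yields zero flagged windows", {
  set.seed(11)
  cn <- matrix(rnorm(200 * 8, 2, 0.3), 200, 8)
  bb <- detect_bad_bins(make_cn(cn), merge = FALSE)
  # brute-force scan over all windows
  expected <- which(apply(cn, 1, function(x) sum(x > 10) >= ceiling(0.9 * 8)))
  expect_length(bb$ranges, length(expected))
  expect_length(expected, 0L)
})

test_that("bad-bin and gap overlap filters use >= 1 bp semantics", {
  cat0 <- make_catalog(data.frame(chrom = "chr1",
                                  start = c(150, 90, 301),
                                  end = c(250, 199, 400),
                                  svtype = "DEL"))
  bins <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
  res <- filter_bad_bin_overlap(cat0, bins)
  # spans the window -> removed; ends 1 bp before (199) and starts 1 bp
  # after (301) -> retained
  expect_setequal(res$catalog$variants$start, c(90, 301))
  expect_equal(res$report$n_removed + res$report$n_retained,
               res$report$n_input)

  genome <- genome_model(c(chr1 = 10000),
                         data.frame(chrom = "chr1", start = 200, end = 300))
  res2 <- filter_gap_overlap(cat0, genome)
  expect_setequal(res2$catalog$variants$start, c(90, 301))
})

test_that("random SVs against planted bins match a per-base oracle", {
  set.seed(5)
  start <- sample.int(9000, 20)
  cat0 <- make_catalog(data.frame(chrom = "chr1", start = start,
                                  end = start + sample(50:400, 20, TRUE),
                                  svtype = "DEL"))
  bins <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(1000, 4000, 7000),
                                                  c(1300, 4300, 7300)))
  res <- filter_bad_bin_overlap(cat0, bins)
  v <- cat0$variants
  keep_oracle <- vapply(seq_len(nrow(v)), function(i)
    oracle_overlap_bp(v$chrom[i], v$start[i], v$end[i], bins) == 0, TRUE)
  expect_setequal(res$catalog$variants$id, v$id[keep_oracle])
})

test_that("minimum-length rule removes 49 bp and keeps 50 bp events", {
  lens <- c(49, 50, 51, 30, 500, 49, 1000)
  cat0 <- make_catalog(data.frame(chrom = "chr1",
                                  start = seq(1, by = 2000, length.out = 7),
                                  end = seq(1, by = 2000, length.out = 7) +
                                    lens - 1,
                                  svtype = "DEL"))
  res <- filter_min_length(cat0)
  expect_equal(res$report$n_removed, sum(lens < 50))
  expect_setequal(res$catalog$variants$length, lens[lens >= 50])
})

test_that("type-specific evidence filters follow the strict thresholds", {
  df <- data.frame(chrom = "chr1",
                   start = c(1000, 5000, 9000, 13000, 17000, 21000),
                   end = c(1799, 5799, 29000, 13599, 27000, 22000),
                   svtype = c("DEL", "DEL", "INV", "MEI", "BND", "DUP"),
                   msq = c(120, 101, 151, 100, 250, NA))
  gt <- matrix(1L, 6, 3, dimnames = list(NULL, c("A", "B", "C")))
  sr <- matrix(0L, 6, 3); sr[2, 2] <- 3L
  ab <- matrix(0.12, 6, 3)
  cat0 <- sv_catalog(df, gt, sr_support = sr, allele_balance = ab)
  res <- apply_type_filters(cat0)
  kept <- res$catalog$variants$svtype
  # DEL 800bp MSQ 120 SR 0 -> removed (small DEL rule)
  # DEL 800bp MSQ 101 with SR in one sample -> retained
  # INV MSQ 151 support 0.12 -> retained
  # MEI MSQ exactly 100 -> removed (strict >)
  # BND MSQ exactly 250 -> removed (strict >)
  # DUP untouched (even with missing MSQ)
  expect_setequal(kept, c("DEL", "INV", "DUP"))
  expect_equal(res$report$n_removed, 3)
})

test_that("genotype masking hits only the flagged samples/records", {
  df <- data.frame(chrom = "chr1", start = c(100, 5000), end = c(219, 5999),
                   svtype = c("DEL", "DEL"), min_size_95 = c(150, NA))
  gt <- matrix(1L, 2, 3, dimnames = list(NULL, c("A", "B", "C")))
  cat0 <- sv_catalog(df, gt)
  # record 1 shorter (120) than its 95%-confidence minimum size (150)
  m1 <- mask_sample_genotypes(cat0)
  expect_true(all(is.na(m1$genotypes[1, ])))
  expect_true(all(!is.na(m1$genotypes[2, ])))

  flags <- matrix(TRUE, 2, 3); flags[2, 2] <- FALSE
  m2 <- mask_sample_genotypes(cat0, capture_flags = flags,
                              use_min_size = FALSE)
  expect_true(is.na(m2$genotypes[2, 2]))
  expect_false(anyNA(m2$genotypes[2, c(1, 3)]))

  cat_plain <- sv_catalog(df[, 1:4], gt)
  expect_warning(m3 <- mask_sample_genotypes(cat_plain), "unchanged")
  expect_identical(m3$genotypes, cat_plain$genotypes)
})

test_that("allele balance is ALT/(ALT+REF) with (0,0) undefined", {
  expect_equal(allele_balance(5, 5), 0.5)
  expect_equal(allele_balance(0, 7), 0)
  expect_true(is.na(allele_balance(0, 0)))
  expect_equal(allele_balance(c(5, 0, 0), c(5, 7, 0)), c(0.5, 0, NA))
})

test_that("sample-level filters exclude on >15% missing or low SV count", {
  gt <- matrix(1L, 100, 4, dimnames = list(NULL, c("ok", "edge", "miss", "few")))
  gt[1:16, "miss"] <- NA         # 16% missing
  gt[1:15, "edge"] <- NA         # exactly 15% -> retained
  gt[, "few"] <- 0L              # carries nothing
  cat0 <- make_catalog(data.frame(chrom = "chr1",
                                  start = seq(1, by = 3000, length.out = 100),
                                  end = seq(1, by = 3000, length.out = 100) + 99,
                                  svtype = "DEL"),
                       gt = gt)
  res <- sample_level_filters(cat0, min_sv_count = 50)
  expect_identical(res$excluded, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(res$reason[3], "missing_rate")
  expect_identical(res$reason[4], "sv_count")
})

test_that("each filter is idempotent and order-insensitive as a set", {
  sim <- shared_sim()
  cat0 <- sim$catalog
  genome <- sim$tracks$genome
  bins <- sim$tracks$bad_bins

  f1 <- filter_min_length(cat0)$catalog
  expect_identical(filter_min_length(f1)$catalog$variants$id, f1$variants$id)
  f2 <- apply_type_filters(cat0)$catalog
  expect_identical(apply_type_filters(f2)$catalog$variants$id, f2$variants$id)
  f3 <- filter_gap_overlap(cat0, genome)$catalog
  expect_identical(filter_gap_overlap(f3, genome)$catalog$variants$id,
                   f3$variants$id)

  # reordering the catalog leaves the retained set unchanged
  set.seed(1)
  perm <- sample(n_svs(cat0))
  shuffled <- subset_svs(cat0, perm)
  a <- filter_bad_bin_overlap(cat0, bins)$catalog$variants$id
  b <- filter_bad_bin_overlap(shuffled, bins)$catalog$variants$id
  expect_setequal(a, b)
})

test_that("the full QC stack equals a record-by-record brute-force pass", {
  sim <- shared_sim()
  bb <- detect_bad_bins(sim$cn)
  res <- run_qc(sim$catalog, sim$tracks$genome, bb)
  keep <- oracle_qc_keep(sim$catalog, bb$ranges, sim$tracks$genome$gaps)
  expect_setequal(res$catalog$variants$id, sim$catalog$variants$id[keep])
  # tallies are conserved per filter
  expect_true(all(res$report$n_removed + res$report$n_retained ==
                    res$report$n_input))
})
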