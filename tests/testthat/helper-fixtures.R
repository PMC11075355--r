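# Shared fixtures and independent brute-force oracles. The oracles work on
# explicit base positions (integer sets) or plain arithmetic, never through
# the interval machinery they are checking.

# memoized default synthetic study so expensive fixtures build once per run
.fixture_env <- new.env(parent = emptyenv())
shared_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_study(sim_config(seed = seed))
  .fixture_env[[key]]
}
shared_pipeline <- function(seed = 42) {
  key <- paste0("pipe", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_pipeline(sim_config(seed = seed))
  .fixture_env[[key]]
}

# tiny catalog builder
make_catalog <- function(df, n_samples = 4, gt = NULL, ...) {
  if (is.null(df$id))
    df$id <- sv_id(df$chrom, df$start, df$end, df$svtype)
  if (is.null(gt))
    gt <- matrix(1L, nrow(df), n_samples,
                 dimnames = list(df$id, paste0("S", seq_len(n_samples))))
  sv_catalog(df, gt, colnames(gt), ...)
}

# integer base positions covered by an IRanges
ir_bases <- function(ir) {
  if (length(ir) == 0L) return(integer())
  unlist(lapply(seq_along(ir), function(i)
    seq.int(IRanges::start(ir)[i], IRanges::end(ir)[i])))
}

gr_bases <- function(gr, chrom) {
  gr <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chrom]
  if (length(gr) == 0L) return(integer())
  unique(unlist(lapply(seq_along(gr), function(i)
    seq.int(GenomicRanges::start(gr)[i], GenomicRanges::end(gr)[i]))))
}

# per-base reimplementation of the category rules, straight from their
# written definitions (used to check the interval-based classifier)
oracle_classify <- function(sv, gene, strong = 0.2) {
  if (!identical(as.character(sv$chrom), gene$chrom)) return(NULL)
  if (sv$end < gene$body_start || sv$start > gene$body_end) return(NULL)
  svb <- seq.int(sv$start, sv$end)
  sv_len <- length(svb)
  cds_ov <- length(intersect(svb, ir_bases(gene$cds)))
  utr5_ov <- length(intersect(svb, ir_bases(gene$utr5)))
  utr3_ov <- length(intersect(svb, ir_bases(gene$utr3)))
  engulfs <- sv$start <= gene$body_start && sv$end >= gene$body_end
  if (engulfs && sv$svtype %in% c("DEL", "DUP", "INV"))
    return(c(DEL = "WlGnDel", DUP = "WlGnDup", INV = "WlGnInv")[[sv$svtype]])
  if (cds_ov > 0) {
    base <- c(DEL = "pLoF", MEI = "pLoF", DUP = "CpGn", INV = "codInv",
              BND = "codBnd")[[sv$svtype]]
    if (base %in% c("codInv", "codBnd")) return(base)
    return(paste0(base, if (cds_ov / sv_len >= strong) "_St" else "_Wk"))
  }
  if (utr5_ov > 0 || utr3_ov > 0) {
    side <- if (utr5_ov >= utr3_ov) "5" else "3"
    frac <- max(utr5_ov, utr3_ov) / sv_len
    if (side == "3") frac <- utr3_ov / sv_len
    if (side == "5") frac <- utr5_ov / sv_len
    return(paste0("Rglt", side, if (frac >= strong) "_St" else "_Wk"))
  }
  exon_ov <- length(intersect(svb, ir_bases(gene$exons)))
  if (exon_ov > 0 && gene$biotype != "protein_coding") return("noncoding")
  "intron"
}

# brute-force per-base bp overlap between an interval and a GRanges
oracle_overlap_bp <- function(chrom, start, end, gr) {
  length(intersect(seq.int(start, end), gr_bases(gr, chrom)))
}

# textbook Pearson chi-squared for a 2x2 table, via stats::chisq.test
oracle_chi2 <- function(a, b, c, d) {
  suppressWarnings(stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                                     correct = FALSE)$statistic)
}

# simple record-by-record QC reference (plain loops, no interval machinery)
oracle_qc_keep <- function(catalog, bad_bins, gaps, min_len = 50) {
  v <- catalog$variants
  keep <- logical(nrow(v))
  for (i in seq_len(nrow(v))) {
    ok <- TRUE
    for (gr in list(bad_bins, gaps)) {
      g <- gr[as.character(GenomeInfoDb::seqnames(gr)) == v$chrom[i]]
      if (length(g) && any(GenomicRanges::start(g) <= v$end[i] &
                           GenomicRanges::end(g) >= v$start[i]))
        ok <- FALSE
    }
    if (ok && !is.na(v$length[i]) && v$length[i] < min_len) ok <- FALSE
    if (ok) {
      msq <- v$msq[i]; svt <- v$svtype[i]
      if (svt %in% c("DEL", "MEI") && (is.na(msq) || msq <= 100)) ok <- FALSE
      if (ok && svt == "DEL" && v$length[i] <= 1000 &&
          !any(catalog$sr_support[i, ] >= 1, na.rm = TRUE)) ok <- FALSE
      if (svt == "INV") {
        carriers <- !is.na(catalog$genotypes[i, ]) & catalog$genotypes[i, ] >= 1
        mab <- mean(catalog$allele_balance[i, carriers], na.rm = TRUE)
        if (is.na(msq) || msq <= 150 || is.nan(mab) || mab < 0.10) ok <- FALSE
      }
      if (svt == "BND" && (is.na(msq) || msq <= 250)) ok <- FALSE
    }
    keep[i] <- ok
  }
  keep
}
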