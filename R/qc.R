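# Catalog quality control: bad-bin detection from windowed copy number,
# gap-overlap removal, minimum-length rule, type-specific evidence filters,
# and per-sample genotype masking. Threshold comparisons follow the catalog
# conventions literally: CN "> 10" strict, MSQ "> 100/150/250" strict,
# "<= 1000 bp" inclusive, "smaller than 50 bp" strict.

#' Windowed copy-number matrix
#'
#' The genome tiled into fixed-size windows (default 100 bp) with a per-sample
#' copy-number value per window.
#' @param windows `GRanges` of non-overlapping, uniformly sized windows.
#' @param cn Numeric matrix (windows x samples) of copy-number values.
#' @param window_size Window width in bp.
#' @return Object of class `cn_window_matrix`.
#' @export
cn_window_matrix <- function(windows, cn, window_size = 100L) {
  cn <- as.matrix(cn)
  if (length(windows) != nrow(cn)) stop("window count and CN rows differ")
  if (ncol(cn) < 1L) stop("CN matrix needs at least one sample")
  w <- GenomicRanges::width(windows)
  n_chrom <- length(unique(as.character(GenomeInfoDb::seqnames(windows))))
  # uniform tiling: only the final window of each chromosome may be shorter
  if (any(w > window_size) || sum(w != window_size) > n_chrom)
    stop("window size not uniform")
  structure(list(windows = windows, cn = cn, window_size = window_size),
            class = "cn_window_matrix")
}

#' Tile a genome into fixed windows
#' @param genome A `genome_model`.
#' @param window_size Window width in bp (last window per chromosome may be
#'   shorter).
#' @export
tile_genome <- function(genome, window_size = 100L) {
  grl <- GenomicRanges::tileGenome(genome$chrom_lengths, tilewidth = window_size,
                                   cut.last.tile.in.chrom = TRUE)
  grl
}

#' Detect high-copy-number "bad bin" windows
#'
#' A window is flagged when its copy number exceeds `cn_threshold` (strictly)
#' in at least `ceiling(sample_fraction * n_samples)` samples — regions of
#' collapsed repeats or segmental duplication where short-read SV calls are
#' unreliable.
#'
#' @param cn A `cn_window_matrix`.
#' @param cn_threshold Copy-number cut-off (default 10, five times diploid).
#' @param sample_fraction Fraction of samples required (default 0.90).
#' @param merge Merge adjacent flagged windows in the returned track.
#' @return A `feature_track` named "bad_bins" with label "bad_bin".
#' @export
detect_bad_bins <- function(cn, cn_threshold = 10, sample_fraction = 0.90,
                            merge = TRUE) {
  stopifnot(inherits(cn, "cn_window_matrix"))
  need <- ceiling(sample_fraction * ncol(cn$cn))
  flagged <- rowSums(cn$cn > cn_threshold) >= need
  gr <- cn$windows[flagged]
  if (merge) gr <- GenomicRanges::reduce(gr)
  feature_track("bad_bins",
                as.character(GenomeInfoDb::seqnames(gr)),
                GenomicRanges::start(gr), GenomicRanges::end(gr),
                label = rep("bad_bin", length(gr)),
                vocabulary = "bad_bin")
}

qc_step <- function(catalog, keep, filter_name) {
  removed <- catalog$variants$id[!keep]
  list(catalog = subset_svs(catalog, which(keep)),
       report = data.frame(filter = filter_name,
                           n_input = length(keep),
                           n_removed = sum(!keep),
                           n_retained = sum(keep)),
       removed = removed)
}

#' Remove SVs overlapping bad bins (>= 1 bp)
#' @param catalog An `sv_catalog`.
#' @param bad_bins `feature_track` or `GRanges` of bad-bin windows.
#' @return list(catalog, report, removed).
#' @export
filter_bad_bin_overlap <- function(catalog, bad_bins) {
  gr <- if (inherits(bad_bins, "feature_track")) bad_bins$ranges else bad_bins
  hit <- GenomicRanges::countOverlaps(sv_ranges(catalog), gr,
                                      ignore.strand = TRUE) > 0
  qc_step(catalog, !hit, "bad_bin_overlap")
}

#' Remove SVs overlapping reference assembly gaps (>= 1 bp)
#' @param catalog An `sv_catalog`.
#' @param genome A `genome_model` carrying gap intervals.
#' @return list(catalog, report, removed).
#' @export
filter_gap_overlap <- function(catalog, genome) {
  hit <- GenomicRanges::countOverlaps(sv_ranges(catalog), genome$gaps,
                                      ignore.strand = TRUE) > 0
  qc_step(catalog, !hit, "gap_overlap")
}

#' Remove events shorter than the minimum SV length
#'
#' Events with length strictly below `min_len` are removed (length-49 goes,
#' length-50 stays at the default). Records without a defined length
#' (inter-chromosomal breakends) are retained.
#' @param catalog An `sv_catalog`.
#' @param min_len Minimum length in bp (default 50).
#' @return list(catalog, report, removed).
#' @export
filter_min_length <- function(catalog, min_len = 50) {
  len <- catalog$variants$length
  keep <- is.na(len) | len >= min_len
  qc_step(catalog, keep, "min_length")
}

#' Type-specific evidence filters
#'
#' Applies, in order: (a) DEL/MEI require MSQ > `msq_del_mei`; (b) DELs with
#' length <= `small_del_max` additionally require split-read support in at
#' least one sample; (c) INVs require MSQ > `msq_inv` AND mean allele balance
#' across carrier samples >= `inv_support_min`; (d) BNDs require
#' MSQ > `msq_bnd`. DUPs pass untouched. A record subject to an MSQ rule with
#' missing MSQ is removed (conservative) and logged.
#'
#' @param catalog An `sv_catalog` with `msq`, and `sr_support` /
#'   `allele_balance` matrices where the DEL and INV rules apply.
#' @param msq_del_mei,msq_inv,msq_bnd MSQ thresholds (strict >).
#' @param small_del_max DELs at or below this length need split-read support.
#' @param inv_support_min Minimum mean carrier allele balance for INVs.
#' @return list(catalog, report, removed).
#' @export
apply_type_filters <- function(catalog, msq_del_mei = 100, msq_inv = 150,
                               msq_bnd = 250, small_del_max = 1000,
                               inv_support_min = 0.10) {
  v <- catalog$variants
  msq <- v$msq
  keep <- rep(TRUE, nrow(v))

  dm <- v$svtype %in% c("DEL", "MEI")
  keep[dm] <- !is.na(msq[dm]) & msq[dm] > msq_del_mei
  if (any(dm & is.na(msq)))
    message("removed ", sum(dm & is.na(msq)), " DEL/MEI record(s) with missing MSQ")

  small_del <- v$svtype == "DEL" & v$length <= small_del_max
  if (any(small_del)) {
    if (is.null(catalog$sr_support)) {
      keep[small_del] <- FALSE
      message("removed ", sum(small_del),
              " small DEL(s): no split-read support matrix available")
    } else {
      has_sr <- rowSums(catalog$sr_support >= 1, na.rm = TRUE) > 0
      keep[small_del] <- keep[small_del] & has_sr[small_del]
    }
  }

  inv <- v$svtype == "INV"
  if (any(inv)) {
    ab_ok <- rep(FALSE, nrow(v))
    if (!is.null(catalog$allele_balance)) {
      carrier <- !is.na(catalog$genotypes) & catalog$genotypes >= 1
      ab <- catalog$allele_balance
      ab[!carrier] <- NA
      mean_ab <- rowMeans(ab, na.rm = TRUE)
      ab_ok <- !is.nan(mean_ab) & mean_ab >= inv_support_min
    }
    keep[inv] <- !is.na(msq[inv]) & msq[inv] > msq_inv & ab_ok[inv]
  }

  bnd <- v$svtype == "BND"
  keep[bnd] <- !is.na(msq[bnd]) & msq[bnd] > msq_bnd

  qc_step(catalog, keep, "type_filters")
}

#' Per-sample genotype masking for DEL/MEI records
#'
#' Sets DEL/MEI genotypes to missing where the site was poorly captured by
#' split reads in that sample (capture flag FALSE) or the event is shorter
#' than the minimum size genotypable at 95% confidence for the record.
#'
#' @param catalog An `sv_catalog`.
#' @param capture_flags Optional logical matrix (variants x samples); TRUE =
#'   well captured. `NULL` skips that rule.
#' @param use_min_size Apply the `min_size_95` length rule where annotated.
#' @return The catalog with masked genotypes (a warning when no annotations
#'   are supplied, in which case it is returned unchanged).
#' @export
mask_sample_genotypes <- function(catalog, capture_flags = NULL,
                                  use_min_size = TRUE) {
  v <- catalog$variants
  dm <- v$svtype %in% c("DEL", "MEI")
  has_ms <- use_min_size && any(!is.na(v$min_size_95))
  if (is.null(capture_flags) && !has_ms) {
    warning("no masking annotations supplied; catalog unchanged")
    return(catalog)
  }
  gt <- catalog$genotypes
  if (!is.null(capture_flags)) {
    stopifnot(nrow(capture_flags) == nrow(v), ncol(capture_flags) == ncol(gt))
    gt[dm & !capture_flags] <- NA_integer_
  }
  if (has_ms) {
    too_small <- dm & !is.na(v$min_size_95) & v$length < v$min_size_95
    gt[too_small, ] <- NA_integer_
  }
  catalog$genotypes <- gt
  catalog
}

#' Allele balance from read counts
#'
#' ALT-supporting reads divided by the sum of ALT- and REF-supporting reads;
#' undefined (NA) when both are zero.
#' @param alt_reads,ref_reads Non-negative read counts (vectorized).
#' @return Numeric vector in \[0, 1\] with NA where undefined.
#' @export
allele_balance <- function(alt_reads, ref_reads) {
  tot <- alt_reads + ref_reads
  ifelse(tot > 0, alt_reads / tot, NA_real_)
}

#' Sample-level exclusion by missing rate and SV count
#'
#' Flags samples with genotype missing rate strictly above `max_missing`
#' (exactly 15\% is retained) or with fewer than `min_sv_count` carried SVs
#' (non-missing dosage >= 1).
#' @param catalog An `sv_catalog`.
#' @param max_missing Maximum tolerated missing rate (default 0.15).
#' @param min_sv_count Minimum carried-SV count (default 10000).
#' @return data.frame with per-sample metrics, `excluded` flag and reason.
#' @export
sample_level_filters <- function(catalog, max_missing = 0.15,
                                 min_sv_count = 10000) {
  gt <- catalog$genotypes
  miss <- colMeans(is.na(gt))
  count <- colSums(!is.na(gt) & gt >= 1)
  excl_miss <- miss > max_missing
  excl_count <- count < min_sv_count
  data.frame(sample_id = catalog$samples, missing_rate = miss,
             sv_count = count, excluded = excl_miss | excl_count,
             reason = ifelse(excl_miss & excl_count, "missing_rate;sv_count",
                      ifelse(excl_miss, "missing_rate",
                      ifelse(excl_count, "sv_count", ""))),
             row.names = NULL)
}

#' Run the full QC stack in the fixed order
#'
#' Order: bad-bin overlap, gap overlap, minimum length, type-specific
#' filters, per-sample masking.
#' @param catalog An `sv_catalog`.
#' @param genome A `genome_model`.
#' @param bad_bins Bad-bin `feature_track` (e.g. from [detect_bad_bins()]),
#'   or `NULL` to skip.
#' @param capture_flags Passed to [mask_sample_genotypes()].
#' @param ... Threshold overrides passed to the individual filters.
#' @return list(catalog, report) where report stacks the per-filter tallies.
#' @export
run_qc <- function(catalog, genome, bad_bins = NULL, capture_flags = NULL, ...) {
  dots <- list(...)
  reports <- list()
  if (!is.null(bad_bins)) {
    s <- filter_bad_bin_overlap(catalog, bad_bins)
    catalog <- s$catalog; reports <- c(reports, list(s$report))
  }
  s <- filter_gap_overlap(catalog, genome)
  catalog <- s$catalog; reports <- c(reports, list(s$report))
  s <- do.call(filter_min_length,
               c(list(catalog), dots[intersect(names(dots), "min_len")]))
  catalog <- s$catalog; reports <- c(reports, list(s$report))
  tf_args <- dots[intersect(names(dots), c("msq_del_mei", "msq_inv", "msq_bnd",
                                           "small_del_max", "inv_support_min"))]
  s <- do.call(apply_type_filters, c(list(catalog), tf_args))
  catalog <- s$catalog; reports <- c(reports, list(s$report))
  if (!is.null(capture_flags) || any(!is.na(catalog$variants$min_size_95))) {
    cf <- capture_flags
    if (!is.null(cf)) {
      cf <- cf[catalog$variants$id, catalog$samples, drop = FALSE]
    }
    catalog <- mask_sample_genotypes(catalog, cf)
  }
  list(catalog = catalog, report = do.call(rbind, reports))
}
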