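# Validation of short-read SVs against an assembly-comparison SV set:
# >= 1 bp overlap matching plus a min/max length-consistency ratio.

#' Match a query SV set against a truth (assembly-derived) set
#'
#' All same-chromosome overlaps of at least `min_overlap` bp are reported;
#' for consistency scoring each query keeps its best match — the pair with
#' the largest reciprocal overlap (the smaller of the two overlap fractions),
#' ties broken by the smaller length difference. The consistency ratio of a
#' pair is min(lengths) / max(lengths).
#'
#' @param query,truth `GRanges` (named, or names are generated) or
#'   `sv_catalog` objects.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return data.frame of matched pairs: ids, lengths, overlap bp, reciprocal
#'   overlap, consistency, and a `best` flag.
#' @export
match_sv_sets <- function(query, truth, min_overlap = 1) {
  as_gr <- function(x, prefix) {
    if (inherits(x, "sv_catalog")) x <- sv_ranges(x)
    if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
    x
  }
  query <- as_gr(query, "q"); truth <- as_gr(truth, "t")
  hits <- GenomicRanges::findOverlaps(query, truth, minoverlap = min_overlap,
                                      ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(query_id = character(), truth_id = character(),
                      query_len = numeric(), truth_len = numeric(),
                      overlap_bp = numeric(), reciprocal = numeric(),
                      consistency = numeric(), best = logical()))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::pintersect(query[qh], truth[sh])
  ov_bp <- as.numeric(GenomicRanges::width(ov))
  ql <- as.numeric(GenomicRanges::width(query))[qh]
  tl <- as.numeric(GenomicRanges::width(truth))[sh]
  pairs <- data.frame(query_id = names(query)[qh], truth_id = names(truth)[sh],
                      query_len = ql, truth_len = tl, overlap_bp = ov_bp,
                      reciprocal = pmin(ov_bp / ql, ov_bp / tl),
                      consistency = pmin(ql, tl) / pmax(ql, tl))
  ord <- order(pairs$query_id, -pairs$reciprocal, abs(pairs$query_len -
                                                       pairs$truth_len))
  pairs <- pairs[ord, ]
  pairs$best <- !duplicated(pairs$query_id)
  rownames(pairs) <- NULL
  pairs
}

#' Validation rates from matched pairs
#'
#' By count: validated (matched) query records over all query records. By
#' length: bp of validated query records over total query bp. Also reports
#' the fraction of best-matched pairs with length consistency above
#' `consistency_min`.
#' @param pairs Output of [match_sv_sets()].
#' @param query The query set used for matching (`GRanges` or `sv_catalog`).
#' @param consistency_min High-consistency bound (default 0.98, strict >).
#' @return One-row data.frame of class `validation_report`.
#' @export
validation_rates <- function(pairs, query, consistency_min = 0.98) {
  if (inherits(query, "sv_catalog")) query <- sv_ranges(query)
  if (is.null(names(query))) names(query) <- paste0("q", seq_along(query))
  matched <- names(query) %in% pairs$query_id
  lens <- as.numeric(GenomicRanges::width(query))
  best <- pairs[pairs$best, , drop = FALSE]
  out <- data.frame(
    n_query = length(query), n_validated = sum(matched),
    rate_by_count = mean(matched),
    rate_by_length = sum(lens[matched]) / sum(lens),
    frac_high_consistency = if (nrow(best))
      mean(best$consistency > consistency_min) else NA_real_)
  class(out) <- c("validation_report", "data.frame")
  out
}
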