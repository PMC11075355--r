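# Internal helpers shared across modules. Internal coordinates are 1-based,
# both ends inclusive (so a single base has start == end and width 1).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Length of a 1-based inclusive span
#'
#' @param start,end Integer-like vectors of 1-based inclusive coordinates.
#' @return `end - start + 1`.
#' @export
span_length <- function(start, end) end - start + 1

# BED (0-based half-open) <-> internal (1-based inclusive)
bed_to_internal_start <- function(start0) start0 + 1
internal_to_bed_start <- function(start1) start1 - 1

#' Total non-redundant base pairs covered by a set of ranges
#' @param gr A `GRanges`.
#' @return Numeric scalar: bp covered after merging overlaps.
#' @export
reduced_bp <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr, ignore.strand = TRUE))))
}

#' Base pairs shared by two range sets
#' @param a,b `GRanges` objects.
#' @return Numeric scalar: bp in the intersection of the merged sets.
#' @export
overlap_bp <- function(a, b) {
  ia <- GenomicRanges::reduce(a, ignore.strand = TRUE)
  ib <- GenomicRanges::reduce(b, ignore.strand = TRUE)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::intersect(ia, ib, ignore.strand = TRUE))))
}

# Per-range bp of overlap with a (merged) subject set.
per_range_overlap_bp <- function(query, subject) {
  subject <- GenomicRanges::reduce(subject, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  if (length(hits) == 0L) return(numeric(length(query)))
  pieces <- GenomicRanges::pintersect(
    query[S4Vectors::queryHits(hits)], subject[S4Vectors::subjectHits(hits)]
  )
  bp <- tapply(as.numeric(GenomicRanges::width(pieces)), S4Vectors::queryHits(hits), sum)
  out <- numeric(length(query))
  out[as.integer(names(bp))] <- as.numeric(bp)
  out
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop("'", name, "' must be a single non-missing number")
}
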