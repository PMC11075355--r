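# Gene-impact classification: DEL->MEI reclassification by repeat coverage,
# the 15-category gene-overlap scheme with strong/weak calls, allele-count
# frequency classes, and regulator overlapped/flanking relations.

#' The gene-overlap impact categories
#'
#' Thirteen named whole-gene/exonic categories plus `intron` and `noncoding`;
#' SVs overlapping no gene are `intergenic`.
#' @export
IMPACT_CATEGORIES <- c("WlGnDel", "WlGnDup", "WlGnInv",
                       "pLoF_St", "pLoF_Wk", "CpGn_St", "CpGn_Wk",
                       "codInv", "codBnd",
                       "Rglt5_St", "Rglt5_Wk", "Rglt3_St", "Rglt3_Wk",
                       "intron", "noncoding")

#' Reclassify deletions as mobile element insertions by repeat coverage
#'
#' A reference-based catalog detects a polymorphic mobile element as a DEL
#' where the reference carries the element. A DEL becomes an MEI when the
#' union of overlapping repeat intervals covers strictly more than
#' `cover_threshold` of its length (90\% keeps the DEL; 90.1\% flips it).
#' Coordinates are never changed, only the type.
#'
#' @param catalog An `sv_catalog`.
#' @param repeats `feature_track` of repeat intervals (overlaps are merged
#'   before summing so duplicated repeat records cannot double-count).
#' @param cover_threshold Coverage fraction (strict >; default 0.90).
#' @return The catalog with reclassified svtype and updated ids kept intact.
#' @export
reclassify_del_to_mei <- function(catalog, repeats, cover_threshold = 0.90) {
  v <- catalog$variants
  del <- which(v$svtype == "DEL")
  if (!length(del)) return(catalog)
  rep_gr <- if (inherits(repeats, "feature_track")) repeats$ranges else repeats
  gr <- sv_ranges(catalog)[del]
  cov <- per_range_overlap_bp(gr, rep_gr)
  flip <- cov > cover_threshold * v$length[del]
  catalog$variants$svtype[del[flip]] <- "MEI"
  catalog
}

# Overlap bp between one interval and an IRanges set on the same chromosome.
ir_overlap_bp <- function(start, end, ir) {
  if (length(ir) == 0L) return(0)
  sum(IRanges::width(IRanges::intersect(IRanges::IRanges(start, end),
                                        IRanges::reduce(ir))))
}

#' Classify one SV against one gene
#'
#' Precedence: whole-gene engulfment (DEL/DUP/INV) > CDS overlap > UTR
#' overlap > exon overlap in a non-protein-coding gene (`noncoding`) >
#' `intron`. CDS- and UTR-mapped calls are strong (`St`) when the overlapped
#' feature accounts for at least 20\% of the SV's own length, weak (`Wk`)
#' below. When both UTRs are hit, the larger overlap wins (ties go 5').
#'
#' @param sv A list/row with `chrom`, `start`, `end`, `svtype`, `length`
#'   (e.g. one row of `catalog$variants`), overlapping the gene body >= 1 bp.
#' @param gene A `gene_model`.
#' @param strong_fraction St/Wk boundary on the SV-length fraction
#'   (default 0.20, inclusive for St).
#' @return list with `category`, `cds_fraction`, `utr5_fraction`,
#'   `utr3_fraction`.
#' @export
classify_sv_gene <- function(sv, gene, strong_fraction = 0.20) {
  if (length(gene$exons) == 0L) stop("gene '", gene$gene_id, "' has no exons")
  if (!identical(as.character(sv$chrom), gene$chrom))
    stop("SV and gene are on different chromosomes")
  sv_len <- sv$end - sv$start + 1
  cds_bp <- ir_overlap_bp(sv$start, sv$end, gene$cds)
  utr5_bp <- ir_overlap_bp(sv$start, sv$end, gene$utr5)
  utr3_bp <- ir_overlap_bp(sv$start, sv$end, gene$utr3)
  fr <- list(cds_fraction = cds_bp / sv_len,
             utr5_fraction = utr5_bp / sv_len,
             utr3_fraction = utr3_bp / sv_len)

  engulfs <- sv$start <= gene$body_start && sv$end >= gene$body_end
  if (engulfs && sv$svtype %in% c("DEL", "DUP", "INV")) {
    cat <- switch(sv$svtype, DEL = "WlGnDel", DUP = "WlGnDup", INV = "WlGnInv")
    return(c(list(category = cat), fr))
  }
  if (cds_bp > 0) {
    base <- switch(sv$svtype, DEL = "pLoF", MEI = "pLoF", DUP = "CpGn",
                   INV = "codInv", BND = "codBnd")
    cat <- if (base %in% c("pLoF", "CpGn")) {
      paste0(base, if (fr$cds_fraction >= strong_fraction) "_St" else "_Wk")
    } else base
    return(c(list(category = cat), fr))
  }
  if (utr5_bp > 0 || utr3_bp > 0) {
    side <- if (utr5_bp >= utr3_bp) "5" else "3"   # tie -> 5'
    frac <- if (side == "5") fr$utr5_fraction else fr$utr3_fraction
    cat <- paste0("Rglt", side, if (frac >= strong_fraction) "_St" else "_Wk")
    return(c(list(category = cat), fr))
  }
  exon_bp <- ir_overlap_bp(sv$start, sv$end, gene$exons)
  if (exon_bp > 0 && gene$biotype != "protein_coding")
    return(c(list(category = "noncoding"), fr))
  c(list(category = "intron"), fr)
}

#' Classify every (SV, gene) overlap in a catalog
#'
#' One impact call per overlapping (SV, gene) pair — an SV spanning two genes
#' is tallied once in each category it triggers — and a single `intergenic`
#' call for SVs overlapping no gene.
#'
#' @param catalog An `sv_catalog`.
#' @param genes A `gene_model_set`.
#' @param strong_fraction Passed to [classify_sv_gene()].
#' @return data.frame of calls (`sv_id`, `gene_id`, `category`, fractions).
#'   The per-category summary is available via [category_counts()].
#' @export
classify_catalog <- function(catalog, genes, strong_fraction = 0.20) {
  v <- catalog$variants
  empty <- data.frame(sv_id = character(), gene_id = character(),
                      category = character(), cds_fraction = numeric(),
                      utr5_fraction = numeric(), utr3_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(v) == 0L) return(empty)
  if (length(genes) == 0L) {
    return(rbind(empty,
                 data.frame(sv_id = v$id, gene_id = NA_character_,
                            category = "intergenic", cds_fraction = 0,
                            utr5_fraction = 0, utr3_fraction = 0)))
  }
  hits <- GenomicRanges::findOverlaps(sv_ranges(catalog), genes$bodies,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  calls <- vector("list", length(qh))
  for (k in seq_along(qh)) {
    i <- qh[k]
    g <- genes$genes[[sh[k]]]
    cl <- classify_sv_gene(v[i, ], g, strong_fraction)
    calls[[k]] <- data.frame(sv_id = v$id[i], gene_id = g$gene_id,
                             category = cl$category,
                             cds_fraction = cl$cds_fraction,
                             utr5_fraction = cl$utr5_fraction,
                             utr3_fraction = cl$utr3_fraction,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else empty
  inter <- setdiff(v$id, out$sv_id)
  if (length(inter))
    out <- rbind(out, data.frame(sv_id = inter, gene_id = NA_character_,
                                 category = "intergenic", cds_fraction = 0,
                                 utr5_fraction = 0, utr3_fraction = 0))
  rownames(out) <- NULL
  out
}

#' Distinct SV and gene counts per impact category
#' @param calls Output of [classify_catalog()].
#' @return data.frame with `category`, `n_sv`, `n_gene`.
#' @export
category_counts <- function(calls) {
  cats <- c(IMPACT_CATEGORIES, "intergenic")
  out <- data.frame(category = cats,
                    n_sv = vapply(cats, function(cc)
                      length(unique(calls$sv_id[calls$category == cc])), 0L),
                    n_gene = vapply(cats, function(cc)
                      length(unique(stats::na.omit(
                        calls$gene_id[calls$category == cc]))), 0L),
                    row.names = NULL)
  out
}

#' Allele-count frequency class
#'
#' Singleton: AC = 1; rare: 1 < AC <= `rare_ac_max`; common: AC >
#' `rare_ac_max`. The allele frequency AC / (2 x non-missing samples) is
#' reported alongside but the boundary is AC-based.
#' @param ac Allele count(s), non-negative integers.
#' @param n_samples_nonmissing Samples with non-missing genotypes.
#' @param rare_ac_max Rare/common boundary (default 10).
#' @return data.frame with `ac`, `af`, `class`.
#' @export
frequency_class <- function(ac, n_samples_nonmissing, rare_ac_max = 10) {
  af <- ac / (2 * n_samples_nonmissing)
  af[rep_len(n_samples_nonmissing == 0, length(ac))] <- NA_real_
  cls <- ifelse(ac == 1, "singleton",
         ifelse(ac > 1 & ac <= rare_ac_max, "rare",
         ifelse(ac > rare_ac_max, "common", "absent")))
  data.frame(ac = ac, af = af, class = cls)
}

#' Relation of a regulatory element to an SV
#'
#' `overlapped` when the element intersects the SV by >= 1 bp (takes
#' precedence); `flanking` when it intersects either 5-kb flank
#' (`[start-flank, start-1]` or `[end+1, end+flank]`); `none` otherwise.
#' @param sv List/row with `chrom`, `start`, `end`.
#' @param elements `GRanges` (or `feature_track`) of elements.
#' @param flank Flank width in bp (default 5000).
#' @return Character vector, one relation per element.
#' @export
regulator_relation <- function(sv, elements, flank = 5000) {
  gr <- if (inherits(elements, "feature_track")) elements$ranges else elements
  rel <- rep("none", length(gr))
  same <- as.character(GenomeInfoDb::seqnames(gr)) == as.character(sv$chrom)
  s <- GenomicRanges::start(gr); e <- GenomicRanges::end(gr)
  ovl <- same & s <= sv$end & e >= sv$start
  left <- same & s <= sv$start - 1 & e >= max(1, sv$start - flank)
  right <- same & s <= sv$end + flank & e >= sv$end + 1
  rel[(left | right)] <- "flanking"
  rel[ovl] <- "overlapped"
  rel
}
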