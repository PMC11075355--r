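#' @importFrom stats setNames
NULL

#' Recognized structural variant types
#' @export
SV_TYPES <- c("DEL", "MEI", "DUP", "INV", "BND")

#' Parse a structural variant identifier
#'
#' Identifiers take the form `"chrom:start-end:TYPE"` with 1-based, both-ends
#' inclusive coordinates; the separator between start and end may be an ASCII
#' hyphen or an en-dash (as printed in many publications). The length of a
#' non-BND event is `end - start + 1`; for a BND identifier the two positions
#' are junction partners and the "length" is the absolute position difference.
#'
#' @param id Character scalar identifier.
#' @return A list with `id`, `chrom`, `start`, `end`, `svtype`, `length` —
#'   a skeleton for [sv_catalog()] records.
#' @examples
#' parse_sv_identifier("1:119154722-119155024:DEL")$length  # 303
#' @export
parse_sv_identifier <- function(id) {
  if (!is.character(id) || length(id) != 1L || is.na(id))
    stop("'id' must be a single character string")
  m <- regmatches(id, regexec("^([^:]+):([0-9]+)[-–]([0-9]+):([A-Za-z]+)$", id))[[1]]
  if (length(m) == 0L)
    stop("malformed SV identifier: '", id, "' (expected \"chrom:start-end:TYPE\")")
  svtype <- m[5]
  if (!svtype %in% SV_TYPES)
    stop("unknown SV type token '", svtype, "' in identifier '", id, "'")
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (start > end)
    stop("start > end (", m[3], " > ", m[4], ") in identifier '", id, "'")
  len <- if (svtype == "BND") end - start else end - start + 1
  list(id = id, chrom = m[2], start = start, end = end, svtype = svtype, length = len)
}

#' Compose a canonical SV identifier
#' @param chrom,start,end,svtype Vectors describing the events.
#' @return Character vector `"chrom:start-end:TYPE"`.
#' @export
sv_id <- function(chrom, start, end, svtype) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), svtype)
}

#' Reference genome model: chromosome lengths and assembly gaps
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp > 0).
#' @param gaps Optional `GRanges` (or data.frame with chrom/start/end, 1-based
#'   inclusive) of assembly gap intervals; each must lie within its chromosome.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(chrom_lengths, gaps = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must be a named vector")
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0")
  if (is.null(gaps)) {
    gaps <- GenomicRanges::GRanges()
  } else if (is.data.frame(gaps)) {
    gaps <- GenomicRanges::GRanges(gaps$chrom, IRanges::IRanges(gaps$start, gaps$end))
  }
  if (length(gaps)) {
    chr <- as.character(GenomeInfoDb::seqnames(gaps))
    if (!all(chr %in% names(chrom_lengths)))
      stop("gap intervals on unknown chromosomes: ",
           paste(unique(setdiff(chr, names(chrom_lengths))), collapse = ", "))
    if (any(GenomicRanges::start(gaps) < 1) ||
        any(GenomicRanges::end(gaps) > chrom_lengths[chr]))
      stop("gap intervals outside chromosome bounds")
  }
  structure(list(chrom_lengths = chrom_lengths, gaps = gaps), class = "genome_model")
}

#' @method print genome_model
#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp,",
      length(x$gaps), "gap intervals\n")
  invisible(x)
}

#' Total genome size of a genome model
#' @param genome A `genome_model`.
#' @export
genome_bp <- function(genome) sum(as.numeric(genome$chrom_lengths))

#' A labeled genomic interval track
#'
#' One schema for repeat annotations, chromatin-state segmentations,
#' enhancer/promoter calls, QTL intervals and bad-bin lists. Coordinates are
#' 1-based inclusive (use [read_feature_track()] for BED input).
#'
#' @param name Track name.
#' @param chrom,start,end Interval coordinates.
#' @param label Feature class label per interval.
#' @param tissue Optional tissue per interval.
#' @param vocabulary Optional allowed label set; out-of-vocabulary labels are
#'   an error listing the offenders.
#' @return An object of class `feature_track` wrapping a `GRanges` with
#'   metadata columns `label` and `tissue`.
#' @export
feature_track <- function(name, chrom, start, end, label,
                          tissue = NA_character_, vocabulary = NULL) {
  if (any(start > end)) stop("feature intervals with start > end")
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(label), vocabulary)
    if (length(bad))
      stop("track '", name, "': labels outside vocabulary: ", paste(bad, collapse = ", "))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  S4Vectors::mcols(gr)$label <- label
  S4Vectors::mcols(gr)$tissue <- rep_len(tissue, length(gr))
  structure(list(name = name, vocabulary = vocabulary %||% sort(unique(label)),
                 ranges = gr),
            class = "feature_track")
}

#' @method print feature_track
#' @export
print.feature_track <- function(x, ...) {
  cat("feature_track '", x$name, "': ", length(x$ranges), " intervals, ",
      length(x$vocabulary), " labels\n", sep = "")
  invisible(x)
}

#' Extract the GRanges of a feature track (optionally one label)
#' @param track A `feature_track`.
#' @param label Optional label(s) to keep.
#' @param tissue Optional tissue(s) to keep.
#' @export
track_ranges <- function(track, label = NULL, tissue = NULL) {
  gr <- track$ranges
  if (!is.null(label)) gr <- gr[S4Vectors::mcols(gr)$label %in% label]
  if (!is.null(tissue)) gr <- gr[S4Vectors::mcols(gr)$tissue %in% tissue]
  gr
}

#' Structural variant catalog
#'
#' The central container of the pipeline: a table of SV records plus aligned
#' per-sample matrices. Genotypes are dosages in \{0, 1, 2\} with `NA` for
#' missing; missing is never counted in allele-count denominators.
#'
#' @param variants data.frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype`, and optionally `length`, `msq`, `min_size_95`. Non-BND lengths
#'   must equal `end - start + 1` (filled in when absent).
#' @param genotypes Integer matrix (variants x samples); rownames = ids.
#' @param samples Sample roster (defaults to `colnames(genotypes)`).
#' @param sr_support,pe_support Optional per-sample split-read / paired-end
#'   support count matrices, same shape as `genotypes`.
#' @param allele_balance Optional per-sample matrix of ALT/(ALT+REF) read
#'   fractions in \[0, 1\].
#' @param copy_number Optional per-sample copy-number matrix.
#' @param provenance Character notes carried along.
#' @return An object of class `sv_catalog`.
#' @export
sv_catalog <- function(variants, genotypes, samples = colnames(genotypes),
                       sr_support = NULL, pe_support = NULL,
                       allele_balance = NULL, copy_number = NULL,
                       provenance = character()) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "svtype")
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (is.null(variants$id))
    variants$id <- sv_id(variants$chrom, variants$start, variants$end,
                         variants$svtype)
  if (anyDuplicated(variants$id))
    stop("duplicate SV ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (!all(variants$svtype %in% SV_TYPES))
    stop("unknown svtype values: ",
         paste(setdiff(unique(variants$svtype), SV_TYPES), collapse = ", "))
  if (any(variants$end < variants$start)) stop("records with end < start")
  if (is.null(variants$length)) variants$length <- NA_real_
  nb <- variants$svtype != "BND"
  expect_len <- variants$end - variants$start + 1
  variants$length[nb & is.na(variants$length)] <- expect_len[nb & is.na(variants$length)]
  if (any(nb & variants$length != expect_len))
    stop("non-BND records where length != end - start + 1")
  # intra-chromosomal breakend span: junction distance
  bnd_fill <- !nb & is.na(variants$length) & variants$end > variants$start
  variants$length[bnd_fill] <-
    variants$end[bnd_fill] - variants$start[bnd_fill]
  if (is.null(variants$msq)) variants$msq <- NA_real_
  if (is.null(variants$min_size_95)) variants$min_size_95 <- NA_real_
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(variants))
    stop("genotype matrix rows must match variant count")
  rownames(genotypes) <- variants$id
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(genotypes)))
  colnames(genotypes) <- samples
  ok <- genotypes %in% c(0L, 1L, 2L) | is.na(genotypes)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or NA")
  align <- function(m) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    stopifnot(nrow(m) == nrow(variants), ncol(m) == length(samples))
    dimnames(m) <- list(variants$id, samples)
    m
  }
  structure(list(variants = variants, genotypes = genotypes, samples = samples,
                 sr_support = align(sr_support), pe_support = align(pe_support),
                 allele_balance = align(allele_balance),
                 copy_number = align(copy_number),
                 provenance = provenance),
            class = "sv_catalog")
}

#' @method print sv_catalog
#' @export
print.sv_catalog <- function(x, ...) {
  cat("sv_catalog:", nrow(x$variants), "SVs x", length(x$samples), "samples\n")
  print(table(x$variants$svtype))
  invisible(x)
}

#' Number of SV records in a catalog
#' @param catalog An `sv_catalog`.
#' @export
n_svs <- function(catalog) nrow(catalog$variants)

#' Catalog records as a GRanges
#'
#' BND records are represented by their junction span (both partners
#' intra-chromosomal) or by the single breakpoint base.
#' @param catalog An `sv_catalog`.
#' @export
sv_ranges <- function(catalog) {
  v <- catalog$variants
  gr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$start, v$end))
  names(gr) <- v$id
  S4Vectors::mcols(gr)$svtype <- v$svtype
  gr
}

#' Subset a catalog by variant ids (or logical/integer index)
#' @param catalog An `sv_catalog`.
#' @param i Ids, logical mask, or integer index over records.
#' @export
subset_svs <- function(catalog, i) {
  if (is.character(i)) i <- match(i, catalog$variants$id)
  sub <- function(m) if (is.null(m)) NULL else m[i, , drop = FALSE]
  sv_catalog(catalog$variants[i, , drop = FALSE],
             catalog$genotypes[i, , drop = FALSE], catalog$samples,
             sr_support = sub(catalog$sr_support),
             pe_support = sub(catalog$pe_support),
             allele_balance = sub(catalog$allele_balance),
             copy_number = sub(catalog$copy_number),
             provenance = catalog$provenance)
}

#' Allele counts and frequencies over non-missing genotypes
#' @param catalog An `sv_catalog`.
#' @return data.frame with `id`, `ac`, `an` (non-missing allele number), `af`.
#' @export
allele_counts <- function(catalog) {
  gt <- catalog$genotypes
  ac <- rowSums(gt, na.rm = TRUE)
  an <- 2 * rowSums(!is.na(gt))
  data.frame(id = catalog$variants$id, ac = ac, an = an,
             af = ifelse(an > 0, ac / an, NA_real_), row.names = NULL)
}

#' Sample-to-population metadata
#'
#' The ancestral group is derived deterministically from the main population:
#' ASW/ASD -> AS, EUC/EUD/EUW -> EU, ASxEU/OTG -> other.
#'
#' @param sample_id,population,subpopulation Vectors of equal length;
#'   `population` must be one of ASW, ASD, ASxEU, EUC, EUD, EUW, OTG.
#' @return data.frame of class `population_map` with an `ancestral` column.
#' @export
population_map <- function(sample_id, population, subpopulation = NA_character_) {
  main <- c("ASW", "ASD", "ASxEU", "EUC", "EUD", "EUW", "OTG")
  bad <- setdiff(unique(population), main)
  if (length(bad)) stop("unknown main populations: ", paste(bad, collapse = ", "))
  if (anyDuplicated(sample_id)) stop("duplicate sample ids in population map")
  anc <- c(ASW = "AS", ASD = "AS", ASxEU = "other",
           EUC = "EU", EUD = "EU", EUW = "EU", OTG = "other")[population]
  out <- data.frame(sample_id = sample_id, population = population,
                    subpopulation = rep_len(subpopulation, length(sample_id)),
                    ancestral = unname(anc), stringsAsFactors = FALSE)
  class(out) <- c("population_map", "data.frame")
  out
}

#' Check that a population map covers a sample roster
#' @param pop_map A `population_map`.
#' @param samples Character roster.
#' @export
check_population_map <- function(pop_map, samples) {
  miss <- setdiff(samples, pop_map$sample_id)
  if (length(miss))
    stop("population map is missing samples: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Samples x variants dosage matrix for SVs and/or SNPs
#'
#' @param gt Integer dosage matrix (variants x samples), `NA` = missing.
#' @param info data.frame with `id`, `chrom`, `pos`, `kind` ("SV" or "SNP").
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(gt, info) {
  gt <- as.matrix(gt)
  info <- as.data.frame(info, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos", "kind") %in% names(info)),
            nrow(gt) == nrow(info))
  if (!all(info$kind %in% c("SV", "SNP"))) stop("variant kind must be SV or SNP")
  if (anyDuplicated(info$id)) stop("duplicate variant ids in genotype matrix")
  rownames(gt) <- info$id
  structure(list(gt = gt, info = info, samples = colnames(gt)),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$gt), "variants x", ncol(x$gt), "samples (",
      sum(x$info$kind == "SV"), "SV /", sum(x$info$kind == "SNP"), "SNP )\n")
  invisible(x)
}

#' Combine an SV catalog and a SNP genotype matrix
#'
#' Builds the combined dosage matrix used for SV-SNP linkage disequilibrium.
#' SV position is the start coordinate. Sample rosters must agree.
#' @param catalog An `sv_catalog`.
#' @param snps A `genotype_matrix` of kind SNP.
#' @export
combine_genotypes <- function(catalog, snps) {
  if (!identical(sort(catalog$samples), sort(snps$samples)))
    stop("sample rosters of catalog and SNP matrix differ")
  sv_info <- data.frame(id = catalog$variants$id, chrom = catalog$variants$chrom,
                        pos = catalog$variants$start, kind = "SV",
                        stringsAsFactors = FALSE)
  genotype_matrix(rbind(catalog$genotypes[, snps$samples, drop = FALSE], snps$gt),
                  rbind(sv_info, snps$info))
}
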