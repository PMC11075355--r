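# Readers/writers for the standard formats every stage touches. Internal
# coordinates are 1-based inclusive; BED input/output converts at the border.

gt_string_to_dosage <- function(gt) {
  gt <- sub(":.*", "", gt)
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

dosage_to_gt_string <- function(d) {
  c("0/0", "0/1", "1/1")[d + 1L] -> s
  s[is.na(d)] <- "./."
  s
}

#' Read a structural variant catalog from VCF
#'
#' Accepts the symbolic-allele VCF 4.2 dialect (`<DEL>`, `<DUP>`, `<INV>`,
#' `<INS:ME>`, and breakend notation for BND). INFO keys used: `SVTYPE`
#' (required; records without it are rejected with a logged reason), `END`
#' and/or `SVLEN`, `MSQ`, `MINSIZE95`, `MATEID`. FORMAT fields `GT` and, when
#' present, `SR`, `PE`, `AB`, `CN` populate the per-sample matrices.
#'
#' `END` is interpreted as the last affected base, so `length = END - POS + 1`
#' for non-BND records; if both `END` and `SVLEN` are present they must agree
#' under that convention. Intra-chromosomal breakend lengths are the absolute
#' difference of the two junction positions; when mates are paired by
#' `MATEID`, only the first mate of each pair is kept as the record.
#'
#' @param path VCF file.
#' @param samples Optional expected sample roster (checked).
#' @return An `sv_catalog`.
#' @export
read_sv_vcf <- function(path, samples = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info1 <- function(key) suppressWarnings(vcfR::extract.info(vcf, key))
  svtype <- info1("SVTYPE")
  keep <- !is.na(svtype) & nzchar(svtype)
  if (any(!keep))
    message("rejected ", sum(!keep), " record(s) without SVTYPE")
  endi <- suppressWarnings(as.numeric(info1("END")))
  svlen <- suppressWarnings(as.numeric(info1("SVLEN")))
  msq <- suppressWarnings(as.numeric(info1("MSQ")))
  ms95 <- suppressWarnings(as.numeric(info1("MINSIZE95")))
  mateid <- info1("MATEID")
  pos <- as.numeric(fix$POS)
  alt <- fix$ALT

  n <- nrow(fix)
  start <- pos; end <- rep(NA_real_, n); len <- rep(NA_real_, n)
  for (i in which(keep)) {
    if (svtype[i] == "BND") {
      m <- regmatches(alt[i],
                      regexec("[\\[\\]]([^:\\[\\]]+):([0-9]+)[\\[\\]]",
                              alt[i], perl = TRUE))[[1]]
      if (length(m)) {
        mchrom <- m[2]; mpos <- as.numeric(m[3])
        if (identical(mchrom, fix$CHROM[i])) {
          start[i] <- min(pos[i], mpos); end[i] <- max(pos[i], mpos)
          len[i] <- end[i] - start[i]
        } else {
          end[i] <- pos[i]          # inter-chromosomal: no length
        }
      } else end[i] <- pos[i]
    } else {
      if (!is.na(endi[i])) {
        end[i] <- endi[i]
        len[i] <- end[i] - pos[i] + 1
        if (!is.na(svlen[i]) && abs(svlen[i]) != len[i])
          stop("record ", i, ": END (", endi[i], ") and SVLEN (", svlen[i],
               ") are mutually inconsistent under the inclusive convention")
      } else if (!is.na(svlen[i])) {
        len[i] <- abs(svlen[i])
        end[i] <- pos[i] + len[i] - 1
      } else stop("record ", i, ": neither END nor SVLEN present")
    }
  }

  # drop second mates of MATEID-paired breakends
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | !nzchar(ids)
  ids[no_id] <- sv_id(fix$CHROM[no_id], start[no_id], end[no_id], svtype[no_id])
  second_mate <- rep(FALSE, n)
  if (!all(is.na(mateid))) {
    seen <- character()
    for (i in which(keep & svtype == "BND")) {
      if (!is.na(mateid[i]) && mateid[i] %in% seen) second_mate[i] <- TRUE
      seen <- c(seen, ids[i])
    }
  }
  keep <- keep & !second_mate

  fmt <- function(key, numeric = TRUE) {
    if (is.null(vcf@gt) || !any(grepl(key, vcf@gt[, "FORMAT"]))) return(NULL)
    m <- vcfR::extract.gt(vcf, element = key, as.numeric = numeric)
    m[keep, , drop = FALSE]
  }
  gtc <- vcfR::extract.gt(vcf, element = "GT")
  dos <- apply(gtc[keep, , drop = FALSE], 2, gt_string_to_dosage)
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = sum(keep),
                                     dimnames = list(NULL, colnames(gtc)))
  if (!is.null(samples) && !identical(sort(colnames(dos)), sort(samples)))
    stop("VCF sample roster differs from expected roster")

  variants <- data.frame(id = ids[keep], chrom = fix$CHROM[keep],
                         start = start[keep], end = end[keep],
                         svtype = svtype[keep], length = len[keep],
                         msq = msq[keep], min_size_95 = ms95[keep],
                         stringsAsFactors = FALSE)
  sv_catalog(variants, dos, colnames(dos),
             sr_support = fmt("SR"), pe_support = fmt("PE"),
             allele_balance = fmt("AB"), copy_number = fmt("CN"),
             provenance = paste("read from", path))
}

#' Write a structural variant catalog as VCF 4.2
#'
#' Symbolic ALT alleles (`<DEL>`, `<DUP>`, `<INV>`, `<INS:ME>`) and breakend
#' notation for BND. Round-trips through [read_sv_vcf()].
#' @param catalog An `sv_catalog`.
#' @param path Output file.
#' @param genome Optional `genome_model` for contig header lines.
#' @export
write_sv_vcf <- function(catalog, path, genome = NULL) {
  v <- catalog$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=svcat",
           if (!is.null(genome))
             sprintf("##contig=<ID=%s,length=%d>", names(genome$chrom_lengths),
                     as.integer(genome$chrom_lengths)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"Last affected base\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=MSQ,Number=1,Type=Float,Description=\"Mean sample quality\">",
           "##INFO=<ID=MINSIZE95,Number=1,Type=Integer,Description=\"Minimum genotypable size at 95% confidence\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=SR,Number=1,Type=Integer,Description=\"Split-read support\">",
           "##FORMAT=<ID=PE,Number=1,Type=Integer,Description=\"Paired-end support\">",
           "##FORMAT=<ID=AB,Number=1,Type=Float,Description=\"Allele balance\">",
           "##FORMAT=<ID=CN,Number=1,Type=Float,Description=\"Copy number\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", catalog$samples), collapse = "\t"))
  alt <- ifelse(v$svtype == "MEI", "<INS:ME>",
         ifelse(v$svtype == "BND",
                sprintf("N[%s:%d[", v$chrom, as.integer(v$end)),
                sprintf("<%s>", v$svtype)))
  info <- sprintf("SVTYPE=%s", v$svtype)
  nb <- v$svtype != "BND"
  info[nb] <- sprintf("%s;END=%d;SVLEN=%d", info[nb], as.integer(v$end[nb]),
                      as.integer(v$length[nb]))
  info <- ifelse(is.na(v$msq), info, sprintf("%s;MSQ=%g", info, v$msq))
  info <- ifelse(is.na(v$min_size_95), info,
                 sprintf("%s;MINSIZE95=%d", info, as.integer(v$min_size_95)))

  fields <- list(GT = apply(catalog$genotypes, 2, dosage_to_gt_string))
  for (key in c("SR", "PE", "AB", "CN")) {
    slot <- switch(key, SR = "sr_support", PE = "pe_support",
                   AB = "allele_balance", CN = "copy_number")
    m <- catalog[[slot]]
    if (!is.null(m)) {
      s <- matrix(ifelse(is.na(m), ".", format(m, trim = TRUE, digits = 6)),
                  nrow = nrow(m))
      fields[[key]] <- s
    }
  }
  fields <- lapply(fields, function(m) {
    if (!is.matrix(m)) m <- matrix(m, nrow = nrow(v))
    m
  })
  fmt_key <- paste(names(fields), collapse = ":")
  samp_cols <- Reduce(function(a, b) matrix(paste(a, b, sep = ":"), nrow = nrow(a)),
                      fields)
  body <- paste(v$chrom, as.integer(v$start), v$id, "N", alt, ".", "PASS",
                info, fmt_key, sep = "\t")
  body <- paste(body, apply(samp_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read SNP genotypes from VCF into a genotype matrix
#' @param path VCF file with GT calls.
#' @return A `genotype_matrix` of kind SNP.
#' @export
read_snp_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gtc <- vcfR::extract.gt(vcf, element = "GT")
  dos <- apply(gtc, 2, gt_string_to_dosage)
  if (!is.matrix(dos)) dos <- matrix(dos, nrow = nrow(fix),
                                     dimnames = list(NULL, colnames(gtc)))
  ids <- fix$ID
  no_id <- is.na(ids) | ids == "." | !nzchar(ids)
  ids[no_id] <- paste0(fix$CHROM[no_id], ":", fix$POS[no_id])
  genotype_matrix(dos, data.frame(id = ids, chrom = fix$CHROM,
                                  pos = as.numeric(fix$POS), kind = "SNP",
                                  stringsAsFactors = FALSE))
}

#' Write SNP genotypes as a minimal VCF
#' @param gm A `genotype_matrix` of kind SNP.
#' @param path Output file.
#' @export
write_snp_vcf <- function(gm, path) {
  hdr <- c("##fileformat=VCFv4.2", "##source=svcat",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", gm$samples), collapse = "\t"))
  gts <- apply(gm$gt, 2, dosage_to_gt_string)
  if (!is.matrix(gts)) gts <- matrix(gts, nrow = nrow(gm$gt))
  body <- paste(gm$info$chrom, as.integer(gm$info$pos), gm$info$id,
                "A", "G", ".", "PASS", ".", "GT", sep = "\t")
  body <- paste(body, apply(gts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a BED-like file into a feature track
#'
#' BED coordinates (0-based, half-open) are converted to the internal 1-based
#' inclusive convention. Columns: chrom, start, end, label, optional tissue.
#' @param path BED-like TSV without header.
#' @param name Track name.
#' @param vocabulary Optional allowed label set (out-of-vocabulary = error).
#' @return A `feature_track`.
#' @export
read_feature_track <- function(path, name = basename(path), vocabulary = NULL) {
  d <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  if (ncol(d) < 4L) stop("feature track needs >= 4 columns (chrom,start,end,label)")
  names(d)[1:4] <- c("chrom", "start", "end", "label")
  tissue <- if (ncol(d) >= 5L) as.character(d[[5]]) else NA_character_
  feature_track(name, d$chrom, bed_to_internal_start(d$start), d$end,
                as.character(d$label), tissue = tissue, vocabulary = vocabulary)
}

#' Write a feature track as BED (0-based half-open)
#' @param track A `feature_track`.
#' @param path Output file.
#' @export
write_feature_track <- function(track, path) {
  gr <- track$ranges
  d <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                  start = internal_to_bed_start(GenomicRanges::start(gr)),
                  end = GenomicRanges::end(gr),
                  label = S4Vectors::mcols(gr)$label,
                  tissue = S4Vectors::mcols(gr)$tissue)
  if (all(is.na(d$tissue))) d$tissue <- NULL
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population TSV
#'
#' Expects header columns `sample_id`, `population`, optionally
#' `subpopulation`. When `samples` is supplied, every catalog sample must be
#' present (missing samples are an error naming them).
#' @param path TSV file.
#' @param samples Optional roster to validate against.
#' @return A `population_map`.
#' @export
read_population_map <- function(path, samples = NULL) {
  d <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!all(c("sample_id", "population") %in% names(d)))
    stop("population map needs columns sample_id, population")
  pm <- population_map(as.character(d$sample_id), as.character(d$population),
                       if ("subpopulation" %in% names(d))
                         as.character(d$subpopulation) else NA_character_)
  if (!is.null(samples)) check_population_map(pm, samples)
  pm
}

#' Write a population map as TSV
#' @param pop_map A `population_map`.
#' @param path Output file.
#' @export
write_population_map <- function(pop_map, path) {
  data.table::fwrite(pop_map[, c("sample_id", "population", "subpopulation")],
                     path, sep = "\t")
  invisible(path)
}

#' Write a list of result tables as TSV files
#' @param tables Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(as.data.frame(tables[[nm]]), p, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
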