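#' Build a gene model
#'
#' A gene is a set of transcripts, each with exon and optional CDS/UTR
#' intervals (1-based inclusive). The model stores per-transcript structure
#' plus the union (over transcripts) of exons, CDS, 5'UTR and 3'UTR — the
#' canonical feature set used by the impact classifier.
#'
#' @param gene_id Gene identifier.
#' @param chrom,strand Location; strand "+" or "-".
#' @param biotype "protein_coding" or other.
#' @param transcripts Named list; each element a list with data.frames
#'   `exons`, and optionally `cds`, `utr5`, `utr3`, each with `start`/`end`.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, biotype, transcripts) {
  if (!length(transcripts)) stop("gene '", gene_id, "' has no transcripts")
  as_ir <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return(IRanges::IRanges())
    IRanges::IRanges(df$start, df$end)
  }
  un <- function(field) {
    IRanges::reduce(do.call(c, unname(lapply(transcripts, function(tx) as_ir(tx[[field]])))))
  }
  exons <- un("exons")
  if (length(exons) == 0L) stop("gene '", gene_id, "' has no exons")
  cds <- un("cds"); utr5 <- un("utr5"); utr3 <- un("utr3")
  within_exons <- function(ir) {
    length(ir) == 0L || sum(IRanges::width(IRanges::setdiff(ir, exons))) == 0L
  }
  if (!within_exons(cds))
    stop("gene '", gene_id, "': CDS outside exon bounds")
  if (!within_exons(utr5) || !within_exons(utr3))
    stop("gene '", gene_id, "': UTR outside exon bounds")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 biotype = biotype, transcripts = transcripts,
                 body_start = min(IRanges::start(exons)),
                 body_end = max(IRanges::end(exons)),
                 exons = exons, cds = cds, utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

#' Collect gene models into an indexed set
#' @param genes List of `gene_model` objects.
#' @return Object of class `gene_model_set` with a `bodies` GRanges index.
#' @export
gene_model_set <- function(genes) {
  if (length(genes) == 0L) {
    return(structure(list(genes = list(), bodies = GenomicRanges::GRanges()),
                     class = "gene_model_set"))
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  bodies <- GenomicRanges::GRanges(
    vapply(genes, `[[`, "", "chrom"),
    IRanges::IRanges(vapply(genes, function(g) g$body_start, 0),
                     vapply(genes, function(g) g$body_end, 0)),
    strand = vapply(genes, `[[`, "", "strand")
  )
  names(bodies) <- names(genes)
  S4Vectors::mcols(bodies)$biotype <- vapply(genes, `[[`, "", "biotype")
  structure(list(genes = genes, bodies = bodies), class = "gene_model_set")
}

#' @method print gene_model_set
#' @export
print.gene_model_set <- function(x, ...) {
  cat("gene_model_set:", length(x$genes), "genes (",
      sum(S4Vectors::mcols(x$bodies)$biotype == "protein_coding"),
      "protein-coding )\n")
  invisible(x)
}

#' @export
length.gene_model_set <- function(x) length(x$genes)

#' Read gene models from GFF3 and apply catalog gene filtering
#'
#' Genes on chromosomes outside `placed_chroms` (unplaced scaffolds) and genes
#' whose id is in `retired_ids` (superseded annotation versions) are removed,
#' mirroring the reference-annotation clean-up that retains only current,
#' placed genes. Removal counts are attached as the `"filter_counts"`
#' attribute. Genes whose CDS falls outside exon bounds are flagged invalid
#' and excluded with a message.
#'
#' @param path GFF3 file with gene/mRNA (or transcript)/exon/CDS/UTR features.
#' @param retired_ids Character vector of retired gene ids.
#' @param placed_chroms Chromosomes considered placed; `NULL` keeps all.
#' @return A `gene_model_set`.
#' @export
read_gene_models <- function(path, retired_ids = character(), placed_chroms = NULL) {
  gff <- rtracklayer::import(path, format = "gff3")
  if (length(gff) == 0L) {
    warning("empty GFF: no gene models read")
    gms <- gene_model_set(list())
    attr(gms, "filter_counts") <- c(total = 0L, retired = 0L, unplaced = 0L,
                                    invalid = 0L, retained = 0L)
    return(gms)
  }
  typ <- as.character(gff$type)
  ids <- as.character(gff$ID)
  parent <- vapply(gff$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  genes_gr <- gff[typ == "gene"]
  gene_ids <- as.character(genes_gr$ID)
  n_total <- length(gene_ids)
  is_retired <- gene_ids %in% retired_ids
  is_unplaced <- if (is.null(placed_chroms)) rep(FALSE, n_total) else
    !as.character(GenomeInfoDb::seqnames(genes_gr)) %in% placed_chroms
  keep_ids <- gene_ids[!is_retired & !is_unplaced]

  tx_rows <- typ %in% c("mRNA", "transcript")
  feat_map <- c(exon = "exons", CDS = "cds",
                five_prime_UTR = "utr5", three_prime_UTR = "utr3")
  n_invalid <- 0L
  models <- list()
  for (gid in keep_ids) {
    g <- genes_gr[gene_ids == gid]
    tx_ids <- ids[tx_rows & parent == gid]
    txs <- lapply(tx_ids, function(tid) {
      rows <- gff[!is.na(parent) & parent == tid & typ %in% names(feat_map)]
      out <- list()
      for (ft in names(feat_map)) {
        r <- rows[as.character(rows$type) == ft]
        out[[feat_map[[ft]]]] <- data.frame(start = GenomicRanges::start(r),
                                            end = GenomicRanges::end(r))
      }
      out
    })
    names(txs) <- tx_ids
    gm <- tryCatch(
      gene_model(gid, as.character(GenomeInfoDb::seqnames(g)),
                 as.character(GenomicRanges::strand(g)),
                 as.character(g$biotype %||% "protein_coding"), txs),
      error = function(e) {
        message("excluding invalid gene model: ", conditionMessage(e))
        NULL
      })
    if (is.null(gm)) n_invalid <- n_invalid + 1L else models[[gid]] <- gm
  }
  gms <- gene_model_set(models)
  attr(gms, "filter_counts") <- c(total = n_total, retired = sum(is_retired),
                                  unplaced = sum(is_unplaced),
                                  invalid = n_invalid,
                                  retained = length(models))
  gms
}

#' Write gene models as GFF3
#' @param genes A `gene_model_set`.
#' @param path Output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  fmt <- function(chrom, type, start, end, strand, attrs) {
    sprintf("%s\tsvcat\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, as.integer(start), as.integer(end), strand, attrs)
  }
  for (g in genes$genes) {
    lines <- c(lines, fmt(g$chrom, "gene", g$body_start, g$body_end, g$strand,
                          sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype)))
    for (tid in names(g$transcripts)) {
      tx <- g$transcripts[[tid]]
      ex <- tx$exons
      lines <- c(lines, fmt(g$chrom, "mRNA", min(ex$start), max(ex$end), g$strand,
                            sprintf("ID=%s;Parent=%s", tid, g$gene_id)))
      emit <- function(df, type) {
        if (is.null(df) || nrow(df) == 0L) return(character())
        fmt(g$chrom, type, df$start, df$end, g$strand, sprintf("Parent=%s", tid))
      }
      lines <- c(lines, emit(tx$exons, "exon"), emit(tx$cds, "CDS"),
                 emit(tx$utr5, "five_prime_UTR"), emit(tx$utr3, "three_prime_UTR"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
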