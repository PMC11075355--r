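# SV-SNP linkage disequilibrium: windowed dosage r-squared, the
# linked/tagged/highly-tagged tiers, positional thinning, and assembly of the
# SV / functional-SNP / gene / trait network.

#' Tier thresholds on r-squared
#' @export
LD_TIERS <- c(linked = 0.2, tagged = 0.5, highly_tagged = 0.8)

#' Pairwise dosage r-squared within a genomic window
#'
#' r-squared is the squared Pearson correlation of dosage vectors over the
#' samples non-missing at both variants (composite LD on genotypes — no
#' phasing), for same-chromosome pairs at distance <= `window`. Pairs where
#' either vector has zero variance are skipped. Records with r-squared
#' strictly above `min_r2` are emitted.
#'
#' @param gm A `genotype_matrix` (e.g. from [combine_genotypes()]).
#' @param window Maximum pair distance in bp (default 1 Mb).
#' @param min_r2 Emission threshold (default 0: all positive r2 kept).
#' @param pairs "all" or "sv_snp" (only SV-SNP pairs).
#' @return data.frame `id_a`, `id_b`, `chrom`, `distance`, `r2`, `tier`
#'   with `id_a` the left (or SV) variant.
#' @export
ld_r2_window <- function(gm, window = 1e6, min_r2 = 0,
                         pairs = c("all", "sv_snp")) {
  pairs <- match.arg(pairs)
  info <- gm$info
  out <- list()
  for (chrom in unique(info$chrom)) {
    idx <- which(info$chrom == chrom)
    idx <- idx[order(info$pos[idx])]
    if (length(idx) < 2L) next
    pos <- info$pos[idx]
    sub <- t(gm$gt[idx, , drop = FALSE])   # samples x variants
    use_matrix <- length(idx) <= 4000L
    cors <- if (use_matrix)
      suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
    else NULL
    ii <- jj <- integer(0)
    for (i in seq_len(length(idx) - 1L)) {
      jmax <- i + findInterval(pos[i] + window, pos[(i + 1):length(idx)])
      if (jmax < i + 1L) next
      ii <- c(ii, rep(i, jmax - i)); jj <- c(jj, (i + 1L):jmax)
    }
    if (!length(ii)) next
    if (pairs == "sv_snp") {
      kind <- info$kind[idx]
      cross <- kind[ii] != kind[jj]
      ii <- ii[cross]; jj <- jj[cross]
      if (!length(ii)) next
    }
    r <- if (use_matrix) cors[cbind(ii, jj)] else
      vapply(seq_along(ii), function(k)
        suppressWarnings(stats::cor(sub[, ii[k]], sub[, jj[k]],
                                    use = "pairwise.complete.obs")), 0)
    r2 <- r^2
    ok <- !is.na(r2) & r2 > min_r2
    if (!any(ok)) next
    a <- idx[ii[ok]]; b <- idx[jj[ok]]
    # put the SV first in SV-SNP pairs
    swap <- info$kind[a] == "SNP" & info$kind[b] == "SV"
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    out[[chrom]] <- data.frame(
      id_a = info$id[a], id_b = info$id[b], chrom = chrom,
      distance = abs(info$pos[b] - info$pos[a]), r2 = r2[ok],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
  else data.frame(id_a = character(), id_b = character(), chrom = character(),
                  distance = numeric(), r2 = numeric())
  res$tier <- assign_tiers(res$r2)
  res
}

#' Assign LD tiers to r-squared values
#'
#' Tiers are nested: linked at r2 >= 0.2, tagged at r2 >= 0.5, highly-tagged
#' at r2 >= 0.8; the returned label is the highest tier reached ("none"
#' below 0.2).
#' @param r2 Numeric vector of r-squared values.
#' @param thresholds Named thresholds (default [LD_TIERS]).
#' @return Character vector of tier labels.
#' @export
assign_tiers <- function(r2, thresholds = LD_TIERS) {
  out <- rep("none", length(r2))
  out[r2 >= thresholds[["linked"]]] <- "linked"
  out[r2 >= thresholds[["tagged"]]] <- "tagged"
  out[r2 >= thresholds[["highly_tagged"]]] <- "highly_tagged"
  out
}

#' Greedy positional thinning
#'
#' Scans each chromosome in position order and keeps a variant iff its
#' distance from the last kept variant is at least `min_gap` (the first
#' variant of each chromosome is always kept). Deterministic, order-free
#' interpretation of "one variant per `min_gap` bp".
#' @param positions Numeric positions.
#' @param chrom Optional chromosome per position (single chromosome if NULL).
#' @param min_gap Minimum spacing in bp (default 1000).
#' @return Logical vector: TRUE for retained positions.
#' @export
thin_variants <- function(positions, chrom = NULL, min_gap = 1000) {
  if (is.null(chrom)) chrom <- rep("*", length(positions))
  keep <- rep(FALSE, length(positions))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    idx <- idx[order(positions[idx])]
    last <- -Inf
    for (i in idx) {
      if (positions[i] - last >= min_gap) {
        keep[i] <- TRUE
        last <- positions[i]
      }
    }
  }
  keep
}

#' Functional-variant catalog (e/sQTL, GWAS, TWAS records)
#'
#' @param records data.frame with columns `kind` in \{eQTL, sQTL, GWAS,
#'   TWAS\}, `snp_id`/`chrom`/`pos` (SNP kinds), `gene_id` (e/sQTL target or
#'   TWAS gene), `tissue`, `trait` (GWAS/TWAS), `p` (GWAS), `fdr` (TWAS).
#' @return The validated data.frame with class `functional_catalog`.
#' @export
functional_catalog <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in c("kind", "snp_id", "gene_id", "tissue", "trait", "p", "fdr"))
    if (is.null(records[[col]]))
      records[[col]] <- rep(if (col %in% c("p", "fdr")) NA_real_
                            else NA_character_, nrow(records))
  bad <- setdiff(unique(records$kind), c("eQTL", "sQTL", "GWAS", "TWAS"))
  if (length(bad)) stop("unknown record kinds: ", paste(bad, collapse = ", "))
  if (any(records$kind == "GWAS" & is.na(records$p)))
    stop("GWAS records must carry a p-value")
  if (any(records$kind == "TWAS" & is.na(records$fdr)))
    stop("TWAS records must carry an FDR")
  if (any(records$kind %in% c("eQTL", "sQTL") & is.na(records$gene_id)))
    stop("e/sQTL records must carry a target gene")
  class(records) <- c("functional_catalog", "data.frame")
  records
}

#' Assemble the SV / functional-SNP / gene / trait network
#'
#' LD edges are kept for SV-SNP pairs with r2 >= `r2_min` (and distance
#' already bounded by the linkage window) whose SNP is functional: any e/sQTL,
#' or a GWAS locus with p <= `gwas_p_max`. TWAS genes pass at FDR <=
#' `twas_fdr_max` and only if also detected as eGene or sGene. SV-gene edges
#' are added when the SV overlaps the gene body extended by `gene_flank` bp
#' on both sides.
#'
#' @param svs An `sv_catalog` (or named `GRanges`) for SV-gene overlap.
#' @param linkage Output of [ld_r2_window()] (SV-SNP rows are used).
#' @param functional A `functional_catalog`.
#' @param genes A `gene_model_set`.
#' @param r2_min LD threshold (default 0.2).
#' @param gwas_p_max GWAS significance bound (default 5e-8).
#' @param twas_fdr_max TWAS FDR bound (default 0.05).
#' @param gene_flank Gene-body extension in bp (default 5000).
#' @return list of class `functional_network`: `nodes` (id, type), `edges`
#'   (from, to, type, weight), and `summary` (per-SV linked kinds).
#' @export
build_functional_network <- function(svs, linkage, functional, genes,
                                     r2_min = 0.2, gwas_p_max = 5e-8,
                                     twas_fdr_max = 0.05, gene_flank = 5000) {
  sv_gr <- if (inherits(svs, "sv_catalog")) sv_ranges(svs) else svs
  esql <- functional[functional$kind %in% c("eQTL", "sQTL"), , drop = FALSE]
  gwas <- functional[functional$kind == "GWAS" &
                       functional$p <= gwas_p_max, , drop = FALSE]
  esgenes <- unique(esql$gene_id)
  twas <- functional[functional$kind == "TWAS" &
                       functional$fdr <= twas_fdr_max &
                       functional$gene_id %in% esgenes, , drop = FALSE]
  functional_snps <- unique(c(esql$snp_id, gwas$snp_id))

  ld <- linkage[linkage$r2 >= r2_min & linkage$id_b %in% functional_snps, ,
                drop = FALSE]
  edges <- list()
  if (nrow(ld))
    edges$ld <- data.frame(from = ld$id_a, to = ld$id_b, type = "ld",
                           weight = ld$r2)
  keep_snps <- unique(ld$id_b)
  eq <- esql[esql$snp_id %in% keep_snps, , drop = FALSE]
  if (nrow(eq))
    edges$esqtl <- data.frame(from = eq$snp_id, to = eq$gene_id,
                              type = paste0(tolower(substr(eq$kind, 1, 1)),
                                            "qtl_gene"),
                              weight = NA_real_)
  gw <- gwas[gwas$snp_id %in% keep_snps, , drop = FALSE]
  if (nrow(gw))
    edges$gwas <- data.frame(from = gw$snp_id, to = gw$trait,
                             type = "gwas_trait", weight = gw$p)
  if (nrow(twas))
    edges$twas <- data.frame(from = twas$gene_id, to = twas$trait,
                             type = "twas_trait", weight = twas$fdr)

  # SV-gene overlap (direct or +/- flank around the gene body)
  linked_svs <- unique(ld$id_a)
  if (length(linked_svs) && length(genes)) {
    ext <- GenomicRanges::trim(GenomicRanges::resize(
      genes$bodies, GenomicRanges::width(genes$bodies) + 2 * gene_flank,
      fix = "center"))
    sub <- sv_gr[names(sv_gr) %in% linked_svs]
    hits <- GenomicRanges::findOverlaps(sub, ext, ignore.strand = TRUE)
    if (length(hits))
      edges$sv_gene <- data.frame(
        from = names(sub)[S4Vectors::queryHits(hits)],
        to = names(ext)[S4Vectors::subjectHits(hits)],
        type = "sv_gene", weight = NA_real_)
  }
  edges <- if (length(edges)) do.call(rbind, c(edges, list(make.row.names = FALSE)))
  else data.frame(from = character(), to = character(), type = character(),
                  weight = numeric())

  node_of <- function(ids, type) if (length(ids))
    data.frame(id = unique(ids), type = type) else NULL
  nodes <- rbind(
    node_of(names(sv_gr), "SV"),
    node_of(keep_snps, "SNP"),
    node_of(c(eq$gene_id, twas$gene_id,
              edges$to[edges$type == "sv_gene"]), "gene"),
    node_of(c(gw$trait, twas$trait), "trait"))

  kinds_by_sv <- NULL
  if (nrow(ld)) {
    kind_of_snp <- function(sid) {
      k <- character()
      if (sid %in% esql$snp_id[esql$kind == "eQTL"]) k <- c(k, "eQTL")
      if (sid %in% esql$snp_id[esql$kind == "sQTL"]) k <- c(k, "sQTL")
      if (sid %in% gwas$snp_id) k <- c(k, "GWAS")
      k
    }
    kinds_by_sv <- do.call(rbind, lapply(split(ld$id_b, ld$id_a), function(s) {
      k <- unique(unlist(lapply(unique(s), kind_of_snp)))
      data.frame(n_snps = length(unique(s)),
                 kinds = paste(sort(k), collapse = ","),
                 n_kinds = length(k))
    }))
    kinds_by_sv <- data.frame(sv_id = rownames(kinds_by_sv), kinds_by_sv,
                              row.names = NULL)
  }
  structure(list(nodes = nodes, edges = edges, summary = kinds_by_sv),
            class = "functional_network")
}

#' @method print functional_network
#' @export
print.functional_network <- function(x, ...) {
  cat("functional_network:", nrow(x$nodes %||% data.frame()), "nodes,",
      nrow(x$edges), "edges\n")
  if (!is.null(x$nodes)) print(table(x$nodes$type))
  invisible(x)
}

#' Write a functional network as node/edge TSVs plus a JSON graph
#' @param network A `functional_network`.
#' @param dir Output directory.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(network$nodes %||%
                       data.frame(id = character(), type = character()),
                     file.path(dir, "nodes.tsv"), sep = "\t")
  data.table::fwrite(network$edges, file.path(dir, "edges.tsv"), sep = "\t")
  jsonlite::write_json(list(nodes = network$nodes, edges = network$edges),
                       file.path(dir, "network.json"), dataframe = "rows",
                       na = "null")
  invisible(dir)
}
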