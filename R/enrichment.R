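# Overlap-proportion and enrichment statistics: fold tests against the
# genomic background with Pearson chi-squared (no continuity correction),
# per-genome singleton-proportion t-tests, chromatin-state proportions,
# regulator location ratios, QTL enrichment and the cross-population ANOVA.

pearson_chi2_2x2 <- function(a, b, c, d) {
  # cells: a=in both, b=row1 only, c=row2/col1, d=neither
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  expected_a <- (a + b) * (a + c) / n
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

chi2_gof_2cell <- function(obs_in, obs_out, p_in) {
  obs_in <- as.numeric(obs_in); obs_out <- as.numeric(obs_out)
  n <- obs_in + obs_out
  e_in <- n * p_in; e_out <- n * (1 - p_in)
  stat <- (obs_in - e_in)^2 / e_in + (obs_out - e_out)^2 / e_out
  if (!is.finite(stat)) stat <- 0
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Fold enrichment of features in SV space versus the genome
#'
#' The fold is the proportion of the feature inside the (merged) SV set
#' divided by the proportion of the feature in the whole genome. `units =
#' "bp"` tests the 2x2 base-pair contingency \{in/out of SV\} x \{in/out of
#' feature\} with Pearson chi-squared; `units = "count"` treats feature
#' elements as units and tests the observed in-SV element count against the
#' genome-wide SV coverage with a 1-df goodness-of-fit chi-squared.
#' P values are Bonferroni-adjusted over the labels tested in the same call.
#'
#' @param svs `GRanges` of SV intervals (or an `sv_catalog`); merged to a
#'   non-redundant set before bp accounting.
#' @param feature A `feature_track` (one test per label) or a `GRanges`.
#' @param genome A `genome_model`.
#' @param units "bp" (default) or "count".
#' @param alpha Significance threshold on the adjusted p (default 0.01).
#' @return data.frame, one row per feature label: bp/count accounting, fold,
#'   chi-squared statistic, raw and Bonferroni-adjusted p, significance flag.
#' @export
fold_enrichment <- function(svs, feature, genome, units = c("bp", "count"),
                            alpha = 0.01) {
  units <- match.arg(units)
  if (inherits(svs, "sv_catalog")) svs <- sv_ranges(svs)
  if (length(svs) == 0L) stop("empty SV set")
  sv_m <- GenomicRanges::reduce(svs, ignore.strand = TRUE)
  g_bp <- genome_bp(genome)
  sv_bp <- reduced_bp(sv_m)
  gr <- if (inherits(feature, "feature_track")) feature$ranges else feature
  label <- if (inherits(feature, "feature_track"))
    S4Vectors::mcols(gr)$label else rep("feature", length(gr))
  labels <- sort(unique(label))

  # merge per label in one pass, then one overlap query for all labels
  grl <- GenomicRanges::reduce(
    GenomicRanges::split(GenomicRanges::granges(gr), factor(label, labels)))
  f_bp <- vapply(GenomicRanges::width(grl), function(w) sum(as.numeric(w)), 0)
  if (any(f_bp == 0))
    stop("feature '", labels[which(f_bp == 0)[1]],
         "' covers zero genome bp")
  merged <- unlist(grl, use.names = FALSE)
  mlab <- rep(labels, lengths(grl))
  hits <- GenomicRanges::findOverlaps(merged, sv_m, ignore.strand = TRUE)
  piece_bp <- numeric(0); piece_lab <- character(0)
  if (length(hits)) {
    pieces <- GenomicRanges::pintersect(merged[S4Vectors::queryHits(hits)],
                                        sv_m[S4Vectors::subjectHits(hits)])
    piece_bp <- as.numeric(GenomicRanges::width(pieces))
    piece_lab <- mlab[S4Vectors::queryHits(hits)]
  }
  in_bp <- stats::setNames(numeric(length(labels)), labels)
  if (length(piece_bp)) {
    agg <- rowsum(piece_bp, piece_lab)
    in_bp[rownames(agg)] <- agg[, 1]
  }

  rows <- lapply(seq_along(labels), function(k) {
    fold <- (in_bp[k] / sv_bp) / (f_bp[k] / g_bp)
    if (units == "bp") {
      ct <- pearson_chi2_2x2(in_bp[k], sv_bp - in_bp[k], f_bp[k] - in_bp[k],
                             g_bp - sv_bp - f_bp[k] + in_bp[k])
      data.frame(label = labels[k], bp_in_sv = unname(in_bp[k]),
                 sv_bp = sv_bp, feature_bp = f_bp[k], genome_bp = g_bp,
                 n_in_sv = NA_integer_, n_total = NA_integer_,
                 fold = unname(fold), chi2 = ct$statistic, p = ct$p)
    } else {
      f <- gr[label == labels[k]]
      n_in <- sum(GenomicRanges::countOverlaps(f, sv_m,
                                               ignore.strand = TRUE) > 0)
      n_tot <- length(f)
      ct <- chi2_gof_2cell(n_in, n_tot - n_in, sv_bp / g_bp)
      data.frame(label = labels[k], bp_in_sv = unname(in_bp[k]),
                 sv_bp = sv_bp, feature_bp = f_bp[k], genome_bp = g_bp,
                 n_in_sv = n_in, n_total = n_tot,
                 fold = (n_in / n_tot) / (sv_bp / g_bp),
                 chi2 = ct$statistic, p = ct$p)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$significant <- out$p_adj <= alpha
  out
}

#' Disjoint genic partition of a genome
#'
#' Splits the genome into CDS, 5'UTR, 3'UTR, other exon, intron and
#' intergenic space (priority CDS > 5'UTR > 3'UTR > exon > intron), for
#' protein-coding genes.
#' @param genes A `gene_model_set`.
#' @param genome A `genome_model`.
#' @return A `feature_track` named "genic_partition".
#' @export
genic_partition <- function(genes, genome) {
  pc <- genes$genes[vapply(genes$genes, function(g)
    g$biotype == "protein_coding", TRUE)]
  gr_of <- function(field) {
    if (!length(pc)) return(GenomicRanges::GRanges())
    suppressWarnings(do.call(c, unname(lapply(pc, function(g) {
      ir <- g[[field]]
      if (length(ir) == 0L) return(GenomicRanges::GRanges())
      GenomicRanges::GRanges(g$chrom, ir)
    }))))
  }
  bodies <- if (length(pc))
    GenomicRanges::reduce(suppressWarnings(do.call(c, unname(lapply(
      pc, function(g)
        GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$body_start,
                                                         g$body_end)))))))
  else GenomicRanges::GRanges()
  sdiff <- function(a, b)
    suppressWarnings(GenomicRanges::setdiff(a, b, ignore.strand = TRUE))
  cds <- GenomicRanges::reduce(gr_of("cds"))
  utr5 <- sdiff(GenomicRanges::reduce(gr_of("utr5")), cds)
  utr3 <- sdiff(GenomicRanges::reduce(gr_of("utr3")), c(cds, utr5))
  exon <- sdiff(GenomicRanges::reduce(gr_of("exons")), c(cds, utr5, utr3))
  intron <- sdiff(bodies, c(cds, utr5, utr3, exon))
  genome_gr <- GenomicRanges::GRanges(
    names(genome$chrom_lengths),
    IRanges::IRanges(1, genome$chrom_lengths))
  intergenic <- sdiff(genome_gr, bodies)
  parts <- list(CDS = cds, UTR5 = utr5, UTR3 = utr3, exon_other = exon,
                intron = intron, intergenic = intergenic)
  parts <- parts[vapply(parts, length, 0L) > 0]
  gr <- suppressWarnings(do.call(c, unname(parts)))
  lab <- rep(names(parts), vapply(parts, length, 0L))
  feature_track("genic_partition",
                as.character(GenomeInfoDb::seqnames(gr)),
                GenomicRanges::start(gr), GenomicRanges::end(gr), lab)
}

#' Per-partition enrichment of SVs in genic space
#' @param svs SV ranges or catalog.
#' @param genes A `gene_model_set`.
#' @param genome A `genome_model`.
#' @param units "bp" or "count" (see [fold_enrichment()]).
#' @param alpha Adjusted-p significance threshold.
#' @export
genic_partition_enrichment <- function(svs, genes, genome,
                                       units = "bp", alpha = 0.01) {
  fold_enrichment(svs, genic_partition(genes, genome), genome,
                  units = units, alpha = alpha)
}

#' Per-sample, per-category SV summaries
#'
#' For each sample and impact category: the number of carried SVs (dosage >=
#' 1, non-missing) and the proportion of those that are singletons (AC = 1 in
#' the catalog). The singleton proportion is undefined (NA) when a sample
#' carries no SV of the category.
#' @param catalog An `sv_catalog`.
#' @param calls Output of [classify_catalog()].
#' @return data.frame with `sample_id`, `category`, `n_carried`,
#'   `singleton_prop`.
#' @export
per_genome_category_summary <- function(catalog, calls) {
  ac <- allele_counts(catalog)
  singleton <- stats::setNames(ac$ac == 1, ac$id)
  carrier <- !is.na(catalog$genotypes) & catalog$genotypes >= 1
  cats <- unique(calls$category)
  rows <- list()
  for (cc in cats) {
    ids <- unique(calls$sv_id[calls$category == cc])
    idx <- match(ids, catalog$variants$id)
    sub <- carrier[idx, , drop = FALSE]
    n_car <- colSums(sub)
    n_sing <- colSums(sub & singleton[ids])
    rows[[cc]] <- data.frame(sample_id = catalog$samples, category = cc,
                             n_carried = n_car,
                             singleton_prop = ifelse(n_car > 0,
                                                     n_sing / n_car, NA_real_),
                             row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

pooled_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    return(list(statistic = NA_real_, p = NA_real_, defined = FALSE))
  tt <- tryCatch(stats::t.test(x, y, var.equal = TRUE),
                 error = function(e) NULL)   # e.g. both groups constant
  if (is.null(tt))
    return(list(statistic = NA_real_, p = NA_real_, defined = FALSE))
  list(statistic = unname(tt$statistic), p = tt$p.value, defined = TRUE)
}

#' Singleton-proportion tests per category against a reference
#'
#' Two-sided pooled-variance (Student's) t-test of each category's per-sample
#' singleton proportions against the reference category, Bonferroni-adjusted
#' over the categories tested.
#' @param summaries Output of [per_genome_category_summary()].
#' @param reference Reference category (default "intergenic").
#' @param alpha Adjusted-p significance threshold (default 0.01).
#' @return data.frame per category with t statistic, p, adjusted p, flag.
#' @export
singleton_proportion_tests <- function(summaries, reference = "intergenic",
                                       alpha = 0.01) {
  ref <- summaries$singleton_prop[summaries$category == reference]
  cats <- setdiff(unique(summaries$category), reference)
  rows <- lapply(cats, function(cc) {
    tt <- pooled_t_test(summaries$singleton_prop[summaries$category == cc], ref)
    data.frame(category = cc, t = tt$statistic, p = tt$p, defined = tt$defined)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  out
}

#' Chromatin-state overlap proportions and tests against the quiescent state
#'
#' For every (tissue, state): overlapped length of state and SV divided by
#' the state's length in that tissue. Each non-reference state is compared to
#' the reference state (`Qui` by default) across tissues with a pooled
#' t-test, Bonferroni-adjusted.
#' @param states `feature_track` with labels = states and a tissue column.
#' @param svs SV ranges or catalog.
#' @param reference Reference state label (default "Qui").
#' @param alpha Adjusted-p significance threshold.
#' @return list(proportions, tests).
#' @export
chromatin_state_overlap <- function(states, svs, reference = "Qui",
                                    alpha = 0.01) {
  if (inherits(svs, "sv_catalog")) svs <- sv_ranges(svs)
  sv_m <- GenomicRanges::reduce(svs, ignore.strand = TRUE)
  mc <- S4Vectors::mcols(states$ranges)
  combos <- unique(data.frame(tissue = mc$tissue, state = mc$label))
  prop <- vapply(seq_len(nrow(combos)), function(k) {
    gr <- track_ranges(states, label = combos$state[k],
                       tissue = combos$tissue[k])
    overlap_bp(gr, sv_m) / reduced_bp(gr)
  }, 0)
  proportions <- data.frame(combos, proportion = prop)
  sts <- setdiff(unique(proportions$state), reference)
  ref_p <- proportions$proportion[proportions$state == reference]
  tests <- do.call(rbind, lapply(sts, function(s) {
    tt <- pooled_t_test(proportions$proportion[proportions$state == s], ref_p)
    data.frame(state = s, t = tt$statistic, p = tt$p, defined = tt$defined)
  }))
  if (!is.null(tests)) {
    tests$p_adj <- pmin(1, tests$p * nrow(tests))
    tests$significant <- !is.na(tests$p_adj) & tests$p_adj <= alpha
  }
  list(proportions = proportions, tests = tests)
}

# Assign each element a genomic location relative to protein-coding genes.
# Priority: 5'UTR > 3'UTR > exon > intron > gene flanking (+/- flank) >
# intergenic.
element_locations <- function(elements, genes, flank = 5000) {
  part <- genic_partition_ranges_cache(genes)
  loc <- rep("intergenic", length(elements))
  assign_hit <- function(loc, gr, name) {
    if (length(gr) == 0L) return(loc)
    hit <- GenomicRanges::countOverlaps(elements, gr, ignore.strand = TRUE) > 0
    loc[hit & loc == "intergenic"] <- name
    loc
  }
  flanks <- if (length(part$bodies)) {
    f1 <- GenomicRanges::flank(part$bodies, flank, start = TRUE)
    f2 <- GenomicRanges::flank(part$bodies, flank, start = FALSE)
    suppressWarnings(GenomicRanges::trim(c(f1, f2)))
  } else GenomicRanges::GRanges()
  # lowest priority first; later assignments overwrite via ordering below
  for (nm in c("gene_flanking", "intron", "exon", "UTR3", "UTR5")) {
    gr <- switch(nm, gene_flanking = flanks, intron = part$intron,
                 exon = part$exon, UTR3 = part$utr3, UTR5 = part$utr5)
    if (length(gr) == 0L) next
    hit <- GenomicRanges::countOverlaps(elements, gr, ignore.strand = TRUE) > 0
    loc[hit] <- nm
  }
  loc
}

genic_partition_ranges_cache <- function(genes) {
  pc <- genes$genes[vapply(genes$genes, function(g)
    g$biotype == "protein_coding", TRUE)]
  gr_of <- function(field) {
    if (!length(pc)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(suppressWarnings(do.call(c, unname(lapply(
      pc, function(g) {
        ir <- g[[field]]
        if (length(ir) == 0L) return(GenomicRanges::GRanges())
        GenomicRanges::GRanges(g$chrom, ir)
      })))))
  }
  bodies <- if (length(pc))
    GenomicRanges::reduce(suppressWarnings(do.call(c, unname(lapply(
      pc, function(g)
        GenomicRanges::GRanges(g$chrom,
                               IRanges::IRanges(g$body_start, g$body_end)))))))
  else GenomicRanges::GRanges()
  exons <- gr_of("exons")
  list(bodies = bodies, exon = exons, utr5 = gr_of("utr5"),
       utr3 = gr_of("utr3"),
       intron = suppressWarnings(GenomicRanges::setdiff(bodies, exons,
                                                        ignore.strand = TRUE)))
}

#' SV-related regulator ratios by genomic location
#'
#' For enhancers or promoters: the count of SV-overlapped elements divided by
#' all elements, per genomic location (gene flanking +/- 5 kb, exon, 5'UTR,
#' 3'UTR, intron, intergenic) and tissue, plus a pooled t-test of each
#' location's per-tissue ratios against the overall per-tissue ratios,
#' Bonferroni-adjusted.
#' @param elements `feature_track` of elements with a tissue column.
#' @param svs SV ranges or catalog.
#' @param genes A `gene_model_set`.
#' @param flank Gene flank width in bp (default 5000).
#' @param alpha Adjusted-p significance threshold.
#' @return list(ratios, tests).
#' @export
regulator_location_ratios <- function(elements, svs, genes, flank = 5000,
                                      alpha = 0.01) {
  if (inherits(svs, "sv_catalog")) svs <- sv_ranges(svs)
  gr <- elements$ranges
  sv_m <- GenomicRanges::reduce(svs, ignore.strand = TRUE)
  in_sv <- GenomicRanges::countOverlaps(gr, sv_m, ignore.strand = TRUE) > 0
  loc <- element_locations(gr, genes, flank)
  tissue <- S4Vectors::mcols(gr)$tissue
  d <- data.frame(tissue = tissue, location = loc, in_sv = in_sv)
  agg <- stats::aggregate(in_sv ~ tissue + location, data = d, FUN = function(x)
    c(n_in_sv = sum(x), n_total = length(x)))
  ratios <- data.frame(tissue = agg$tissue, location = agg$location,
                       n_in_sv = agg$in_sv[, "n_in_sv"],
                       n_total = agg$in_sv[, "n_total"])
  ratios$ratio <- ratios$n_in_sv / ratios$n_total
  overall <- stats::aggregate(in_sv ~ tissue, data = d, FUN = mean)
  locs <- unique(ratios$location)
  tests <- do.call(rbind, lapply(locs, function(l) {
    tt <- pooled_t_test(ratios$ratio[ratios$location == l], overall$in_sv)
    data.frame(location = l, t = tt$statistic, p = tt$p, defined = tt$defined)
  }))
  tests$p_adj <- pmin(1, tests$p * nrow(tests))
  tests$significant <- !is.na(tests$p_adj) & tests$p_adj < alpha
  list(ratios = ratios, tests = tests)
}

#' QTL enrichment in SV space
#'
#' QTL intervals larger than `max_qtl_len` are dropped, then each trait's
#' QTL bp are tested for enrichment in the merged SV set; a trait is
#' significantly enriched when its fold is > `fold_min` AND the
#' Bonferroni-adjusted p (over traits) is < `alpha`. Overlap tallies report
#' the fraction of retained QTLs and of traits with >= 1 bp SV overlap.
#' @param qtls `feature_track` with labels = trait names.
#' @param svs SV ranges or catalog.
#' @param genome A `genome_model`.
#' @param max_qtl_len Maximum QTL length in bp (default 1 Mb; strictly larger
#'   are removed).
#' @param fold_min Fold requirement (default 2).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return list(per_trait, tallies, n_qtl_kept, n_trait_kept).
#' @export
qtl_enrichment <- function(qtls, svs, genome, max_qtl_len = 1e6,
                           fold_min = 2, alpha = 0.01) {
  if (inherits(svs, "sv_catalog")) svs <- sv_ranges(svs)
  gr <- qtls$ranges
  gr <- gr[GenomicRanges::width(gr) <= max_qtl_len]
  kept <- feature_track(qtls$name,
                        as.character(GenomeInfoDb::seqnames(gr)),
                        GenomicRanges::start(gr), GenomicRanges::end(gr),
                        S4Vectors::mcols(gr)$label)
  per_trait <- fold_enrichment(svs, kept, genome, units = "bp", alpha = alpha)
  per_trait$significant <- per_trait$fold > fold_min & per_trait$p_adj < alpha
  sv_m <- GenomicRanges::reduce(svs, ignore.strand = TRUE)
  qtl_hit <- GenomicRanges::countOverlaps(gr, sv_m, ignore.strand = TRUE) > 0
  lab <- S4Vectors::mcols(gr)$label
  trait_hit <- tapply(qtl_hit, lab, any)
  tallies <- data.frame(
    n_qtl = length(gr), n_qtl_overlapped = sum(qtl_hit),
    frac_qtl_overlapped = mean(qtl_hit),
    n_trait = length(unique(lab)), n_trait_overlapped = sum(trait_hit),
    frac_trait_overlapped = mean(trait_hit))
  list(per_trait = per_trait, tallies = tallies,
       n_qtl_kept = length(gr), n_trait_kept = length(unique(lab)))
}

#' Per-individual QTL fold enrichment (log2)
#'
#' For each individual and trait: the trait-QTL bp overlapped by the
#' individual's carried SVs, relative to the individual's SV bp, against the
#' trait-QTL genome fraction; log2 with a 1-bp pseudocount on the overlap.
#' A reconstruction of the per-genome fold used for cross-population
#' comparisons.
#' @param catalog An `sv_catalog`.
#' @param qtls `feature_track` (already length-filtered).
#' @param genome A `genome_model`.
#' @return data.frame `sample_id`, `trait`, `log2_fold`.
#' @export
qtl_individual_fold <- function(catalog, qtls, genome) {
  gr <- sv_ranges(catalog)
  g_bp <- genome_bp(genome)
  carrier <- !is.na(catalog$genotypes) & catalog$genotypes >= 1
  traits <- unique(S4Vectors::mcols(qtls$ranges)$label)
  trait_gr <- lapply(traits, function(tr)
    GenomicRanges::reduce(track_ranges(qtls, label = tr)))
  trait_bp <- vapply(trait_gr, reduced_bp, 0)
  # disjoint SV pieces so overlapping carried SVs never double-count bp
  dj <- GenomicRanges::disjoin(gr, with.revmap = TRUE, ignore.strand = TRUE)
  revmap <- S4Vectors::mcols(dj)$revmap
  M <- Matrix::sparseMatrix(i = rep(seq_along(dj), lengths(revmap)),
                            j = unlist(revmap), x = 1,
                            dims = c(length(dj), length(gr)))
  w <- as.numeric(GenomicRanges::width(dj))
  W <- vapply(trait_gr, function(t) per_range_overlap_bp(dj, t),
              numeric(length(dj)))              # pieces x traits
  covered <- as.matrix(M %*% carrier) > 0       # pieces x samples
  my_bp <- colSums(w * covered)
  ov <- t(W) %*% covered                        # traits x samples
  rows <- lapply(which(my_bp > 0), function(j) {
    fold <- ((ov[, j] + 1) / my_bp[j]) / (trait_bp / g_bp)
    data.frame(sample_id = catalog$samples[j], trait = traits,
               log2_fold = log2(fold))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Cross-population ANOVA on per-individual trait folds
#'
#' One-way ANOVA (equivalent to a type III test for a single factor) of the
#' per-individual log2 fold values across main populations, per trait, with
#' Bonferroni adjustment; a trait is reported when the adjusted p < `alpha`
#' AND the coefficient of variation of the population mean log2 folds
#' exceeds `cv_min`.
#' @param values data.frame `sample_id`, `trait`, `log2_fold`.
#' @param pop_map A `population_map`; OTG samples are excluded so the test
#'   runs across the main pig populations.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param cv_min Coefficient-of-variation threshold (default 1).
#' @return data.frame per trait: F statistic, p, adjusted p, CV, flag.
#' @export
population_anova <- function(values, pop_map, alpha = 0.01, cv_min = 1) {
  d <- merge(values, pop_map[, c("sample_id", "population")], by = "sample_id")
  d <- d[d$population != "OTG", ]
  if (length(unique(d$population)) < 2L)
    stop("ANOVA needs at least 2 populations")
  traits <- unique(d$trait)
  rows <- lapply(traits, function(tr) {
    dd <- d[d$trait == tr, ]
    grp_means <- tapply(dd$log2_fold, dd$population, mean)
    cv <- stats::sd(grp_means) / abs(mean(grp_means))
    if (length(unique(dd$population)) < 2L ||
        stats::var(dd$log2_fold) == 0) {
      return(data.frame(trait = tr, f = 0, p = 1, cv = ifelse(is.na(cv), 0, cv)))
    }
    fit <- stats::aov(log2_fold ~ population, data = dd)
    an <- summary(fit)[[1]]
    data.frame(trait = tr, f = an$`F value`[1], p = an$`Pr(>F)`[1], cv = cv)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * nrow(out))
  out$reported <- out$p_adj < alpha & !is.na(out$cv) & out$cv > cv_min
  out
}
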