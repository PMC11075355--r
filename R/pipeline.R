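# End-to-end orchestration over a seeded synthetic study: each stage is a
# thin composition of the module functions; `all` equals the composition of
# the individual stages, and a manifest records seed, thresholds and output
# checksums.

PIPELINE_STAGES <- c("simulate", "qc", "classify", "enrich", "popgen", "ld",
                     "network", "validate")

stage_deps <- list(
  simulate = character(), qc = "simulate", classify = "qc", enrich = "classify",
  popgen = "qc", ld = "qc", network = "ld", validate = "qc")

expand_stages <- function(stages) {
  if (identical(stages, "all")) return(PIPELINE_STAGES)
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  want <- character()
  grow <- function(s) {
    for (d in stage_deps[[s]]) grow(d)
    if (!s %in% want) want <<- c(want, s)
  }
  for (s in stages) grow(s)
  want[order(match(want, PIPELINE_STAGES))]
}

#' Default analysis thresholds
#'
#' The thresholds applied by [run_pipeline()], all overridable: CN > 10 in >=
#' 90\% of samples for bad bins, 50 bp minimum length, MSQ > 100/150/250 for
#' DEL+MEI/INV/BND, split-read support for DELs <= 1000 bp, 10\% INV read
#' support, 90\% repeat cover for the MEI reclassification, 20\% strong/weak
#' boundary, 5 kb regulator flank, 1 Mb QTL length cap, MAF 0.01 and 0.95
#' call rate for the differentiation scan, top 1\% FST, 1 Mb LD window with
#' 0.2/0.5/0.8 tiers, 1 kb thinning, GWAS p <= 5e-8, TWAS FDR <= 0.05.
#' @export
pipeline_thresholds <- function() {
  list(cn_threshold = 10, cn_sample_fraction = 0.90, min_len = 50,
       msq_del_mei = 100, msq_inv = 150, msq_bnd = 250, small_del_max = 1000,
       inv_support_min = 0.10, mei_cover = 0.90, strong_fraction = 0.20,
       regulator_flank = 5000, max_qtl_len = 1e6, maf_min = 0.01,
       min_call_rate = 0.95, fst_top_q = 0.01, ld_window = 1e6,
       tiers = LD_TIERS, thin_gap = 1000, gwas_p_max = 5e-8,
       twas_fdr_max = 0.05, gene_flank = 5000)
}

#' Run the synthetic-study pipeline
#'
#' Stages (dependency-ordered): `simulate` (the seeded study), `qc` (bad-bin
#' detection and the full filter stack, then MEI reclassification), `classify`
#' (gene-impact calls and frequency classes), `enrich` (genic partition,
#' repeat, chromatin-state and QTL enrichment with the cross-population
#' ANOVA), `popgen` (group allele frequencies, group-specific SVs, FST with
#' top-percentile calls), `ld` (combined SV+SNP r2 within 1 Mb and tiers),
#' `network` (functional-variant network), `validate` (assembly-truth
#' matching). `stages = "all"` composes them and additionally scores
#' recovery against the planted ground truth.
#'
#' @param config A `sim_config` (its seed drives every stage).
#' @param stages Character: "all" or a subset of the stage names.
#' @param out_dir Optional directory for TSV/JSON outputs and the manifest.
#' @param thresholds Named overrides of [pipeline_thresholds()].
#' @return Named list with one element per executed stage plus `recovery`
#'   and `manifest` when everything ran.
#' @export
run_pipeline <- function(config, stages = "all", out_dir = NULL,
                         thresholds = list()) {
  th <- utils::modifyList(pipeline_thresholds(), thresholds)
  want <- expand_stages(stages)
  res <- list()

  sim <- simulate_study(config)
  res$simulate <- sim

  if ("qc" %in% want) {
    bad_bins <- detect_bad_bins(sim$cn, cn_threshold = th$cn_threshold,
                                sample_fraction = th$cn_sample_fraction)
    qc <- run_qc(sim$catalog, sim$tracks$genome, bad_bins,
                 min_len = th$min_len, msq_del_mei = th$msq_del_mei,
                 msq_inv = th$msq_inv, msq_bnd = th$msq_bnd,
                 small_del_max = th$small_del_max,
                 inv_support_min = th$inv_support_min)
    clean <- reclassify_del_to_mei(qc$catalog, sim$tracks$repeats,
                                   cover_threshold = th$mei_cover)
    res$qc <- list(bad_bins = bad_bins, report = qc$report, catalog = clean,
                   samples = sample_level_filters(clean, min_sv_count = 0))
  }

  if ("classify" %in% want) {
    catalog <- res$qc$catalog
    calls <- classify_catalog(catalog, sim$tracks$genes,
                              strong_fraction = th$strong_fraction)
    ac <- allele_counts(catalog)
    freq <- cbind(id = ac$id,
                  frequency_class(ac$ac, ac$an / 2), row.names = NULL)
    res$classify <- list(calls = calls, counts = category_counts(calls),
                         freq = freq,
                         per_genome = per_genome_category_summary(catalog,
                                                                 calls))
  }

  if ("enrich" %in% want) {
    catalog <- res$qc$catalog
    genome <- sim$tracks$genome
    res$enrich <- list(
      genic = genic_partition_enrichment(catalog, sim$tracks$genes, genome),
      repeats = fold_enrichment(catalog, sim$tracks$repeats, genome),
      chromatin = chromatin_state_overlap(sim$tracks$states, catalog),
      regulators = regulator_location_ratios(
        sim$tracks$enhancers, catalog, sim$tracks$genes,
        flank = th$regulator_flank),
      singletons = singleton_proportion_tests(res$classify$per_genome),
      qtl = qtl_enrichment(sim$tracks$qtls, catalog, genome,
                           max_qtl_len = th$max_qtl_len))
    kept_qtls <- sim$tracks$qtls
    kept <- kept_qtls$ranges[GenomicRanges::width(kept_qtls$ranges) <=
                               th$max_qtl_len]
    kept_qtls <- feature_track("qtls",
                               as.character(GenomeInfoDb::seqnames(kept)),
                               GenomicRanges::start(kept),
                               GenomicRanges::end(kept),
                               S4Vectors::mcols(kept)$label)
    folds <- qtl_individual_fold(catalog, kept_qtls, genome)
    res$enrich$anova <- population_anova(folds, sim$pop_map)
  }

  if ("popgen" %in% want) {
    catalog <- res$qc$catalog
    gaf <- group_allele_frequencies(catalog, sim$pop_map,
                                    group_by = "ancestral")
    spec <- group_specific_svs(catalog, sim$pop_map)
    fst <- weir_cockerham_fst(catalog, sim$pop_map)
    top <- top_percentile(fst$fst, q = th$fst_top_q)
    res$popgen <- list(group_af = gaf, specific = spec, fst = fst,
                       fst_top = top)
  }

  if ("ld" %in% want) {
    combined <- combine_genotypes(res$qc$catalog, sim$snps)
    linkage <- ld_r2_window(combined, window = th$ld_window,
                            pairs = "sv_snp")
    thin_keep <- thin_variants(sim$snps$info$pos, sim$snps$info$chrom,
                               min_gap = th$thin_gap)
    res$ld <- list(linkage = linkage, thinned_snps = sim$snps$info$id[thin_keep])
  }

  if ("network" %in% want) {
    res$network <- build_functional_network(
      res$qc$catalog, res$ld$linkage, sim$functional, sim$tracks$genes,
      r2_min = th$tiers[["linked"]], gwas_p_max = th$gwas_p_max,
      twas_fdr_max = th$twas_fdr_max, gene_flank = th$gene_flank)
  }

  if ("validate" %in% want) {
    pairs <- match_sv_sets(res$qc$catalog, sim$assembly_truth)
    res$validate <- list(pairs = pairs,
                         rates = validation_rates(pairs, res$qc$catalog))
  }

  if (setequal(want, PIPELINE_STAGES))
    res$recovery <- score_recovery(res, sim)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- character()
    if (!is.null(res$qc))
      paths <- c(paths, write_tables(list(qc_report = res$qc$report,
                                          samples = res$qc$samples), out_dir))
    if (!is.null(res$classify))
      paths <- c(paths, write_tables(list(impact_calls = res$classify$calls,
                                          category_counts = res$classify$counts,
                                          frequency_classes = res$classify$freq),
                                     out_dir))
    if (!is.null(res$enrich))
      paths <- c(paths, write_tables(list(genic_enrichment = res$enrich$genic,
                                          qtl_enrichment = res$enrich$qtl$per_trait,
                                          qtl_anova = res$enrich$anova),
                                     out_dir))
    if (!is.null(res$popgen))
      paths <- c(paths, write_tables(list(group_specific = res$popgen$specific,
                                          fst = res$popgen$fst), out_dir))
    if (!is.null(res$ld))
      paths <- c(paths, write_tables(list(linkage = res$ld$linkage), out_dir))
    if (!is.null(res$network)) write_network(res$network, out_dir)
    if (!is.null(res$validate))
      paths <- c(paths, write_tables(list(validation = res$validate$rates),
                                     out_dir))
    manifest <- list(seed = config$seed, thresholds = th,
                     stages = want,
                     files = as.list(tools::md5sum(sort(paths))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}

# Compare pipeline output against the planted ground truth.
score_recovery <- function(res, sim) {
  truth <- sim$truth
  out <- list()

  # bad bins: every planted window recovered (and, with the clean background,
  # nothing else)
  planted <- GenomicRanges::reduce(sim$tracks$bad_bins$ranges)
  detected <- GenomicRanges::reduce(res$qc$bad_bins$ranges)
  missed <- GenomicRanges::setdiff(planted, detected)
  extra <- GenomicRanges::setdiff(detected, planted)
  out$bad_bin_recall <- 1 - sum(GenomicRanges::width(missed)) /
    sum(GenomicRanges::width(planted))
  out$bad_bin_extra_bp <- sum(GenomicRanges::width(extra))

  # group-specific SVs: planted ids detected with the right label
  spec <- res$popgen$specific
  lab <- paste0(truth$specific$group, "-specific")
  got <- spec$status[match(truth$specific$sv_id, spec$id)]
  out$specific_recall <- mean(!is.na(got) & got == lab)

  # impact categories on planted (SV, gene) pairs
  calls <- res$classify$calls
  key <- paste(calls$sv_id, calls$gene_id)
  got_cat <- calls$category[match(paste(truth$impact$sv_id,
                                        truth$impact$gene_id), key)]
  out$impact_accuracy <- mean(!is.na(got_cat) &
                                got_cat == truth$impact$category)
  out$n_impact_planted <- nrow(truth$impact)

  # planted QC failures all removed
  out$qc_fail_removed <- mean(!truth$qc_fail$sv_id %in%
                                res$qc$catalog$variants$id)
  # MEI-destined DELs all reclassified
  v <- res$qc$catalog$variants
  out$mei_recall <- mean(v$svtype[match(intersect(truth$mei_ids, v$id),
                                        v$id)] == "MEI")
  out
}
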