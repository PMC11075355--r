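# Synthetic study generator: genome + annotation tracks, multi-population
# SV and SNP genotype panels under the Balding-Nichols model, windowed
# copy-number matrices with planted bad bins, and functional-variant
# catalogs — all with known ground truth so every pipeline stage can be
# tested without external data. All randomness flows from the single config
# seed; each component re-seeds from a fixed offset so components are
# reproducible in isolation.

#' Simulation configuration
#'
#' Defaults define the synthetic study conditions: a 3 x 5 Mb genome, seven
#' main populations with Balding-Nichols differentiation, SV length
#' distributions with SINE-like (~250 bp) and LINE-like (~7.5 kb) repeat
#' modes, SNPs coupled to SVs with distance-decaying fidelity to induce LD
#' tiers, planted high-copy-number bad bins, planted group-specific SVs and
#' planted gene-impact SVs of each category.
#'
#' @param seed Integer seed (mandatory; keep below 2^31).
#' @param ... Overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  stop_if_not_scalar_number(seed, "seed")
  defaults <- list(
    seed = as.integer(seed),
    chrom_lengths = c(chr1 = 5e6, chr2 = 5e6, chr3 = 5e6),
    n_gaps_per_chrom = 2, gap_len = 2e4,
    n_genes = 120, noncoding_frac = 0.10, second_tx_prob = 0.3,
    n_sine = 1200, n_line = 120, n_ltr = 150, n_satellite = 40,
    n_tissues = 3,
    chromatin_states = c("TssA", "TssAHet", "TxFlnk", "TxFlnkWk", "TxFlnkHet",
                         "EnhA", "EnhAMe", "EnhAWk", "EnhAHet", "EnhPois",
                         "ATAC_Is", "TssBiv", "Repr", "ReprWk", "Qui"),
    qui_weight = 0.6,
    n_enhancers = 300, n_promoters = 150,
    n_traits = 25, qtl_per_trait_mean = 8,
    qtl_len_meanlog = log(2e5), qtl_len_sdlog = 1,
    pop_sizes = c(ASW = 8, ASD = 40, ASxEU = 4, EUC = 40, EUD = 12,
                  EUW = 6, OTG = 4),
    pop_F = c(ASW = 0.15, ASD = 0.08, ASxEU = 0.05, EUC = 0.10, EUD = 0.10,
              EUW = 0.15, OTG = 0.35),
    n_del = 120, n_mei_like = 60, n_dup = 25, n_inv = 15, n_bnd = 25,
    del_len_meanlog = log(1500), del_len_sdlog = 0.8,
    dup_len_meanlog = log(12000), dup_len_sdlog = 0.7,
    inv_len_meanlog = log(20000), inv_len_sdlog = 0.7,
    bnd_span_meanlog = log(5e4), bnd_span_sdlog = 1,
    n_specific_per_group = 10, n_impact_per_template = 2,
    n_qc_fail_per_reason = 2,
    n_snps = 1500, n_coupled_svs = 30,
    coupling_phis = c(0.98, 0.85, 0.60), coupling_window = 1e5,
    cn_window = 100L, n_bad_bins = 5, bad_bin_windows = 3L,
    eqtl_frac = 0.08, sqtl_frac = 0.05, n_gwas = 40, n_twas = 30,
    assembly_match_frac = 0.6, assembly_len_jitter = 0.01)
  cfg <- utils::modifyList(defaults, list(...))
  cfg$seed <- as.integer(seed)
  class(cfg) <- c("sim_config", "list")
  cfg
}

# uniform placement of intervals, optionally avoiding a GRanges
place_intervals <- function(lengths, genome, avoid = NULL, max_tries = 500) {
  cl <- genome$chrom_lengths
  n <- length(lengths)
  chrom <- character(n); start <- numeric(n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_tries)) {
      ch <- sample(names(cl), 1, prob = cl)
      if (cl[ch] <= lengths[i]) next
      s <- sample.int(cl[ch] - lengths[i], 1)
      if (!is.null(avoid) && length(avoid)) {
        cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, s + lengths[i] - 1))
        if (suppressWarnings(GenomicRanges::countOverlaps(
              cand, avoid, ignore.strand = TRUE)) > 0)
          next
      }
      chrom[i] <- ch; start[i] <- s
      break
    }
    if (chrom[i] == "") stop("could not place interval of length ", lengths[i])
  }
  data.frame(chrom = chrom, start = start, end = start + lengths - 1)
}

draw_transcript_layout <- function() {
  k <- sample(4:8, 1)
  exon_len <- round(stats::runif(k, 150, 600))
  intron_len <- round(stats::runif(k - 1, 800, 3000))
  starts <- cumsum(c(1, exon_len[-k] + intron_len))
  list(k = k, exon_start = starts, exon_end = starts + exon_len - 1,
       span = starts[k] + exon_len[k] - 1)
}

build_gene <- function(gene_id, chrom, offset, strand, biotype, second_tx) {
  lay <- draw_transcript_layout()
  es <- lay$exon_start + offset - 1; ee <- lay$exon_end + offset - 1
  exons <- data.frame(start = es, end = ee)
  txs <- list()
  if (biotype == "protein_coding") {
    w1 <- ee[1] - es[1] + 1; wk <- ee[lay$k] - es[lay$k] + 1
    left_utr_len <- round(stats::runif(1, 80, min(250, w1 - 60)))
    right_utr_len <- round(stats::runif(1, 80, min(250, wk - 60)))
    left_utr <- data.frame(start = es[1], end = es[1] + left_utr_len - 1)
    right_utr <- data.frame(start = ee[lay$k] - right_utr_len + 1,
                            end = ee[lay$k])
    cds <- exons
    cds$start[1] <- left_utr$end + 1
    cds$end[lay$k] <- right_utr$start - 1
    if (strand == "+") { utr5 <- left_utr; utr3 <- right_utr }
    else { utr5 <- right_utr; utr3 <- left_utr }
    txs$t1 <- list(exons = exons, cds = cds, utr5 = utr5, utr3 = utr3)
    if (second_tx && lay$k >= 4) {
      drop <- sample(2:(lay$k - 1), 1)
      txs$t2 <- list(exons = exons[-drop, ], cds = cds[-drop, ],
                     utr5 = utr5, utr3 = utr3)
    }
  } else {
    txs$t1 <- list(exons = exons, cds = NULL, utr5 = NULL, utr3 = NULL)
  }
  names(txs) <- paste0(gene_id, ".", seq_along(txs))
  gene_model(gene_id, chrom, strand, biotype, txs)
}

#' Simulate a genome with gene, repeat, chromatin, regulator and QTL tracks
#'
#' Genes are non-overlapping with exon/CDS/UTR structure and at least 2 kb of
#' clear space between bodies; repeat intervals are labeled
#' SINE/LINE/LTR/Satellite with SINE ~250 bp and LINE ~7.5 kb modes;
#' chromatin-state segmentations tile each chromosome exactly once per
#' tissue; QTL intervals carry trait labels and include some over 1 Mb to
#' exercise the length filter. Planted bad-bin windows (aligned to the
#' copy-number grid) are returned as ground truth for the QC stage.
#'
#' @param config A `sim_config`.
#' @return list(genome, genes, repeats, states, enhancers, promoters, qtls,
#'   bad_bins).
#' @export
simulate_genome_and_tracks <- function(config) {
  set.seed(config$seed + 1L)
  cl <- config$chrom_lengths
  gaps <- place_intervals(rep(config$gap_len, config$n_gaps_per_chrom *
                                length(cl)),
                          genome_model(cl))
  genome <- genome_model(cl, gaps)
  gap_gr <- genome$gaps

  # planted bad bins, aligned to the CN window grid, clear of gaps
  w <- config$cn_window
  bin_len <- config$bad_bin_windows * w
  bb <- place_intervals(rep(bin_len, config$n_bad_bins), genome,
                        avoid = gap_gr + 200)
  bb$start <- floor((bb$start - 1) / w) * w + 1
  bb$end <- bb$start + bin_len - 1
  bad_bins <- feature_track("true_bad_bins", bb$chrom, bb$start, bb$end,
                            rep("bad_bin", nrow(bb)))

  # genes: sequential placement per chromosome, avoiding gaps and bad bins
  avoid <- c(GenomicRanges::granges(gap_gr),
             GenomicRanges::granges(bad_bins$ranges))
  genes <- list()
  if (config$n_genes > 0) {
    per_chrom <- ceiling(config$n_genes / length(cl))
    gid <- 0L
    for (ch in names(cl)) {
      cursor <- round(stats::runif(1, 5000, 20000))
      placed <- 0L
      while (placed < per_chrom && gid < config$n_genes) {
        lay_try <- 0L
        repeat {
          lay_try <- lay_try + 1L
          gid2 <- gid + 1L
          gene_id <- sprintf("G%04d", gid2)
          strand <- sample(c("+", "-"), 1)
          biotype <- if (stats::runif(1) < config$noncoding_frac) "lncRNA"
          else "protein_coding"
          g <- build_gene(gene_id, ch, cursor, strand, biotype,
                          stats::runif(1) < config$second_tx_prob)
          span <- GenomicRanges::GRanges(ch, IRanges::IRanges(
            g$body_start - 1000, g$body_end + 1000))
          if (g$body_end + 2000 > cl[ch]) { g <- NULL; break }
          if (suppressWarnings(GenomicRanges::countOverlaps(
                span, avoid, ignore.strand = TRUE)) == 0) break
          cursor <- cursor + 5000
          if (lay_try > 50) { g <- NULL; break }
        }
        if (is.null(g)) break
        gid <- gid + 1L
        genes[[g$gene_id]] <- g
        placed <- placed + 1L
        cursor <- g$body_end + round(stats::runif(1, 4000, 15000))
      }
    }
  }
  gene_set <- gene_model_set(genes)

  rep_spec <- list(SINE = list(n = config$n_sine, mean = 250, sd = 30),
                   LINE = list(n = config$n_line, mean = 7500, sd = 800),
                   LTR = list(n = config$n_ltr, mean = 1500, sd = 300),
                   Satellite = list(n = config$n_satellite, mean = 3000,
                                    sd = 500))
  rep_rows <- lapply(names(rep_spec), function(cls) {
    sp <- rep_spec[[cls]]
    if (sp$n == 0) return(NULL)
    len <- pmax(60, round(stats::rnorm(sp$n, sp$mean, sp$sd)))
    d <- place_intervals(len, genome)
    d$label <- cls
    d
  })
  rep_df <- do.call(rbind, rep_rows)
  repeats <- feature_track("repeats", rep_df$chrom, rep_df$start, rep_df$end,
                           rep_df$label,
                           vocabulary = names(rep_spec))

  # chromatin-state tiling per tissue
  states <- config$chromatin_states
  wts <- c(rep((1 - config$qui_weight) / (length(states) - 1),
               length(states) - 1), config$qui_weight)
  st_rows <- list()
  for (tis in paste0("tissue", seq_len(config$n_tissues))) {
    for (ch in names(cl)) {
      pos <- 1
      seg_start <- numeric(); seg_end <- numeric()
      while (pos <= cl[ch]) {
        len <- round(stats::rexp(1, 1 / 2000)) + 200
        end <- min(pos + len - 1, cl[ch])
        seg_start <- c(seg_start, pos); seg_end <- c(seg_end, end)
        pos <- end + 1
      }
      st_rows[[paste(tis, ch)]] <- data.frame(
        chrom = ch, start = seg_start, end = seg_end,
        label = sample(states, length(seg_start), replace = TRUE, prob = wts),
        tissue = tis)
    }
  }
  st_df <- do.call(rbind, st_rows)
  state_track <- feature_track("chromatin_states", st_df$chrom, st_df$start,
                               st_df$end, st_df$label, tissue = st_df$tissue,
                               vocabulary = states)

  reg_track <- function(n, len_mean, len_sd, name) {
    len <- pmax(100, round(stats::rnorm(n, len_mean, len_sd)))
    d <- place_intervals(len, genome)
    feature_track(name, d$chrom, d$start, d$end, rep(name, n),
                  tissue = sample(paste0("tissue",
                                         seq_len(config$n_tissues)),
                                  n, replace = TRUE))
  }
  enhancers <- reg_track(config$n_enhancers, 400, 50, "enhancer")
  promoters <- reg_track(config$n_promoters, 600, 100, "promoter")

  n_qtl <- stats::rpois(config$n_traits, config$qtl_per_trait_mean) + 1L
  traits <- sprintf("trait%02d", seq_len(config$n_traits))
  qtl_len <- round(stats::rlnorm(sum(n_qtl), config$qtl_len_meanlog,
                                 config$qtl_len_sdlog))
  qtl_len <- pmin(qtl_len, min(cl) - 2)
  qd <- place_intervals(qtl_len, genome)
  qd$label <- rep(traits, n_qtl)
  qtls <- feature_track("qtls", qd$chrom, qd$start, qd$end, qd$label,
                        vocabulary = traits)

  list(genome = genome, genes = gene_set, repeats = repeats,
       states = state_track, enhancers = enhancers, promoters = promoters,
       qtls = qtls, bad_bins = bad_bins)
}

# --- impact-template planting -----------------------------------------------

exon_table <- function(gene) {
  ex <- gene$exons
  data.frame(start = IRanges::start(ex), end = IRanges::end(ex))
}

internal_cds_exons <- function(gene) {
  ex <- exon_table(gene)
  if (nrow(ex) < 3) return(NULL)
  cds <- gene$cds
  out <- list()
  for (i in 2:(nrow(ex) - 1)) {
    w <- ex$end[i] - ex$start[i] + 1
    in_cds <- ir_overlap_bp(ex$start[i], ex$end[i], cds) == w
    if (!in_cds) next
    out[[length(out) + 1]] <- data.frame(
      start = ex$start[i], end = ex$end[i], width = w,
      gap_left = ex$start[i] - ex$end[i - 1] - 1,
      gap_right = ex$start[i + 1] - ex$end[i] - 1)
  }
  if (length(out)) do.call(rbind, out) else NULL
}

plant_impact_sv <- function(gene, template) {
  pick <- function(start, end, svtype, category)
    list(start = start, end = end, svtype = svtype, category = category,
         gene_id = gene$gene_id)
  if (template %in% c("WlGnDel", "WlGnDup", "WlGnInv")) {
    svt <- c(WlGnDel = "DEL", WlGnDup = "DUP", WlGnInv = "INV")[[template]]
    return(pick(gene$body_start - 500, gene$body_end + 500, svt, template))
  }
  if (template == "noncoding") {
    if (gene$biotype == "protein_coding") return(NULL)
    ex <- exon_table(gene)
    ex <- ex[ex$end - ex$start + 1 >= 80, , drop = FALSE]
    if (!nrow(ex)) return(NULL)
    return(pick(ex$start[1] + 10, ex$start[1] + 69, "DEL", "noncoding"))
  }
  if (gene$biotype != "protein_coding") return(NULL)
  if (template %in% c("pLoF_St", "CpGn_St", "codInv", "codBnd")) {
    e <- internal_cds_exons(gene)
    if (is.null(e)) return(NULL)
    e <- e[e$gap_left >= 60 & e$gap_right >= 60, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    e <- e[1, ]
    pad <- min(floor(e$width / 2), e$gap_left - 20, e$gap_right - 20)
    svt <- switch(template, pLoF_St = "DEL", CpGn_St = "DUP",
                  codInv = "INV", codBnd = "BND")
    return(pick(e$start - pad, e$end + pad, svt, template))
  }
  if (template %in% c("pLoF_Wk", "CpGn_Wk")) {
    e <- internal_cds_exons(gene)
    if (is.null(e)) return(NULL)
    e <- e[e$gap_left >= 600, , drop = FALSE]
    if (!nrow(e)) return(NULL)
    e <- e[1, ]
    ov <- 60; ext <- min(540, e$gap_left - 20)
    if (ov / (ov + ext) >= 0.2) return(NULL)
    svt <- if (template == "pLoF_Wk") "DEL" else "DUP"
    return(pick(e$start - ext, e$start + ov - 1, svt, template))
  }
  if (template %in% c("Rglt5_St", "Rglt3_St")) {
    utr <- if (template == "Rglt5_St") gene$utr5 else gene$utr3
    if (length(utr) == 0L || max(IRanges::width(utr)) < 70) return(NULL)
    u <- utr[which.max(IRanges::width(utr))]
    s <- IRanges::start(u) + 5
    return(pick(s, s + 49, "DEL", template))
  }
  if (template %in% c("Rglt5_Wk", "Rglt3_Wk")) {
    utr <- if (template == "Rglt5_Wk") gene$utr5 else gene$utr3
    if (length(utr) == 0L) return(NULL)
    u <- utr[1]
    # only usable when this UTR sits at a gene-body edge; extend outside
    if (IRanges::start(u) == gene$body_start) {
      sv <- pick(gene$body_start - 400, gene$body_start + 49, "DEL", template)
    } else if (IRanges::end(u) == gene$body_end) {
      sv <- pick(gene$body_end - 49, gene$body_end + 400, "DEL", template)
    } else return(NULL)
    return(sv)
  }
  if (template == "intron") {
    ex <- exon_table(gene)
    if (nrow(ex) < 2) return(NULL)
    gaps <- data.frame(start = ex$end[-nrow(ex)] + 1, end = ex$start[-1] - 1)
    gaps <- gaps[gaps$end - gaps$start + 1 >= 140, , drop = FALSE]
    if (!nrow(gaps)) return(NULL)
    g <- gaps[1, ]
    return(pick(g$start + 20, g$start + 119, "DEL", "intron"))
  }
  NULL
}

IMPACT_TEMPLATES <- c("WlGnDel", "WlGnDup", "WlGnInv", "pLoF_St", "pLoF_Wk",
                      "CpGn_St", "CpGn_Wk", "codInv", "codBnd",
                      "Rglt5_St", "Rglt5_Wk", "Rglt3_St", "Rglt3_Wk",
                      "intron", "noncoding")

# --- genotype machinery -----------------------------------------------------

#' Balding-Nichols population allele frequency
#'
#' Population AF drawn from Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral
#' frequency p; the limit F -> 0 returns p itself.
#' @param p Ancestral allele frequency (vectorized).
#' @param F Differentiation parameter in \[0, 1).
#' @return Population allele frequencies.
#' @export
balding_nichols_af <- function(p, F) {
  if (F <= 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# genotypes for one variant across populations; pop_of: sample -> population
bn_genotypes <- function(p_anc, pop_of, F_by_pop) {
  n <- length(pop_of)
  out <- integer(n)
  for (pop in unique(pop_of)) {
    idx <- which(pop_of == pop)
    pk <- balding_nichols_af(p_anc, F_by_pop[[pop]])
    out[idx] <- stats::rbinom(length(idx), 2, pk)
  }
  out
}

#' Simulate a two-group Balding-Nichols genotype panel
#'
#' A fixture for differentiation-recovery experiments: two populations of
#' equal size, each drifted from a shared ancestral frequency (~Uniform(0.05,
#' 0.95)) with the same F, genotypes Binomial(2, AF).
#' @param n_variants Number of variants.
#' @param n_per_group Samples per group.
#' @param F Balding-Nichols differentiation parameter.
#' @param seed Integer seed.
#' @return list(gm = `genotype_matrix`, pop_map = `population_map`).
#' @export
simulate_bn_panel <- function(n_variants, n_per_group, F, seed) {
  set.seed(as.integer(seed))
  samples <- c(paste0("A", seq_len(n_per_group)),
               paste0("B", seq_len(n_per_group)))
  pops <- rep(c("ASD", "EUC"), each = n_per_group)
  p_anc <- stats::runif(n_variants, 0.05, 0.95)
  gt <- matrix(0L, n_variants, 2 * n_per_group,
               dimnames = list(NULL, samples))
  for (v in seq_len(n_variants)) {
    p1 <- balding_nichols_af(p_anc[v], F)
    p2 <- balding_nichols_af(p_anc[v], F)
    gt[v, ] <- c(stats::rbinom(n_per_group, 2, p1),
                 stats::rbinom(n_per_group, 2, p2))
  }
  info <- data.frame(id = sprintf("V%05d", seq_len(n_variants)),
                     chrom = "chr1", pos = seq_len(n_variants) * 1000,
                     kind = "SNP")
  list(gm = genotype_matrix(gt, info),
       pop_map = population_map(samples, pops))
}

#' Simulate the multi-population SV catalog and SNP panel
#'
#' Builds the SV variant table (background SVs per type, repeat-embedded
#' DELs destined for MEI reclassification, planted gene-impact SVs, planted
#' group-specific SVs, planted QC-failure records), draws genotypes under
#' the per-population Balding-Nichols model, attaches evidence annotations
#' (MSQ, split-read support, allele balance) consistent with the QC rules,
#' simulates SNPs, and couples a subset of SNPs to SVs by per-sample allele
#' copying with configured fidelity to induce LD tiers.
#'
#' @param config A `sim_config`.
#' @param tracks Output of [simulate_genome_and_tracks()].
#' @return list(catalog, snps, pop_map, truth) where truth holds the planted
#'   impact calls, group-specific labels, QC-failure reasons, MEI-destined
#'   ids, per-population F, and the SV-SNP coupling table.
#' @export
simulate_population_genotypes <- function(config, tracks) {
  set.seed(config$seed + 2L)
  genome <- tracks$genome
  avoid_qc <- c(GenomicRanges::granges(genome$gaps),
                GenomicRanges::granges(tracks$bad_bins$ranges))

  samples <- unlist(lapply(names(config$pop_sizes), function(p)
    sprintf("%s_%02d", p, seq_len(config$pop_sizes[[p]]))))
  pop_of <- rep(names(config$pop_sizes), config$pop_sizes)
  pm <- population_map(samples, pop_of)

  rows <- list(); truth_impact <- list(); truth_specific <- list()
  truth_qc <- list(); mei_ids <- character()
  add_row <- function(chrom, start, end, svtype, tag) {
    id <- sv_id(chrom, start, end, svtype)
    rows[[length(rows) + 1]] <<- data.frame(
      id = id, chrom = chrom, start = start, end = end, svtype = svtype,
      tag = tag, stringsAsFactors = FALSE)
    id
  }

  # planted gene-impact SVs
  pc_pool <- names(tracks$genes$genes)
  used_genes <- character()
  for (template in IMPACT_TEMPLATES) {
    placed <- 0L
    for (gid in setdiff(pc_pool, used_genes)) {
      if (placed >= config$n_impact_per_template) break
      sv <- plant_impact_sv(tracks$genes$genes[[gid]], template)
      if (is.null(sv)) next
      cand <- GenomicRanges::GRanges(tracks$genes$genes[[gid]]$chrom,
                                     IRanges::IRanges(sv$start, sv$end))
      if (suppressWarnings(GenomicRanges::countOverlaps(
            cand, avoid_qc, ignore.strand = TRUE)) > 0) next
      id <- add_row(tracks$genes$genes[[gid]]$chrom, sv$start, sv$end,
                    sv$svtype, "impact")
      truth_impact[[id]] <- data.frame(sv_id = id, gene_id = sv$gene_id,
                                       category = sv$category)
      used_genes <- c(used_genes, gid)
      placed <- placed + 1L
    }
  }

  # planted group-specific SVs in clear intergenic space
  clear <- c(avoid_qc, GenomicRanges::granges(tracks$genes$bodies + 6000))
  for (grp in c("AS", "EU")) {
    if (config$n_specific_per_group == 0) next
    len <- round(stats::rlnorm(config$n_specific_per_group,
                               config$del_len_meanlog, config$del_len_sdlog))
    len <- pmax(len, 60)
    d <- place_intervals(len, genome, avoid = clear)
    for (i in seq_len(nrow(d))) {
      id <- add_row(d$chrom[i], d$start[i], d$end[i], "DEL", "specific")
      truth_specific[[id]] <- data.frame(sv_id = id, group = grp)
    }
  }

  # repeat-embedded DELs (MEI-destined)
  if (config$n_mei_like > 0) {
    rep_gr <- tracks$repeats$ranges
    rep_gr <- rep_gr[S4Vectors::mcols(rep_gr)$label %in% c("SINE", "LINE")]
    rep_gr <- rep_gr[GenomicRanges::width(rep_gr) >= 80]
    rep_gr <- rep_gr[GenomicRanges::countOverlaps(rep_gr, avoid_qc,
                                                  ignore.strand = TRUE) == 0]
    sel <- sample(seq_along(rep_gr), min(config$n_mei_like, length(rep_gr)))
    for (k in sel) {
      w <- GenomicRanges::width(rep_gr)[k]
      margin <- max(1, floor(w * 0.02))
      s <- GenomicRanges::start(rep_gr)[k] + margin
      e <- GenomicRanges::end(rep_gr)[k] - margin
      if (e - s + 1 < 50) next
      id <- add_row(as.character(GenomeInfoDb::seqnames(rep_gr))[k], s, e,
                    "DEL", "mei_like")
      mei_ids <- c(mei_ids, id)
    }
  }

  # background SVs per type
  bg <- list(DEL = c(config$n_del, config$del_len_meanlog, config$del_len_sdlog),
             DUP = c(config$n_dup, config$dup_len_meanlog, config$dup_len_sdlog),
             INV = c(config$n_inv, config$inv_len_meanlog, config$inv_len_sdlog),
             BND = c(config$n_bnd, config$bnd_span_meanlog,
                     config$bnd_span_sdlog))
  for (svt in names(bg)) {
    n <- bg[[svt]][1]
    if (n == 0) next
    len <- pmax(60, round(stats::rlnorm(n, bg[[svt]][2], bg[[svt]][3])))
    d <- place_intervals(len, genome, avoid = avoid_qc)
    for (i in seq_len(nrow(d)))
      add_row(d$chrom[i], d$start[i], d$end[i], svt, "background")
  }

  # planted QC failures
  nq <- config$n_qc_fail_per_reason
  if (nq > 0) {
    plant_fail <- function(reason, svtype, len, avoid = avoid_qc,
                           inside = NULL) {
      for (i in seq_len(nq)) {
        if (!is.null(inside)) {
          k <- sample(length(inside), 1)
          s <- GenomicRanges::start(inside)[k] + sample(5:150, 1)
          e <- min(s + len - 1, GenomicRanges::end(inside)[k])
          ch <- as.character(GenomeInfoDb::seqnames(inside))[k]
        } else {
          d <- place_intervals(len, genome, avoid = avoid)
          ch <- d$chrom[1]; s <- d$start[1]; e <- d$end[1]
        }
        id <- add_row(ch, s, e, svtype, paste0("qcfail_", reason))
        truth_qc[[id]] <<- data.frame(sv_id = id, reason = reason)
      }
    }
    plant_fail("short", "DEL", 40)
    plant_fail("gap_overlap", "DEL", 500, inside = genome$gaps)
    plant_fail("bad_bin_overlap", "DEL", 500,
               inside = tracks$bad_bins$ranges + 200)
    plant_fail("low_msq_del", "DEL", 2000)
    plant_fail("low_msq_inv", "INV", 5000)
    plant_fail("low_msq_bnd", "BND", 10000)
    plant_fail("small_del_no_sr", "DEL", 400)
  }

  variants <- do.call(rbind, rows)
  nv <- nrow(variants)
  ns <- length(samples)
  anc <- pm$ancestral[match(samples, pm$sample_id)]

  # genotypes
  gt <- matrix(0L, nv, ns, dimnames = list(variants$id, samples))
  p_anc <- stats::runif(nv, 0.05, 0.6)
  for (v in seq_len(nv)) {
    id <- variants$id[v]
    if (!is.null(truth_specific[[id]])) {
      grp <- truth_specific[[id]]$group
      idx <- which(anc == grp)
      pk <- stats::runif(1, 0.15, 0.4)
      gt[v, idx] <- stats::rbinom(length(idx), 2, pk)
      if (sum(gt[v, idx]) == 0) gt[v, idx[1]] <- 1L
    } else {
      gt[v, ] <- bn_genotypes(p_anc[v], pop_of, config$pop_F)
      if (sum(gt[v, ]) == 0) gt[v, sample(ns, 1)] <- 1L
    }
  }

  # evidence annotations consistent with the QC rules
  msq <- stats::runif(nv, 160, 400)
  msq[variants$svtype == "INV"] <- stats::runif(sum(variants$svtype == "INV"),
                                                200, 400)
  msq[variants$svtype == "BND"] <- stats::runif(sum(variants$svtype == "BND"),
                                                300, 500)
  carrier <- gt >= 1
  sr <- matrix(0L, nv, ns, dimnames = dimnames(gt))
  sr[carrier] <- stats::rpois(sum(carrier), 4) + 1L
  ab <- matrix(NA_real_, nv, ns, dimnames = dimnames(gt))
  ab[gt == 0] <- 0
  ab[gt == 1] <- stats::rbeta(sum(gt == 1), 8, 8)
  ab[gt == 2] <- stats::rbeta(sum(gt == 2), 30, 3)

  # degrade evidence for the planted failures
  for (id in names(truth_qc)) {
    v <- match(id, variants$id)
    reason <- truth_qc[[id]]$reason
    if (reason == "low_msq_del") msq[v] <- stats::runif(1, 20, 100)
    if (reason == "low_msq_inv") msq[v] <- stats::runif(1, 20, 150)
    if (reason == "low_msq_bnd") msq[v] <- stats::runif(1, 100, 250)
    if (reason == "small_del_no_sr") sr[v, ] <- 0L
  }

  catalog <- sv_catalog(
    data.frame(variants[, c("id", "chrom", "start", "end", "svtype")],
               msq = msq),
    gt, samples, sr_support = sr, allele_balance = ab,
    provenance = sprintf("synthetic study, seed %d", config$seed))

  # SNPs, with a coupled subset copying SV alleles
  set.seed(config$seed + 3L)
  snp_pos <- sort(sample.int(genome_bp(genome), config$n_snps))
  cl <- genome$chrom_lengths
  breaks <- cumsum(c(0, cl))
  snp_chrom <- names(cl)[findInterval(snp_pos, breaks, left.open = TRUE)]
  snp_pos_chr <- snp_pos - breaks[match(snp_chrom, names(cl))]
  snp_pos_chr <- pmax(1, snp_pos_chr)
  snp_ids <- sprintf("snp%05d", seq_len(config$n_snps))
  snp_gt <- matrix(0L, config$n_snps, ns, dimnames = list(snp_ids, samples))
  p_snp <- stats::runif(config$n_snps, 0.05, 0.95)
  for (v in seq_len(config$n_snps))
    snp_gt[v, ] <- bn_genotypes(p_snp[v], pop_of, config$pop_F)

  couple_pool <- variants$id[variants$tag %in% c("background", "impact",
                                                 "mei_like")]
  couple_svs <- utils::head(couple_pool, config$n_coupled_svs)
  coupling <- list()
  for (svid in couple_svs) {
    v <- match(svid, variants$id)
    near <- which(snp_chrom == variants$chrom[v] &
                    abs(snp_pos_chr - variants$start[v]) <=
                      config$coupling_window)
    near <- setdiff(near, unlist(lapply(coupling, `[[`, "snp_idx")))
    if (!length(near)) next
    phis <- config$coupling_phis
    take <- utils::head(near[order(abs(snp_pos_chr[near] -
                                         variants$start[v]))], length(phis))
    for (k in seq_along(take)) {
      j <- take[k]; phi <- phis[k]
      copy <- stats::runif(ns) < phi
      snp_gt[j, copy] <- gt[v, copy]
      coupling[[length(coupling) + 1]] <- data.frame(
        sv_id = svid, snp_id = snp_ids[j], snp_idx = j, phi = phi,
        distance = abs(snp_pos_chr[j] - variants$start[v]))
    }
  }
  snps <- genotype_matrix(snp_gt,
                          data.frame(id = snp_ids, chrom = snp_chrom,
                                     pos = snp_pos_chr, kind = "SNP"))

  truth <- list(
    impact = do.call(rbind, c(truth_impact, list(make.row.names = FALSE))),
    specific = do.call(rbind, c(truth_specific, list(make.row.names = FALSE))),
    qc_fail = do.call(rbind, c(truth_qc, list(make.row.names = FALSE))),
    mei_ids = mei_ids,
    pop_F = config$pop_F,
    coupling = if (length(coupling))
      do.call(rbind, c(coupling, list(make.row.names = FALSE))) else NULL,
    tags = variants[, c("id", "tag")])
  list(catalog = catalog, snps = snps, pop_map = pm, truth = truth)
}

#' Simulate the windowed copy-number matrix with planted bad bins
#'
#' Background copy number ~ Normal(2, 0.3) truncated at 0; planted bad-bin
#' windows get CN ~ Uniform(11, 15) in at least 90\% of samples.
#' @param config A `sim_config`.
#' @param genome A `genome_model`.
#' @param bad_bins `feature_track` of planted bad-bin windows.
#' @param samples Sample roster.
#' @return A `cn_window_matrix`.
#' @export
simulate_cn_matrix <- function(config, genome, bad_bins, samples) {
  set.seed(config$seed + 4L)
  windows <- tile_genome(genome, config$cn_window)
  ns <- length(samples)
  cn <- matrix(pmax(0, stats::rnorm(length(windows) * ns, 2, 0.3)),
               length(windows), ns, dimnames = list(NULL, samples))
  hit <- which(GenomicRanges::countOverlaps(windows, bad_bins$ranges,
                                            ignore.strand = TRUE) > 0)
  need <- ceiling(0.9 * ns)
  for (i in hit) {
    who <- sample(ns, sample(need:ns, 1))
    cn[i, who] <- stats::runif(length(who), 11, 15)
  }
  cn_window_matrix(windows, cn, config$cn_window)
}

#' Simulate the functional-variant catalog (e/sQTL, GWAS, TWAS)
#'
#' A configured fraction of SNPs become e/sQTLs with a nearby target gene
#' (coupled SNPs first, so the network has planted pass-throughs); GWAS
#' records have a spiked sub-threshold subset; TWAS records cover a mix of
#' e/sGenes and other genes with FDRs on both sides of 0.05.
#' @param config A `sim_config`.
#' @param snps A `genotype_matrix` of SNPs.
#' @param genes A `gene_model_set`.
#' @return A `functional_catalog`.
#' @export
simulate_functional_catalog <- function(config, snps, genes) {
  set.seed(config$seed + 5L)
  snp_ids <- snps$info$id
  n <- length(snp_ids)
  tissues <- paste0("tissue", seq_len(config$n_tissues))
  traits <- sprintf("trait%02d", seq_len(config$n_traits))
  nearest_gene <- function(idx) {
    if (!length(genes)) return(rep(NA_character_, length(idx)))
    gr <- GenomicRanges::GRanges(snps$info$chrom[idx],
                                 IRanges::IRanges(snps$info$pos[idx],
                                                  snps$info$pos[idx]))
    hit <- GenomicRanges::nearest(gr, genes$bodies, ignore.strand = TRUE)
    names(genes$bodies)[hit]
  }
  recs <- list()
  n_e <- round(config$eqtl_frac * n); n_s <- round(config$sqtl_frac * n)
  pick_e <- sample(n, n_e); pick_s <- sample(setdiff(seq_len(n), pick_e), n_s)
  if (n_e)
    recs$e <- data.frame(kind = "eQTL", snp_id = snp_ids[pick_e],
                         chrom = snps$info$chrom[pick_e],
                         pos = snps$info$pos[pick_e],
                         gene_id = nearest_gene(pick_e),
                         tissue = sample(tissues, n_e, TRUE),
                         trait = NA_character_, p = NA_real_, fdr = NA_real_)
  if (n_s)
    recs$s <- data.frame(kind = "sQTL", snp_id = snp_ids[pick_s],
                         chrom = snps$info$chrom[pick_s],
                         pos = snps$info$pos[pick_s],
                         gene_id = nearest_gene(pick_s),
                         tissue = sample(tissues, n_s, TRUE),
                         trait = NA_character_, p = NA_real_, fdr = NA_real_)
  if (config$n_gwas) {
    gw <- sample(n, config$n_gwas)
    pass <- seq_len(config$n_gwas) <= ceiling(config$n_gwas / 2)
    pvals <- ifelse(pass, 10^stats::runif(config$n_gwas, -12, -8.31),
                    10^stats::runif(config$n_gwas, -6, -2))
    recs$g <- data.frame(kind = "GWAS", snp_id = snp_ids[gw],
                         chrom = snps$info$chrom[gw], pos = snps$info$pos[gw],
                         gene_id = NA_character_,
                         tissue = NA_character_,
                         trait = sample(traits, config$n_gwas, TRUE),
                         p = pvals, fdr = NA_real_)
  }
  if (config$n_twas && length(genes)) {
    esg <- unique(c(recs$e$gene_id, recs$s$gene_id))
    others <- setdiff(names(genes$genes), esg)
    gpool <- c(utils::head(esg, ceiling(config$n_twas * 0.7)),
               utils::head(others, floor(config$n_twas * 0.3)))
    gpool <- gpool[!is.na(gpool)]
    fdrs <- ifelse(seq_along(gpool) %% 2 == 0,
                   stats::runif(length(gpool), 0, 0.04),
                   stats::runif(length(gpool), 0.06, 0.5))
    recs$t <- data.frame(kind = "TWAS", snp_id = NA_character_,
                         chrom = NA_character_, pos = NA_real_,
                         gene_id = gpool,
                         tissue = sample(tissues, length(gpool), TRUE),
                         trait = sample(traits, length(gpool), TRUE),
                         p = NA_real_, fdr = fdrs)
  }
  functional_catalog(do.call(rbind, c(recs, list(make.row.names = FALSE))))
}

#' Simulate the complete synthetic study
#'
#' Runs all generator components off the single config seed and additionally
#' builds an assembly-comparison truth set: a configured fraction of the
#' non-BND catalog records with up to +/- 1\% length jitter (the
#' "validatable" subset), for the validation stage.
#' @param config A `sim_config`.
#' @return list(tracks, catalog, snps, pop_map, cn, functional,
#'   assembly_truth, truth, config).
#' @export
simulate_study <- function(config) {
  tracks <- simulate_genome_and_tracks(config)
  pg <- simulate_population_genotypes(config, tracks)
  cn <- simulate_cn_matrix(config, tracks$genome, tracks$bad_bins,
                           pg$catalog$samples)
  fc <- simulate_functional_catalog(config, pg$snps, tracks$genes)

  set.seed(config$seed + 6L)
  v <- pg$catalog$variants
  cand <- which(v$svtype != "BND")
  take <- sample(cand, round(config$assembly_match_frac * length(cand)))
  jit <- function(len) pmax(50, round(len * stats::runif(
    length(len), 1 - config$assembly_len_jitter,
    1 + config$assembly_len_jitter)))
  tr_len <- jit(v$length[take])
  shift <- round(stats::runif(length(take), -20, 20))
  truth_gr <- GenomicRanges::GRanges(
    v$chrom[take],
    IRanges::IRanges(pmax(1, v$start[take] + shift),
                     width = tr_len))
  names(truth_gr) <- paste0("asm_", v$id[take])
  pg$truth$assembly_matched <- v$id[take]

  list(tracks = tracks, catalog = pg$catalog, snps = pg$snps,
       pop_map = pg$pop_map, cn = cn, functional = fc,
       assembly_truth = truth_gr, truth = pg$truth, config = config)
}
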