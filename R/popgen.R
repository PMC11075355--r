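# Population differentiation: per-group allele frequencies with MAF and
# call-rate filters, group-specific/shared SVs, per-variant Weir-Cockerham
# (1984) FST with top-percentile calls, and a Hudson estimator behind a flag.

#' Per-group allele counts and frequencies
#'
#' Counts only non-missing alleles. Optional filters applied first on the
#' whole panel: minor allele frequency >= `maf_min` and per-variant call rate
#' > `min_call_rate`.
#' @param gm A `genotype_matrix` (or `sv_catalog`).
#' @param pop_map A `population_map`.
#' @param group_by Grouping column: "population" (default) or "ancestral".
#' @param maf_min Optional MAF filter (variants below are dropped).
#' @param min_call_rate Optional per-variant genotyping-rate filter (strict >).
#' @return data.frame `id`, `group`, `ac`, `an`, `af` (NA when a group is all
#'   missing).
#' @export
group_allele_frequencies <- function(gm, pop_map, group_by = "population",
                                     maf_min = NULL, min_call_rate = NULL) {
  if (inherits(gm, "sv_catalog")) {
    gm <- genotype_matrix(gm$genotypes,
                          data.frame(id = gm$variants$id,
                                     chrom = gm$variants$chrom,
                                     pos = gm$variants$start, kind = "SV"))
  }
  check_population_map(pop_map, gm$samples)
  gt <- gm$gt
  keep <- rep(TRUE, nrow(gt))
  if (!is.null(min_call_rate))
    keep <- keep & rowMeans(!is.na(gt)) > min_call_rate
  if (!is.null(maf_min)) {
    af <- rowSums(gt, na.rm = TRUE) / (2 * rowSums(!is.na(gt)))
    maf <- pmin(af, 1 - af)
    keep <- keep & !is.na(maf) & maf >= maf_min
  }
  gt <- gt[keep, , drop = FALSE]
  ids <- gm$info$id[keep]
  grp <- pop_map[[group_by]][match(gm$samples, pop_map$sample_id)]
  rows <- lapply(sort(unique(grp)), function(g) {
    sub <- gt[, grp == g, drop = FALSE]
    ac <- rowSums(sub, na.rm = TRUE)
    an <- 2 * rowSums(!is.na(sub))
    data.frame(id = ids, group = g, ac = ac, an = an,
               af = ifelse(an > 0, ac / an, NA_real_), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Group-specific and shared SVs between two groups
#'
#' An SV is A-specific when it is carried (non-missing dosage >= 1) by at
#' least one sample of group A and by no sample of group B; symmetric for B;
#' shared when carried in both. Missing is not absence. "Common-specific"
#' additionally requires AF >= `common_af` within the carrier group.
#' @param catalog An `sv_catalog` (or `genotype_matrix`).
#' @param pop_map A `population_map`.
#' @param group_a,group_b Ancestral group labels (default AS vs EU; samples
#'   in neither group are ignored).
#' @param group_by Grouping column (default "ancestral").
#' @param common_af AF threshold for the common-specific flag (default 0.01).
#' @return data.frame `id`, `status` in \{A-specific, B-specific, shared,
#'   absent\}, per-group AF, `common_specific` flag.
#' @export
group_specific_svs <- function(catalog, pop_map, group_a = "AS",
                               group_b = "EU", group_by = "ancestral",
                               common_af = 0.01) {
  gt <- if (inherits(catalog, "sv_catalog")) catalog$genotypes else catalog$gt
  ids <- if (inherits(catalog, "sv_catalog")) catalog$variants$id else
    catalog$info$id
  samples <- colnames(gt)
  grp <- pop_map[[group_by]][match(samples, pop_map$sample_id)]
  a_cols <- which(grp == group_a); b_cols <- which(grp == group_b)
  if (!length(a_cols) || !length(b_cols))
    stop("both groups need at least one sample")
  carried <- function(cols) {
    rowSums(!is.na(gt[, cols, drop = FALSE]) &
              gt[, cols, drop = FALSE] >= 1) > 0
  }
  af_in <- function(cols) {
    sub <- gt[, cols, drop = FALSE]
    an <- 2 * rowSums(!is.na(sub))
    ifelse(an > 0, rowSums(sub, na.rm = TRUE) / an, NA_real_)
  }
  in_a <- carried(a_cols); in_b <- carried(b_cols)
  status <- ifelse(in_a & !in_b, paste0(group_a, "-specific"),
            ifelse(in_b & !in_a, paste0(group_b, "-specific"),
            ifelse(in_a & in_b, "shared", "absent")))
  af_a <- af_in(a_cols); af_b <- af_in(b_cols)
  carrier_af <- ifelse(in_a & !in_b, af_a, ifelse(in_b & !in_a, af_b, NA_real_))
  data.frame(id = ids, status = status, af_a = af_a, af_b = af_b,
             common_specific = !is.na(carrier_af) & carrier_af >= common_af &
               grepl("-specific$", status),
             row.names = NULL)
}

# Weir & Cockerham (1984) two-population variance components per variant.
# p: 2 x V allele-frequency matrix, h: 2 x V het-frequency matrix,
# n: 2 x V non-missing sample counts.
wc_components <- function(p, h, n) {
  r <- 2
  nbar <- colMeans(n)
  nc <- (r * nbar - colSums(n^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n * p) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, pbar = pbar)
}

#' Pairwise per-variant FST between two groups
#'
#' The Weir & Cockerham (1984) theta-hat from the two-population variance
#' components (the default of the common PLINK-style workflow); the Hudson
#' estimator is available behind `estimator = "hudson"`. Variants with fewer
#' than 2 non-missing samples in either group, or monomorphic across both
#' groups, are skipped (NA estimate with a reason). Estimates may be slightly
#' negative at low differentiation; the multi-locus ratio-of-sums estimate is
#' attached as attribute `"fst_overall"` for the WC estimator.
#'
#' @param gm A `genotype_matrix` or `sv_catalog`.
#' @param pop_map A `population_map`.
#' @param pair Two group labels (default c("AS", "EU")).
#' @param group_by Grouping column (default "ancestral").
#' @param estimator "wc" (default) or "hudson".
#' @return data.frame `id`, `fst`, `reason` (for skipped variants), plus the
#'   percentile rank over the estimated variants.
#' @export
weir_cockerham_fst <- function(gm, pop_map, pair = c("AS", "EU"),
                               group_by = "ancestral",
                               estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  if (inherits(gm, "sv_catalog")) {
    gm <- genotype_matrix(gm$genotypes,
                          data.frame(id = gm$variants$id,
                                     chrom = gm$variants$chrom,
                                     pos = gm$variants$start, kind = "SV"))
  }
  gt <- gm$gt
  grp <- pop_map[[group_by]][match(gm$samples, pop_map$sample_id)]
  stats_for <- function(g) {
    sub <- gt[, which(grp == g), drop = FALSE]
    n <- rowSums(!is.na(sub))
    p <- ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
    h <- ifelse(n > 0, rowSums(sub == 1, na.rm = TRUE) / n, NA_real_)
    list(n = n, p = p, h = h)
  }
  s1 <- stats_for(pair[1]); s2 <- stats_for(pair[2])
  usable <- s1$n >= 2 & s2$n >= 2
  mono <- usable & (pmax(s1$p, s2$p) == 0 | pmin(s1$p, s2$p) == 1)
  est <- rep(NA_real_, nrow(gt))
  reason <- ifelse(!usable, "insufficient_samples",
                   ifelse(mono, "monomorphic", ""))
  idx <- which(usable & !mono)
  overall <- NA_real_
  if (length(idx)) {
    if (estimator == "wc") {
      p <- rbind(s1$p[idx], s2$p[idx])
      h <- rbind(s1$h[idx], s2$h[idx])
      n <- rbind(s1$n[idx], s2$n[idx])
      comp <- wc_components(p, h, n)
      denom <- comp$a + comp$b + comp$c
      est[idx] <- ifelse(denom != 0, comp$a / denom, NA_real_)
      overall <- sum(comp$a) / sum(denom)
    } else {
      p1 <- s1$p[idx]; p2 <- s2$p[idx]
      n1 <- s1$n[idx]; n2 <- s2$n[idx]
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      est[idx] <- ifelse(den != 0, num / den, NA_real_)
    }
  }
  if (any(reason != ""))
    message("FST skipped for ", sum(reason != ""), " variant(s)")
  out <- data.frame(id = gm$info$id, fst = est, reason = reason,
                    row.names = NULL)
  ok <- !is.na(out$fst)
  out$percentile <- NA_real_
  out$percentile[ok] <- rank(out$fst[ok], ties.method = "average") / sum(ok)
  attr(out, "fst_overall") <- overall
  out
}

#' Top-percentile threshold and flags
#'
#' Flags the `k = max(1, floor(q * n))` largest values: the threshold is the
#' k-th largest value (nearest rank) and all ties at the threshold are
#' included.
#' @param values Numeric vector (NAs dropped).
#' @param q Upper tail fraction (default 0.01 = top 1\%).
#' @return list(threshold, flagged (logical over the input), n_flagged).
#' @export
top_percentile <- function(values, q = 0.01) {
  ok <- !is.na(values)
  v <- values[ok]
  n <- length(v)
  if (n == 0L) stop("no non-missing values")
  k <- max(1L, floor(q * n))
  threshold <- sort(v, decreasing = TRUE)[k]
  flagged <- !is.na(values) & values >= threshold
  list(threshold = threshold, flagged = flagged, n_flagged = sum(flagged))
}
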