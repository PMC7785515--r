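# Matched-gene permutation test of gene-set overlap with disease loci,
# plus per-gene peak overlap and TFBS-disruption annotation.

#' Assign genes to size/expression matching bins
#'
#' Bin = (gene-length quantile, mean-expression quantile), boundaries
#' computed on the full universe. When the universe is smaller than the
#' number of bins, the binning is coarsened with a warning.
#'
#' @param genes annotation for the universe (needs `gene_id`, `length`).
#' @param mean_expression named vector covering every universe gene.
#' @param n_size_bins,n_expr_bins quantile bins per dimension.
#' @return Named character vector gene_id -> bin id.
#' @export
assign_match_bins <- function(genes, mean_expression, n_size_bins = 5,
                              n_expr_bins = 5) {
  miss <- setdiff(genes$gene_id, names(mean_expression))
  if (length(miss)) stopf("mean expression missing for %d gene(s)", length(miss))
  n <- nrow(genes)
  if (n < n_size_bins * n_expr_bins) {
    warnf("universe of %d genes smaller than %d bins; coarsening to 2x2",
          n, n_size_bins * n_expr_bins)
    n_size_bins <- n_expr_bins <- min(2, n)
  }
  qbin <- function(x, k) {
    br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1)))
    if (length(br) < 2) return(rep(1L, length(x)))
    cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
  }
  sb <- qbin(genes$length, n_size_bins)
  eb <- qbin(mean_expression[genes$gene_id], n_expr_bins)
  setNames(sprintf("s%d_e%d", sb, eb), genes$gene_id)
}

# logical: does each gene's body intersect any locus?
genes_in_loci <- function(genes, loci) {
  if (nrow(loci) == 0) return(setNames(rep(FALSE, nrow(genes)), genes$gene_id))
  hits <- GenomicRanges::countOverlaps(granges0(genes), granges0(loci)) > 0
  setNames(hits, genes$gene_id)
}

#' Matched permutation test of locus overlap
#'
#' Observed statistic: number of query genes whose body intersects any
#' locus. Each of `B` null draws samples, within every matching bin, as
#' many universe genes as the query holds in that bin; the one-sided
#' enrichment p-value uses the add-one estimator
#' `p = (1 + #{null >= observed}) / (1 + B)`.
#'
#' @param query character vector of gene ids (subset of the universe).
#' @param loci loci data frame from [build_loci()].
#' @param genes annotation of the universe.
#' @param bins gene -> bin map from [assign_match_bins()].
#' @param B permutation draws.
#' @param seed integer seed.
#' @return List: `observed`, `null_mean`, `null_sd`, `p`, `B`.
#' @export
permutation_enrichment <- function(query, loci, genes, bins, B = 10000,
                                   seed = 1L) {
  if (!all(query %in% genes$gene_id)) stopf("query genes outside the universe")
  if (nrow(loci) == 0) stopf("no loci supplied")
  set.seed(seed %% 2147480000)
  inloc <- genes_in_loci(genes, loci)
  observed <- sum(inloc[query])
  qbin <- table(bins[query])
  pools <- split(genes$gene_id, bins[genes$gene_id])
  for (b in names(qbin)) {
    if (length(pools[[b]]) < qbin[[b]])
      stopf("bin '%s' has fewer universe genes (%d) than query genes (%d)",
            b, length(pools[[b]]), qbin[[b]])
  }
  pool_hits <- lapply(pools, function(g) unname(inloc[g]))
  null <- vapply(seq_len(B), function(i) {
    tot <- 0L
    for (b in names(qbin)) {
      ph <- pool_hits[[b]]
      tot <- tot + sum(ph[sample.int(length(ph), qbin[[b]])])
    }
    tot
  }, 0L)
  list(observed = observed, null_mean = mean(null), null_sd = sd(null),
       p = (1 + sum(null >= observed)) / (1 + B), B = B)
}

#' Per-trait enrichment of a gene set in disease loci
#'
#' Runs [permutation_enrichment()] against each trait's loci separately.
#'
#' @inheritParams permutation_enrichment
#' @return Data frame, one row per trait.
#' @export
trait_enrichment <- function(query, loci, genes, bins, B = 10000, seed = 1L) {
  do.call(rbind, lapply(split(loci, loci$trait), function(lc) {
    r <- permutation_enrichment(query, lc, genes, bins, B = B, seed = seed)
    data.frame(trait = unique(lc$trait), observed = r$observed,
               null_mean = r$null_mean, null_sd = r$null_sd, p = r$p,
               stringsAsFactors = FALSE)
  }))
}

#' Genes driving a locus enrichment
#'
#' Query genes whose body intersects a locus, with the trait and locus id
#' of every intersection.
#'
#' @param query gene ids.
#' @param loci loci data frame.
#' @param genes annotation covering `query`.
#' @return Data frame: `gene_id`, `trait`, `locus_id`.
#' @export
driver_genes <- function(query, loci, genes) {
  qg <- genes[genes$gene_id %in% query, , drop = FALSE]
  if (nrow(qg) == 0 || nrow(loci) == 0)
    return(data.frame(gene_id = character(), trait = character(),
                      locus_id = character(), stringsAsFactors = FALSE))
  ov <- GenomicRanges::findOverlaps(granges0(qg), granges0(loci))
  out <- data.frame(gene_id = qg$gene_id[S4Vectors::queryHits(ov)],
                    trait = loci$trait[S4Vectors::subjectHits(ov)],
                    locus_id = loci$locus_id[S4Vectors::subjectHits(ov)],
                    stringsAsFactors = FALSE)
  out[order(out$gene_id, out$trait), , drop = FALSE]
}

#' SNP-in-peak annotation of driver genes
#'
#' For each driver gene, `TRUE` when at least one member SNP of an
#' intersecting locus falls inside a peak (half-open: start inclusive,
#' end exclusive) lying within the gene's flanked window. The summary is
#' the fraction of driver genes with such a SNP.
#'
#' @param drivers data frame from [driver_genes()].
#' @param loci loci data frame (with `members`).
#' @param snp_pos data frame `rsid`, `chrom`, `pos` for every SNP.
#' @param peaks peak data frame (possibly several conditions bound
#'   together).
#' @param genes annotation covering the drivers.
#' @param flank per-side window flank in bp.
#' @return List: `per_gene` (data frame `gene_id`, `snp_in_peak`),
#'   `fraction`.
#' @export
snp_peak_overlap <- function(drivers, loci, snp_pos, peaks, genes,
                             flank = 150000) {
  ids <- unique(drivers$gene_id)
  if (!length(ids))
    return(list(per_gene = data.frame(gene_id = character(),
                                      snp_in_peak = logical()), fraction = 0))
  hit <- setNames(rep(FALSE, length(ids)), ids)
  if (nrow(peaks)) {
    for (gid in ids) {
      g <- genes[genes$gene_id == gid, ]
      win <- gene_window(g, flank = flank)
      lids <- drivers$locus_id[drivers$gene_id == gid]
      members <- unlist(strsplit(loci$members[loci$locus_id %in% lids], ","))
      sp <- snp_pos[snp_pos$rsid %in% members, , drop = FALSE]
      if (!nrow(sp)) next
      pk <- peaks[peaks$chrom %in% sp$chrom, , drop = FALSE]
      if (!nrow(pk)) next
      for (k in seq_len(nrow(sp))) {
        inside <- pk$chrom == sp$chrom[k] & pk$start <= sp$pos[k] &
          sp$pos[k] < pk$end & pk$chrom == win$chrom &
          pk$start < win$end & pk$end > win$start
        if (any(inside)) { hit[gid] <- TRUE; break }
      }
    }
  }
  list(per_gene = data.frame(gene_id = ids, snp_in_peak = unname(hit),
                             stringsAsFactors = FALSE),
       fraction = mean(hit))
}
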