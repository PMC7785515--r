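# Post-peak-call chromatin analytics: gene windows, coverage enrichment
# between stimulation states, motif enrichment in peaks near sensitive
# genes, and peak-set QC.

#' Flanked gene window
#'
#' `[start - flank, end + flank)` clipped at 0 and at the chromosome end
#' (when a genome table is supplied). Strand-agnostic.
#'
#' @param gene one annotation row.
#' @param flank per-side flank in bp.
#' @param genome optional data frame `chrom`, `length` for clipping.
#' @return List: `chrom`, `start`, `end`.
#' @export
gene_window <- function(gene, flank = 150000, genome = NULL) {
  start <- max(0, gene$start - flank)
  end <- gene$end + flank
  if (!is.null(genome)) {
    len <- genome$length[match(gene$chrom, genome$chrom)]
    if (!is.na(len)) end <- min(end, len)
  }
  list(chrom = gene$chrom, start = start, end = end)
}

gene_windows <- function(genes, flank = 150000, genome = NULL) {
  win <- genes[, c("gene_id", "chrom", "start", "end")]
  win$start <- pmax(0, win$start - flank)
  win$end <- win$end + flank
  if (!is.null(genome)) {
    len <- genome$length[match(win$chrom, genome$chrom)]
    win$end <- ifelse(is.na(len), win$end, pmin(win$end, len))
  }
  win
}

#' Window coverage enrichment between two conditions
#'
#' Per gene, `log2((stim + eps) / (rest + eps))` of library-normalized
#' window read mass (mass / total), with pseudo-mass `eps` applied to the
#' raw masses before normalization; the set-level test is a one-sample
#' paired t-test of the log-ratios against 0. Sets smaller than 3 skip
#' the t-test but still report ratios.
#'
#' @param cov_stim,cov_rest data frames `gene_id`, `mass`, `total`.
#' @param gene_set gene ids to evaluate.
#' @param eps pseudo-mass added to the raw masses.
#' @return List: `ratios` (data frame `gene_id`, `log2_ratio`),
#'   `mean_log2_ratio`, `t`, `p`.
#' @export
coverage_enrichment <- function(cov_stim, cov_rest, gene_set, eps = 1) {
  ms <- match(gene_set, cov_stim$gene_id)
  mr <- match(gene_set, cov_rest$gene_id)
  if (anyNA(ms) || anyNA(mr))
    stopf("coverage missing for %d gene(s) in the set",
          sum(is.na(ms) | is.na(mr)))
  num <- (cov_stim$mass[ms] + eps) / cov_stim$total[ms]
  den <- (cov_rest$mass[mr] + eps) / cov_rest$total[mr]
  lr <- log2(num / den)
  ratios <- data.frame(gene_id = gene_set, log2_ratio = lr,
                       stringsAsFactors = FALSE)
  if (length(lr) >= 3 && sd(lr) > 0) {
    tt <- t.test(lr, mu = 0)
    list(ratios = ratios, mean_log2_ratio = mean(lr),
         t = unname(tt$statistic), p = tt$p.value)
  } else if (length(lr) >= 3 && sd(lr) == 0 && mean(lr) != 0) {
    # identical non-zero ratios: degenerate t, infinitely significant
    list(ratios = ratios, mean_log2_ratio = mean(lr),
         t = sign(mean(lr)) * Inf, p = 0)
  } else {
    list(ratios = ratios, mean_log2_ratio = mean(lr), t = NA_real_,
         p = NA_real_)
  }
}

#' Split peaks into foreground and background by gene windows
#'
#' Foreground: peaks intersecting any sensitive-gene window. Background:
#' peaks intersecting any non-DE-gene window and not already in the
#' foreground (foreground precedence).
#'
#' @param peaks peak data frame.
#' @param sensitive_genes,non_de_genes gene-id vectors.
#' @param genes annotation of all genes.
#' @param flank per-side window flank.
#' @param genome optional genome table for clipping.
#' @return List: `fg`, `bg` (peak data frames).
#' @export
select_fg_bg_peaks <- function(peaks, sensitive_genes, non_de_genes, genes,
                               flank = 150000, genome = NULL) {
  win <- gene_windows(genes, flank = flank, genome = genome)
  overlap_any <- function(ids) {
    w <- win[win$gene_id %in% ids, , drop = FALSE]
    if (!nrow(w) || !nrow(peaks)) return(rep(FALSE, nrow(peaks)))
    GenomicRanges::countOverlaps(granges0(peaks), granges0(w)) > 0
  }
  in_fg <- overlap_any(sensitive_genes)
  if (!any(in_fg)) stopf("no peaks intersect the sensitive-gene windows")
  in_bg <- overlap_any(non_de_genes) & !in_fg
  list(fg = peaks[in_fg, , drop = FALSE], bg = peaks[in_bg, , drop = FALSE])
}

#' Motif enrichment in foreground vs background peaks
#'
#' A peak "has" a motif when [scan_pwm()] reports at least one hit in its
#' sequence. Per motif, a one-sided binomial test compares the foreground
#' hit count against the background hit rate as the null probability
#' (background taken as known since it is much larger in intended use);
#' a zero background rate with foreground hits is floored at
#' `1 / (2 * n_bg)`. BH across motifs.
#'
#' @param fg_peaks,bg_peaks peak data frames (disjoint).
#' @param sequences named character vector keyed by `peak_id` covering
#'   both sets.
#' @param pwms named list of `pwm` objects.
#' @param threshold_frac hit threshold fraction for [scan_pwm()].
#' @return Data frame: `motif`, `fg_rate`, `bg_rate`, `p`, `q`.
#' @export
motif_enrichment <- function(fg_peaks, bg_peaks, sequences, pwms,
                             threshold_frac = 0.8) {
  if (!nrow(fg_peaks) || !nrow(bg_peaks))
    stopf("foreground and background peak sets must be non-empty")
  if (length(intersect(fg_peaks$peak_id, bg_peaks$peak_id)))
    stopf("foreground and background peak ids overlap")
  miss <- setdiff(c(fg_peaks$peak_id, bg_peaks$peak_id), names(sequences))
  if (length(miss)) stopf("missing sequence for %d peak(s)", length(miss))
  has_motif <- function(ids, pwm) {
    vapply(ids, function(id) {
      s <- sequences[[id]]
      if (nchar(s) < pwm$length) return(FALSE)
      nrow(scan_pwm(s, pwm, threshold_frac)) > 0
    }, TRUE)
  }
  res <- do.call(rbind, lapply(names(pwms), function(nm) {
    fg_hit <- sum(has_motif(fg_peaks$peak_id, pwms[[nm]]))
    bg_hit <- sum(has_motif(bg_peaks$peak_id, pwms[[nm]]))
    n_fg <- nrow(fg_peaks); n_bg <- nrow(bg_peaks)
    bg_rate <- bg_hit / n_bg
    null_rate <- if (bg_rate == 0 && fg_hit > 0) 1 / (2 * n_bg) else bg_rate
    p <- if (fg_hit == 0 && null_rate == 0) 1
    else binom.test(fg_hit, n_fg, p = min(max(null_rate, 1e-12), 1 - 1e-12),
                    alternative = "greater")$p.value
    data.frame(motif = nm, fg_rate = fg_hit / n_fg, bg_rate = bg_rate,
               fg_hits = fg_hit, bg_hits = bg_hit, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res
}

#' Peak-set QC statistics
#'
#' Per sample: peak count, FRiP (fraction of reads overlapping any peak)
#' and the proportion of peaks with signal score > 10. When two groups of
#' matched samples are supplied, the relative peak-count difference
#' `(a - b) / b` per pair and its paired t-test are reported.
#'
#' @param peaks_by_sample named list of peak data frames.
#' @param reads_by_sample named list of read-interval data frames
#'   (`chrom`, `start`, `end`).
#' @param group_a,group_b optional matched sample-name vectors for the
#'   peak-count comparison.
#' @return List: `per_sample` data frame; optional `relative_diff`,
#'   `paired_p`.
#' @export
peak_qc_stats <- function(peaks_by_sample, reads_by_sample,
                          group_a = NULL, group_b = NULL) {
  per <- do.call(rbind, lapply(names(peaks_by_sample), function(nm) {
    pk <- peaks_by_sample[[nm]]
    rd <- reads_by_sample[[nm]]
    if (is.null(rd) || nrow(rd) == 0) stopf("sample '%s' has zero reads", nm)
    frip <- if (nrow(pk)) mean(GenomicRanges::countOverlaps(
      granges0(rd), granges0(pk)) > 0) else 0
    data.frame(sample = nm, n_peaks = nrow(pk), frip = frip,
               frac_signal_gt_10 = if (nrow(pk)) mean(pk$score > 10) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out <- list(per_sample = per)
  if (!is.null(group_a) && !is.null(group_b)) {
    if (length(group_a) != length(group_b))
      stopf("groups must be matched (equal length)")
    na <- per$n_peaks[match(group_a, per$sample)]
    nb <- per$n_peaks[match(group_b, per$sample)]
    rel <- (na - nb) / nb
    out$relative_diff <- rel
    out$mean_relative_diff <- mean(rel)
    out$paired_p <- if (length(rel) >= 2 && sd(na - nb) > 0)
      t.test(na, nb, paired = TRUE)$p.value else NA_real_
  }
  out
}
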