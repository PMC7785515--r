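#' Allele-specific motif disruption score for a SNP
#'
#' Scores every motif placement overlapping the SNP position on both
#' strands, for the reference and the alternate allele, and reports the
#' per-allele maxima. `delta = best_alt - best_ref` (bits); the SNP is
#' `disrupting` when the better allele reaches the hit threshold
#' (`hit_frac * max_score`) and `|delta| >= delta_min`.
#'
#' @param snp list/row with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param pwm a `pwm` object.
#' @param window sequence string covering the SNP.
#' @param window_start 0-based genomic start of `window`.
#' @param hit_frac hit threshold as a fraction of the motif's maximal
#'   score.
#' @param delta_min minimal |delta| (bits) to call disruption.
#' @return List: `best_ref`, `best_alt`, `delta`, `disrupting`,
#'   `ref_mismatch`.
#' @export
tfbs_disruption <- function(snp, pwm, window, window_start = 0,
                            hit_frac = 0.8, delta_min = 1) {
  rel <- snp$pos - window_start + 1L  # 1-based position within window
  L <- pwm$length
  if (rel < 1 || rel > nchar(window))
    stopf("window does not cover SNP position")
  lo <- rel - L + 1L; hi <- rel + L - 1L
  if (lo < 1 || hi > nchar(window))
    stopf("window too short: needs pos +/- (motif length - 1)")
  ref_at <- substr(window, rel, rel)
  mismatch <- toupper(ref_at) != toupper(snp$ref)
  if (mismatch) {
    warnf("reference allele mismatch at %s:%d (sequence %s, SNP %s); skipped",
          snp$chrom, snp$pos, ref_at, snp$ref)
    return(list(best_ref = NA_real_, best_alt = NA_real_, delta = NA_real_,
                disrupting = FALSE, ref_mismatch = TRUE))
  }
  slice <- substr(window, lo, hi)
  alt_slice <- slice
  substr(alt_slice, L, L) <- toupper(snp$alt)
  best <- function(s) {
    code <- seq_to_code(s)
    max(pwm_scores(code, pwm), pwm_scores(seq_to_code(revcomp(s)), pwm))
  }
  best_ref <- best(slice)
  best_alt <- best(alt_slice)
  delta <- best_alt - best_ref
  thr <- hit_frac * pwm$max_score
  list(best_ref = best_ref, best_alt = best_alt, delta = delta,
       disrupting = max(best_ref, best_alt) >= thr && abs(delta) >= delta_min,
       ref_mismatch = FALSE)
}

#' TFBS disruption annotation across SNPs and motifs
#'
#' @param snps data frame of SNPs (`rsid`, `chrom`, `pos`, `ref`, `alt`).
#' @param pwms named list of `pwm` objects.
#' @param windows named list: per rsid, `list(seq, start)` covering the
#'   SNP.
#' @param hit_frac,delta_min see [tfbs_disruption()].
#' @return Data frame: one row per SNP x motif.
#' @export
tfbs_disruption_table <- function(snps, pwms, windows, hit_frac = 0.8,
                                  delta_min = 1) {
  rows <- list()
  for (i in seq_len(nrow(snps))) {
    w <- windows[[snps$rsid[i]]]
    if (is.null(w)) next
    for (nm in names(pwms)) {
      r <- tryCatch(tfbs_disruption(snps[i, ], pwms[[nm]], w$seq, w$start,
                                    hit_frac, delta_min),
                    error = function(e) NULL)
      if (is.null(r)) next
      rows[[length(rows) + 1]] <- data.frame(
        rsid = snps$rsid[i], motif = nm, best_ref = r$best_ref,
        best_alt = r$best_alt, delta = r$delta, disrupting = r$disrupting,
        ref_mismatch = r$ref_mismatch, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(rsid = character(), motif = character(),
                      best_ref = numeric(), best_alt = numeric(),
                      delta = numeric(), disrupting = logical(),
                      ref_mismatch = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
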