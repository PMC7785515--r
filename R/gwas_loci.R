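# LD-based construction of GWAS disease loci from index SNPs and a
# genotype-dosage panel.

#' Squared LD correlation between two dosage vectors
#'
#' Squared Pearson correlation of 0/1/2 allele dosages.
#'
#' @param g1,g2 equal-length numeric vectors (length >= 3).
#' @return r^2 in [0, 1]; `NA` (with a warning) for constant vectors.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stopf("dosage vectors differ in length")
  if (length(g1) < 3) stopf("need >= 3 samples for LD")
  if (var(g1) == 0 || var(g2) == 0) {
    warnf("constant dosage vector: r^2 undefined")
    return(NA_real_)
  }
  cor(g1, g2)^2
}

merge_intervals <- function(df) {
  if (nrow(df) < 2) return(df)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    last <- nrow(out)
    if (df$chrom[i] == out$chrom[last] && df$start[i] <= out$end[last]) {
      out$end[last] <- max(out$end[last], df$end[i])
      out$members[last] <- paste(out$members[last], df$members[i], sep = ",")
      out$index_snps[last] <- paste(out$index_snps[last], df$index_snps[i],
                                    sep = ",")
    } else {
      out <- rbind(out, df[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Build disease loci from index SNPs via LD expansion
#'
#' Index SNPs are filtered to genome-wide significance (`p < p_max`) and
#' outside the MHC interval. For each remaining index SNP, panel SNPs on
#' the same chromosome within `proxy_radius` with `r^2 > r2_min` become
#' proxies; the locus spans `[min pos, max pos + 1)` over index and
#' proxies, extended by `extend` bp per side and clipped at chromosome
#' bounds. Overlapping loci of the same trait are merged. Index SNPs
#' absent from the panel are kept as singleton loci with a warning.
#'
#' @param index_snps SNP table (0-based `pos`) from [read_snp_table()] or
#'   the simulator.
#' @param dosage samples x SNPs dosage matrix (colnames = rsid).
#' @param snp_pos data frame `rsid`, `chrom`, `pos` for every panel SNP.
#' @param r2_min LD threshold (proxies strictly above).
#' @param extend per-side extension in bp.
#' @param p_max index significance threshold.
#' @param mhc list(chrom, start, end) exclusion interval, or `NULL`.
#' @param proxy_radius search radius around the index SNP.
#' @param genome data frame `chrom`, `length` for clipping; defaults to
#'   [synthetic_genome()].
#' @return Data frame of loci: `trait`, `chrom`, `start`, `end`,
#'   `index_snps`, `members` (comma-separated rsids), `locus_id`.
#' @export
build_loci <- function(index_snps, dosage, snp_pos, r2_min = 0.8,
                       extend = 150000, p_max = 5e-8,
                       mhc = list(chrom = "chr6", start = 25000000,
                                  end = 34000000),
                       proxy_radius = 1000000, genome = synthetic_genome()) {
  snps <- index_snps[index_snps$pvalue < p_max, , drop = FALSE]
  if (!is.null(mhc)) {
    in_mhc <- snps$chrom == mhc$chrom & snps$pos >= mhc$start &
      snps$pos < mhc$end
    snps <- snps[!in_mhc, , drop = FALSE]
  }
  if (nrow(snps) == 0) stopf("no index SNPs remain after p-value/MHC filters")
  absent <- setdiff(snps$rsid, colnames(dosage))
  if (length(absent))
    warnf("%d index SNP(s) absent from the panel kept as singleton loci",
          length(absent))
  loci <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    members <- s$rsid
    span <- c(s$pos, s$pos + 1L)
    if (s$rsid %in% colnames(dosage)) {
      cand <- snp_pos[snp_pos$chrom == s$chrom &
                        abs(snp_pos$pos - s$pos) <= proxy_radius &
                        snp_pos$rsid != s$rsid &
                        snp_pos$rsid %in% colnames(dosage), , drop = FALSE]
      if (nrow(cand)) {
        r2 <- apply(dosage[, cand$rsid, drop = FALSE], 2, function(g)
          suppressWarnings(ld_r2(dosage[, s$rsid], g)))
        proxies <- cand[!is.na(r2) & r2 > r2_min, , drop = FALSE]
        if (nrow(proxies)) {
          members <- c(members, proxies$rsid)
          span <- c(min(s$pos, proxies$pos), max(s$pos, proxies$pos) + 1L)
        }
      }
    }
    chrom_len <- genome$length[match(s$chrom, genome$chrom)]
    if (is.na(chrom_len)) chrom_len <- Inf
    data.frame(trait = s$trait, chrom = s$chrom,
               start = max(0, span[1] - extend),
               end = min(chrom_len, span[2] + extend),
               index_snps = s$rsid,
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  merged <- do.call(rbind, lapply(split(loci, loci$trait), merge_intervals))
  merged <- merged[order(merged$trait, merged$chrom, merged$start), ]
  merged$locus_id <- sprintf("locus_%03d", seq_len(nrow(merged)))
  rownames(merged) <- NULL
  merged
}

#' Write loci as BED (name = trait)
#' @param loci loci data frame from [build_loci()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  write.table(loci[, c("chrom", "start", "end", "trait")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
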