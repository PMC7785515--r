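#' Simulate a GWAS panel with LD blocks and trait loci
#'
#' Index SNPs are placed near genes chosen so that stimulus-sensitive
#' genes (any non-null truth class in either cell type) are covered by
#' loci at `enrichment_factor` times the rate of non-sensitive genes:
#' with `S` sensitive and `NS` non-sensitive genes,
#' `round(n_loci * e*S / (NS + e*S))` locus centres are sensitive genes
#' and the rest non-sensitive, each drawn uniformly within its group.
#' `enrichment_factor = 1` reduces to proportional sampling (a calibrated
#' null). Each index SNP gets `proxies_per_index` LD proxies: the index
#' haplotypes are copied and each haplotype allele is flipped with
#' probability `flip_prob`, so expected r^2 is `(1 - 2*flip_prob)^2`.
#' Unlinked background SNPs are added. Index SNPs receive genome-wide
#' significant p-values (< 5e-8).
#'
#' @param n_loci number of index SNPs (one locus each before merging).
#' @param n_traits traits assigned round-robin to loci.
#' @param proxies_per_index LD proxies per index SNP.
#' @param flip_prob per-haplotype allele flip probability in [0, 0.5).
#' @param enrichment_factor relative coverage rate of sensitive genes
#'   (>= 1).
#' @param genes gene annotation data frame.
#' @param truth gene truth data frame from [simulate_experiment()].
#' @param n_panel diploid panel samples for LD estimation.
#' @param n_background unlinked background SNPs.
#' @param seed integer seed.
#' @return List: `dosage` (samples x SNPs), `snp_table` (index SNPs),
#'   `snp_pos` (all panel SNP coordinates), `locus_truth` (locus centre
#'   gene per index SNP).
#' @export
simulate_gwas_panel <- function(n_loci, n_traits, proxies_per_index = 10,
                                flip_prob = 0.05, enrichment_factor = 1,
                                genes, truth, n_panel = 100,
                                n_background = 50, seed = 1L) {
  if (flip_prob < 0 || flip_prob >= 0.5) stopf("flip_prob must be in [0, 0.5)")
  if (enrichment_factor < 1) stopf("enrichment_factor must be >= 1")
  set.seed(seed %% 2147480000)
  sensitive <- truth$class_naive != "null" | truth$class_memory != "null"
  S <- sum(sensitive); NS <- sum(!sensitive)
  if (n_loci > nrow(genes)) stopf("more loci than genes on the synthetic genome")
  k <- round(n_loci * enrichment_factor * S / (NS + enrichment_factor * S))
  k <- min(k, S, n_loci)
  centre_idx <- c(sample(which(sensitive), k),
                  sample(which(!sensitive), n_loci - k))
  traits <- sprintf("trait_%02d", rep_len(seq_len(n_traits), n_loci))

  snp_rows <- list(); dos_cols <- list(); truth_rows <- list()
  for (i in seq_len(n_loci)) {
    gene <- genes[centre_idx[i], ]
    pos0 <- as.integer(round((gene$start + gene$end) / 2))
    maf <- runif(1, 0.1, 0.5)
    h1 <- rbinom(n_panel, 1, maf); h2 <- rbinom(n_panel, 1, maf)
    rsid <- sprintf("rs%05d", i * 100)
    ids <- rsid
    dose <- list(h1 + h2)
    positions <- pos0
    for (pn in seq_len(proxies_per_index)) {
      f1 <- rbinom(n_panel, 1, flip_prob); f2 <- rbinom(n_panel, 1, flip_prob)
      p1 <- abs(h1 - f1); p2 <- abs(h2 - f2)
      dose[[pn + 1]] <- p1 + p2
      ids <- c(ids, sprintf("rs%05d", i * 100 + pn))
      positions <- c(positions, pos0 +
                       as.integer(round(runif(1, -50000, 50000))))
    }
    snp_rows[[i]] <- data.frame(
      trait = traits[i], rsid = rsid, chrom = gene$chrom, pos = pos0,
      ref = "A", alt = "G",
      pvalue = 10^runif(1, -12, log10(4.9e-8)),
      stringsAsFactors = FALSE)
    dm <- do.call(cbind, dose)
    colnames(dm) <- ids
    dos_cols[[i]] <- dm
    truth_rows[[i]] <- data.frame(rsid = rsid, trait = traits[i],
                                  centre_gene = gene$gene_id,
                                  centre_sensitive = sensitive[centre_idx[i]],
                                  stringsAsFactors = FALSE)
    attr(dos_cols[[i]], "positions") <- positions
  }
  dosage <- do.call(cbind, dos_cols)
  snp_pos <- data.frame(
    rsid = colnames(dosage),
    chrom = rep(vapply(snp_rows, function(r) r$chrom, ""),
                vapply(dos_cols, ncol, 0L)),
    pos = unlist(lapply(dos_cols, attr, "positions")),
    stringsAsFactors = FALSE)
  # unlinked background SNPs scattered over the genome
  if (n_background > 0) {
    genome <- synthetic_genome()
    bg_chrom <- sample(genome$chrom, n_background, replace = TRUE)
    bg_pos <- as.integer(floor(runif(n_background, 0,
                                     genome$length[match(bg_chrom, genome$chrom)])))
    bg_maf <- runif(n_background, 0.1, 0.5)
    bg <- sapply(bg_maf, function(m) rbinom(n_panel, 2, m))
    colnames(bg) <- sprintf("rsbg%04d", seq_len(n_background))
    dosage <- cbind(dosage, bg)
    snp_pos <- rbind(snp_pos, data.frame(rsid = colnames(bg),
                                         chrom = bg_chrom, pos = bg_pos,
                                         stringsAsFactors = FALSE))
  }
  rownames(dosage) <- sprintf("panel_%03d", seq_len(n_panel))
  snp_table <- do.call(rbind, snp_rows)
  list(dosage = dosage, snp_table = snp_table, snp_pos = snp_pos,
       locus_truth = do.call(rbind, truth_rows))
}
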