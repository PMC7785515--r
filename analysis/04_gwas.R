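#!/usr/bin/env Rscript
# Builds LD-defined disease loci from the simulated index SNPs and panel,
# tests the uniquely stimulus-sensitive genes for locus overlap against
# the size/expression-matched permutation null, lists driver genes, and
# annotates their locus SNPs with peak overlap and PWM disruption.
# Reads results/data and results/classification; writes results/gwas/.

library(stimgrid)

dat <- "results/data"
out <- "results/gwas"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config()

design <- read_design(file.path(dat, "design.tsv"))
counts <- read_counts(file.path(dat, "counts.tsv"), design)
ann <- read_annotation(file.path(dat, "annotation.tsv"))
counts <- filter_genes(counts, ann)
snps <- read_snp_table(file.path(dat, "index_snps.tsv"))
dosage <- read_dosage(file.path(dat, "dosage.tsv"))
snp_pos <- read.delim(file.path(dat, "snp_positions.tsv"))
calls <- read.delim(file.path(out, "..", "classification",
                              "sensitivity_calls.tsv"), comment.char = "#")

loci <- build_loci(snps, dosage, snp_pos, r2_min = cfg$ld_r2,
                   extend = cfg$locus_extend, p_max = cfg$gwas_p,
                   mhc = list(chrom = cfg$mhc_chrom, start = cfg$mhc_start,
                              end = cfg$mhc_end),
                   proxy_radius = cfg$proxy_radius)
write_loci_bed(loci, file.path(out, "loci.bed"))
message(nrow(loci), " unique regions across ",
        length(unique(loci$trait)), " traits")

universe <- ann[ann$gene_id %in% rownames(counts), ]
mean_expr <- rowMeans(log_norm_counts(counts, estimate_size_factors(counts)))
bins <- assign_match_bins(universe, mean_expr)
query <- intersect(unique(unique_sensitivity(calls)$gene_id),
                   universe$gene_id)

enr <- trait_enrichment(query, loci, universe, bins, B = cfg$n_perm_gwas,
                        seed = cfg$seed + 401)
overall <- permutation_enrichment(query, loci, universe, bins,
                                  B = cfg$n_perm_gwas, seed = cfg$seed + 402)
enr <- rbind(enr, data.frame(trait = "all_traits", observed = overall$observed,
                             null_mean = overall$null_mean,
                             null_sd = overall$null_sd, p = overall$p))
write_result_table(enr, file.path(out, "trait_enrichment.tsv"),
                   seed = cfg$seed, config = cfg)
print(enr, row.names = FALSE)

drv <- driver_genes(query, loci, universe)
write_result_table(drv, file.path(out, "driver_genes.tsv"),
                   seed = cfg$seed, config = cfg)

peaks <- do.call(rbind, lapply(c("highCD28", "highTCR"), function(cond)
  read_peaks(file.path(dat, paste0("peaks_", cond, ".bed")), cond)))
ov <- snp_peak_overlap(drv, loci, snp_pos, peaks, universe,
                       flank = cfg$window_flank)
write_result_table(ov$per_gene, file.path(out, "driver_snp_in_peak.tsv"),
                   seed = cfg$seed, config = cfg)
message(sprintf("%.0f%% of driver genes have a locus SNP inside a peak",
                100 * ov$fraction))
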