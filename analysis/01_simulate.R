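#!/usr/bin/env Rscript
# Generates the synthetic stimulation-grid experiment that all downstream
# analyses consume: NB counts for 2 cell types x 7 (TCR, CD28) dose
# conditions x 4 donors, with planted linear/switch sensitivity classes,
# 20 switcher genes, pathway sets, and a GWAS panel with LD blocks whose
# loci cover stimulus-sensitive genes at 3x the background rate.
# Writes everything in the package's file dialects under results/data/.

library(stimgrid)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

params <- simulation_params(n_genes = 1000, n_switchers = 20, seed = 20260922)
sim <- simulate_experiment(params)
write_counts(sim$counts, file.path(out, "counts.tsv"))
write_design(sim$design, file.path(out, "design.tsv"))
write_annotation(sim$annotation, file.path(out, "annotation.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gmt(sim$pathways, file.path(out, "pathways.gmt"))

panel <- simulate_gwas_panel(n_loci = 40, n_traits = 5,
                             genes = sim$annotation, truth = sim$truth,
                             enrichment_factor = 3, seed = 20260923)
write_dosage(panel$dosage, file.path(out, "dosage.tsv"))
write_snp_table(panel$snp_table, file.path(out, "index_snps.tsv"))
write.table(panel$snp_pos, file.path(out, "snp_positions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

pwm <- pwm_from_counts(consensus_counts("TGACTCAT"), name = "ap1_like")
chrom <- simulate_chromatin(c("resting", "highCD28", "highTCR"),
                            sim$annotation, sim$truth,
                            list(ap1_like = pwm), planted_motif_rate = 0.5,
                            seed = 20260924)
for (cond in names(chrom$peaks)) {
  write_peaks(chrom$peaks[[cond]], file.path(out, paste0("peaks_", cond, ".bed")))
  write_fasta(chrom$sequences[[cond]],
              file.path(out, paste0("peak_seqs_", cond, ".fa")))
  write.table(chrom$coverage[[cond]],
              file.path(out, paste0("window_mass_", cond, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message("simulated ", nrow(sim$counts), " genes x ", ncol(sim$counts),
        " samples; ", nrow(panel$snp_table), " index SNPs; peaks for ",
        length(chrom$peaks), " conditions -> ", out)
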