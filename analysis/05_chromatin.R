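#!/usr/bin/env Rscript
# Chromatin analytics on the simulated peak calls: window-coverage
# enrichment of CD28-sensitive genes under highCD28 stimulation vs
# resting, motif enrichment in peaks near sensitive genes versus peaks
# near non-DE genes, and peak-set QC. Reads results/data and
# results/classification; writes results/chromatin/.

library(stimgrid)

dat <- "results/data"
out <- "results/chromatin"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config()

design <- read_design(file.path(dat, "design.tsv"))
counts <- read_counts(file.path(dat, "counts.tsv"), design)
ann <- read_annotation(file.path(dat, "annotation.tsv"))
counts <- filter_genes(counts, ann)
truth <- read.delim(file.path(dat, "truth.tsv"))
calls <- read.delim(file.path(dat, "..", "classification",
                              "sensitivity_calls.tsv"), comment.char = "#")

# window-coverage enrichment: CD28-called genes in naive cells (the
# chromatin simulator plants its signal by the naive-cell class),
# highCD28 vs resting
cd28_genes <- unique(calls$gene_id[calls$stimulus == "CD28" &
                                     calls$cell_type == "naive"])
cov_stim <- read.delim(file.path(dat, "window_mass_highCD28.tsv"))
cov_rest <- read.delim(file.path(dat, "window_mass_resting.tsv"))
ce <- coverage_enrichment(cov_stim, cov_rest, cd28_genes,
                          eps = cfg$coverage_pseudomass)
write_result_table(ce$ratios, file.path(out, "coverage_ratios.tsv"),
                   seed = cfg$seed, config = cfg)
message(sprintf("mean log2 coverage ratio %.2f over %d CD28-sensitive genes (paired t p = %.2g)",
                ce$mean_log2_ratio, length(cd28_genes), ce$p))

# motif enrichment: peaks near sensitive genes vs peaks near non-DE genes
peaks <- read_peaks(file.path(dat, "peaks_highCD28.bed"), "highCD28")
seqs <- read_fasta(file.path(dat, "peak_seqs_highCD28.fa"))
names(seqs) <- sub(" .*", "", names(seqs))
# the FASTA is keyed by the simulator's peak ids, which sit in the BED
# name column; remap to the ids assigned on re-read (same line order)
raw <- read.delim(file.path(dat, "peaks_highCD28.bed"), header = FALSE)
id_map <- setNames(peaks$peak_id, raw$V4)
names(seqs) <- unname(id_map[names(seqs)])
sens <- unique(calls$gene_id[calls$stimulus %in% c("TCR", "CD28")])
non_de <- setdiff(rownames(counts), unique(calls$gene_id))
fgbg <- select_fg_bg_peaks(peaks, sens, non_de, ann,
                           flank = cfg$window_flank,
                           genome = synthetic_genome())
pwm <- pwm_from_counts(consensus_counts("TGACTCAT"), name = "ap1_like")
me <- motif_enrichment(fgbg$fg, fgbg$bg, seqs, list(ap1_like = pwm),
                       threshold_frac = cfg$pwm_hit_frac)
write_result_table(me, file.path(out, "motif_enrichment.tsv"),
                   seed = cfg$seed, config = cfg)
print(me, row.names = FALSE)

# peak-set QC on the three simulated conditions; read-level simulation is
# out of scope, so the peak intervals themselves stand in as read
# intervals, which exercises the FRiP/count machinery end to end
conds <- c("resting", "highCD28", "highTCR")
pk_by <- lapply(conds, function(cond)
  read_peaks(file.path(dat, paste0("peaks_", cond, ".bed")), cond))
names(pk_by) <- conds
reads_by <- lapply(pk_by, function(p) p[, c("chrom", "start", "end")])
qc <- peak_qc_stats(pk_by, reads_by)
write_result_table(qc$per_sample, file.path(out, "peak_qc.tsv"),
                   seed = cfg$seed, config = cfg)
print(qc$per_sample, row.names = FALSE)
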