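#!/usr/bin/env Rscript
# Classifies activation-upregulated genes as TCR- or CD28-sensitive under
# the linear (dose) and switch (presence) NB models, separately for naive
# and memory cells, then derives switcher genes and summary counts.
# Reads results/data/ (from 01_simulate.R), writes results/classification/.

library(stimgrid)

dat <- "results/data"
out <- "results/classification"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- default_config()

design <- read_design(file.path(dat, "design.tsv"))
counts <- read_counts(file.path(dat, "counts.tsv"), design)
ann <- read_annotation(file.path(dat, "annotation.tsv"))
truth <- read.delim(file.path(dat, "truth.tsv"))

counts <- filter_genes(counts, ann)
message("kept ", nrow(counts), " genes after the autosome/X and ",
        ">=20-in->=3 filters")

cls <- classify_experiment(counts, design, cfg)
write_result_table(cls$calls, file.path(out, "sensitivity_calls.tsv"),
                   seed = cfg$seed, config = cfg)
summ <- summarize_sensitivity(cls$calls)
write_result_table(summ, file.path(out, "sensitivity_summary.tsv"),
                   seed = cfg$seed, config = cfg)
print(summ, row.names = FALSE)

sw <- find_switchers(cls$naive$calls, cls$memory$calls)
write_result_table(
  data.frame(direction = rep(c("tcr_to_cd28", "cd28_to_tcr"),
                             c(length(sw$tcr_to_cd28), length(sw$cd28_to_tcr))),
             gene_id = c(sw$tcr_to_cd28, sw$cd28_to_tcr)),
  file.path(out, "switchers.tsv"), seed = cfg$seed, config = cfg)

planted <- truth$gene_id[truth$class_naive == "tcr_linear" &
                           truth$class_memory == "cd28_linear"]
message("switchers: ", length(sw$tcr_to_cd28), " TCR->CD28 called, ",
        length(intersect(sw$tcr_to_cd28, planted)), " of ",
        length(planted), " planted recovered")

# truth-aware recovery table for the synthetic run
for (ct in c("naive", "memory")) {
  calls <- cls[[ct]]$calls
  tr <- truth[[paste0("class_", ct)]][match(calls$gene_id, truth$gene_id)]
  tab <- table(truth = tr, call = calls$stimulus)
  message(ct, " recovery:")
  print(tab)
}
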