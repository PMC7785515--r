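#' Run the full synthetic-data pipeline
#'
#' Generates a synthetic experiment, classifies stimulus-sensitive genes
#' in both cell types, runs preranked GSEA on the naive-cell TCR
#' linear-model fold-change ranking, builds GWAS loci from a simulated
#' panel and tests the sensitive-gene set with the matched permutation
#' null, and computes chromatin window-coverage and motif enrichment.
#' Every output table is written under `out_dir` with a provenance
#' header; identical `(params, config, seed)` give byte-identical tables.
#'
#' @param out_dir output directory (created if needed).
#' @param params [simulation_params()] object; the seed inside it drives
#'   all randomness.
#' @param config configuration list.
#' @param n_loci,n_traits GWAS panel shape.
#' @param gsea_perm,gwas_perm permutation counts (kept modest by default;
#'   raise via arguments for production-scale runs).
#' @return Invisible list with the main in-memory results.
#' @export
run_pipeline <- function(out_dir, params = simulation_params(n_genes = 300),
                         config = default_config(), n_loci = 20, n_traits = 4,
                         gsea_perm = 500, gwas_perm = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- params$seed
  wt <- function(df, name) write_result_table(df, file.path(out_dir, name),
                                              seed = seed, config = config)
  sim <- simulate_experiment(params)
  counts <- filter_genes(sim$counts, sim$annotation)
  cls <- classify_experiment(counts, sim$design, config)
  wt(cls$calls, "sensitivity_calls.tsv")
  wt(summarize_sensitivity(cls$calls), "sensitivity_summary.tsv")
  sw <- find_switchers(cls$naive$calls, cls$memory$calls)
  wt(data.frame(direction = rep(c("tcr_to_cd28", "cd28_to_tcr"),
                                c(length(sw$tcr_to_cd28), length(sw$cd28_to_tcr))),
                gene_id = c(sw$tcr_to_cd28, sw$cd28_to_tcr)),
     "switchers.tsv")

  # GSEA on the naive-cell TCR linear-model fold-change ranking
  lin <- cls$naive$stage_results$TCR_linear
  ranking <- ranked_list(lin$gene_id, lin$log2fc)
  gsea <- gsea_test(ranking, sim$pathways, n_perm = gsea_perm,
                    seed = seed + 101, min_size = config$gsea_min_size,
                    max_size = config$gsea_max_size)
  wt(gsea[, c("set", "size", "es", "nes", "p", "q")], "gsea_results.tsv")

  # GWAS locus enrichment of uniquely sensitive genes
  panel <- simulate_gwas_panel(n_loci = n_loci, n_traits = n_traits,
                               genes = sim$annotation, truth = sim$truth,
                               enrichment_factor = 3, seed = seed + 202)
  loci <- build_loci(panel$snp_table, panel$dosage, panel$snp_pos,
                     r2_min = config$ld_r2, extend = config$locus_extend,
                     p_max = config$gwas_p,
                     mhc = list(chrom = config$mhc_chrom,
                                start = config$mhc_start,
                                end = config$mhc_end),
                     proxy_radius = config$proxy_radius)
  wt(loci[, c("trait", "chrom", "start", "end", "locus_id")], "loci.tsv")
  universe <- sim$annotation[sim$annotation$gene_id %in% rownames(counts), ]
  mean_expr <- rowMeans(log_norm_counts(counts, estimate_size_factors(counts)))
  bins <- assign_match_bins(universe, mean_expr)
  query <- intersect(unique(unique_sensitivity(cls$calls)$gene_id),
                     universe$gene_id)
  enr <- permutation_enrichment(query, loci, universe, bins, B = gwas_perm,
                                seed = seed + 303)
  wt(data.frame(query_size = length(query), observed = enr$observed,
                null_mean = enr$null_mean, null_sd = enr$null_sd, p = enr$p),
     "gwas_enrichment.tsv")

  # chromatin: coverage enrichment and motif enrichment vs background
  pwm <- pwm_from_counts(consensus_counts("TGACTCAT"), name = "planted_ap1")
  chrom <- simulate_chromatin(c("resting", "highCD28"), sim$annotation,
                              sim$truth, list(planted_ap1 = pwm),
                              planted_motif_rate = 0.5, seed = seed + 404)
  cd28_genes <- sim$truth$gene_id[sim$truth$class_naive %in%
                                    c("cd28_linear", "cd28_switch")]
  cov <- coverage_enrichment(chrom$coverage$highCD28, chrom$coverage$resting,
                             cd28_genes, eps = config$coverage_pseudomass)
  wt(cov$ratios, "coverage_ratios.tsv")
  non_de <- setdiff(rownames(counts), unique(cls$calls$gene_id))
  fgbg <- select_fg_bg_peaks(chrom$peaks$highCD28, cd28_genes, non_de,
                             sim$annotation, flank = config$window_flank,
                             genome = synthetic_genome())
  me <- motif_enrichment(fgbg$fg, fgbg$bg, chrom$sequences$highCD28,
                         list(planted_ap1 = pwm),
                         threshold_frac = config$pwm_hit_frac)
  wt(me, "motif_enrichment.tsv")

  invisible(list(sim = sim, classification = cls, switchers = sw,
                 gsea = gsea, loci = loci, gwas = enr, coverage = cov,
                 motif = me))
}

#' Count matrix for a fixed consensus sequence
#'
#' Utility for constructing sharp synthetic motifs: 10 counts on the
#' consensus base per column, 0 elsewhere.
#'
#' @param consensus DNA string.
#' @return 4 x L count matrix.
#' @export
consensus_counts <- function(consensus) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  m <- matrix(0, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  m[cbind(match(bases, rownames(m)), seq_along(bases))] <- 10
  m
}
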