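#' Parameters for the synthetic stimulation-grid experiment
#'
#' The generator emulates the study design: two cell types (naive and
#' memory CD4 T cells), the seven (TCR, CD28) dose conditions, `n_donors`
#' donors sequenced in two batches, and NB-distributed counts with planted
#' effects. Gene classes: `tcr_linear` / `cd28_linear` add
#' `per_increment_log2fc` log2 units per dose increment of their stimulus;
#' `tcr_switch` / `cd28_switch` add `switch_log2fc` whenever their
#' stimulus is present; `both` responds linearly to both stimuli; `null`
#' genes are flat.
#'
#' @param n_genes number of genes.
#' @param n_donors donors per cell type (>= 2), split over two batches.
#' @param class_fractions named fractions over the six classes; must sum
#'   to 1.
#' @param per_increment_log2fc planted linear effect per dose increment.
#' @param switch_log2fc planted switch (presence) effect.
#' @param n_switchers genes planted `tcr_linear` in naive but
#'   `cd28_linear` in memory cells (taken out of the null pool).
#' @param baseline_log2_mean,baseline_log2_sd normal distribution of
#'   baseline log2 expression.
#' @param dispersion_meanlog,dispersion_sdlog log-normal distribution of
#'   the NB dispersion alpha.
#' @param batch_effect_sd sd (log2) of the per-(batch, gene) multiplicative
#'   batch factor.
#' @param library_size_range relative sequencing-depth range (uniform).
#' @param seed integer seed.
#' @return List of class `sim_params`.
#' @export
simulation_params <- function(n_genes = 2000, n_donors = 4,
                              class_fractions = c(tcr_linear = 0.10,
                                                  cd28_linear = 0.10,
                                                  tcr_switch = 0.05,
                                                  cd28_switch = 0.05,
                                                  both = 0.05,
                                                  null = 0.65),
                              per_increment_log2fc = 1.0,
                              switch_log2fc = 2.0,
                              n_switchers = 0,
                              baseline_log2_mean = 5, baseline_log2_sd = 2,
                              dispersion_meanlog = log(0.1),
                              dispersion_sdlog = 0.5,
                              batch_effect_sd = 0.3,
                              library_size_range = c(0.7, 1.4),
                              seed = 1L) {
  classes <- c("tcr_linear", "cd28_linear", "tcr_switch", "cd28_switch",
               "both", "null")
  if (!setequal(names(class_fractions), classes))
    stopf("class_fractions must be named over: %s",
          paste(classes, collapse = ", "))
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stopf("class fractions must sum to 1 (got %.4f)", sum(class_fractions))
  if (n_donors < 2) stopf("n_donors must be >= 2")
  if (batch_effect_sd < 0 || baseline_log2_sd < 0)
    stopf("standard deviations must be >= 0")
  structure(as.list(environment()), class = "sim_params")
}

#' Synthetic genome used by the simulators
#'
#' Four chromosomes of 50 Mb; genes are placed in evenly sized slots with
#' jitter, which enforces a minimum spacing of 100 kb so locus overlap is
#' unambiguous.
#'
#' @return data frame: `chrom`, `length`.
#' @export
synthetic_genome <- function() {
  data.frame(chrom = paste0("chr", 1:4), length = 50000000L,
             stringsAsFactors = FALSE)
}

place_genes <- function(n_genes) {
  genome <- synthetic_genome()
  per_chrom <- diff(round(seq(0, n_genes, length.out = nrow(genome) + 1)))
  ann <- do.call(rbind, lapply(seq_len(nrow(genome)), function(ci) {
    n <- per_chrom[ci]
    if (n == 0) return(NULL)
    slot <- genome$length[ci] / n
    if (slot < 5000) stopf("too many genes for the synthetic genome")
    # one gene per slot; inter-gene spacing of 100 kb when density
    # permits, scaled down with the slot size otherwise
    spacing <- min(100000, floor(slot / 2))
    len <- pmin(round(rlnorm(n, log(20000), 0.6)),
                round(slot - spacing - 1000))
    len <- pmax(len, 1000L)
    start <- round((seq_len(n) - 1) * slot +
                     runif(n, 0, slot - len - spacing))
    data.frame(chrom = genome$chrom[ci], start = as.integer(start),
               end = as.integer(start + len),
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  ann <- ann[order(match(ann$chrom, genome$chrom), ann$start), ]
  ann$gene_id <- sprintf("gene_%04d", seq_len(nrow(ann)))
  ann$length <- ann$end - ann$start
  rownames(ann) <- NULL
  ann[, c("gene_id", "chrom", "start", "end", "strand", "length")]
}

class_effect_log2 <- function(class, per_inc, sw, tcr_dose, cd28_dose) {
  switch(class,
         tcr_linear = per_inc * tcr_dose,
         cd28_linear = per_inc * cd28_dose,
         tcr_switch = sw * (tcr_dose > 0),
         cd28_switch = sw * (cd28_dose > 0),
         both = per_inc * tcr_dose + per_inc * cd28_dose,
         null = 0)
}

#' Simulate the seven-condition stimulation experiment
#'
#' Draws counts `y ~ NB(mean = s_j * q_gj, dispersion = alpha_g)` with
#' `log2 q_gj = baseline_g + class effect(condition) + batch term` for all
#' 7 conditions x 2 cell types x n_donors samples. Gene classes are
#' assigned by the configured fractions (identically in both cell types),
#' except for `n_switchers` genes planted TCR-linear in naive and
#' CD28-linear in memory cells. Also plants pathway gene sets for
#' enrichment testing: one set per planted stimulus plus size-matched
#' null sets.
#'
#' @param params a [simulation_params()] object.
#' @return List: `counts`, `design`, `annotation`, `truth`, `pathways`,
#'   `params`.
#' @export
simulate_experiment <- function(params = simulation_params()) {
  stopifnot(inherits(params, "sim_params"))
  grid <- condition_grid()
  # fixed seed offsets per block: gene attributes, design, counts
  set.seed(params$seed %% 2147480000)
  ann <- place_genes(params$n_genes)
  G <- params$n_genes
  classes <- sample(names(params$class_fractions), G, replace = TRUE,
                    prob = params$class_fractions)
  class_naive <- class_memory <- classes
  if (params$n_switchers > 0) {
    pool <- which(classes == "null")
    if (length(pool) < params$n_switchers)
      stopf("not enough null genes to plant %d switchers", params$n_switchers)
    sw <- pool[seq_len(params$n_switchers)]
    class_naive[sw] <- "tcr_linear"
    class_memory[sw] <- "cd28_linear"
  }
  baseline <- rnorm(G, params$baseline_log2_mean, params$baseline_log2_sd)
  alpha <- rlnorm(G, params$dispersion_meanlog, params$dispersion_sdlog)

  design <- do.call(rbind, lapply(c("naive", "memory"), function(ct) {
    do.call(rbind, lapply(seq_len(params$n_donors), function(d) {
      data.frame(sample_id = sprintf("%s_%s_d%d", ct, grid$condition, d),
                 cell_type = ct, tcr_dose = grid$tcr_dose,
                 cd28_dose = grid$cd28_dose, donor = sprintf("d%d", d),
                 batch = sprintf("b%d", 1 + (d > params$n_donors / 2)),
                 stringsAsFactors = FALSE)
    }))
  }))
  design <- validate_design(design)
  n_samp <- nrow(design)
  lib <- runif(n_samp, params$library_size_range[1], params$library_size_range[2])
  batches <- sort(unique(design$batch))
  batch_fx <- matrix(rnorm(G * length(batches), 0, params$batch_effect_sd),
                     G, length(batches), dimnames = list(ann$gene_id, batches))

  counts <- matrix(0L, G, n_samp, dimnames = list(ann$gene_id, design$sample_id))
  cls_by_ct <- list(naive = class_naive, memory = class_memory)
  log2q <- matrix(0, G, n_samp)
  for (j in seq_len(n_samp)) {
    cls <- cls_by_ct[[design$cell_type[j]]]
    eff <- vapply(cls, class_effect_log2, 0,
                  per_inc = params$per_increment_log2fc,
                  sw = params$switch_log2fc,
                  tcr_dose = design$tcr_dose[j],
                  cd28_dose = design$cd28_dose[j])
    log2q[, j] <- baseline + eff + batch_fx[, design$batch[j]]
  }
  mu <- sweep(2^log2q, 2, lib, "*")
  for (g in seq_len(G)) {
    counts[g, ] <- if (alpha[g] < 1e-8) stats::rpois(n_samp, mu[g, ])
    else rnbinom(n_samp, size = 1 / alpha[g], mu = mu[g, ])
  }

  truth <- data.frame(gene_id = ann$gene_id, class_naive = class_naive,
                      class_memory = class_memory,
                      per_increment_log2fc = ifelse(
                        classes %in% c("tcr_linear", "cd28_linear", "both") |
                          class_naive != class_memory,
                        params$per_increment_log2fc, 0),
                      switch_log2fc = ifelse(
                        classes %in% c("tcr_switch", "cd28_switch"),
                        params$switch_log2fc, 0),
                      stringsAsFactors = FALSE)

  pathways <- plant_pathways(truth)
  list(counts = counts, design = design, annotation = ann, truth = truth,
       pathways = pathways, params = params)
}

# Planted pathway sets: one per stimulus drawing from genes with planted
# effects for that stimulus (naive-cell classes), plus null sets of
# matching size drawn from null genes.
plant_pathways <- function(truth, set_size = 30, n_null_sets = 8) {
  fg_tcr <- truth$gene_id[truth$class_naive %in% c("tcr_linear", "tcr_switch")]
  fg_cd28 <- truth$gene_id[truth$class_naive %in% c("cd28_linear", "cd28_switch")]
  nulls <- truth$gene_id[truth$class_naive == "null"]
  sets <- list()
  if (length(fg_tcr) >= 5)
    sets$planted_tcr_response <- sample(fg_tcr, min(set_size, length(fg_tcr)))
  if (length(fg_cd28) >= 5)
    sets$planted_cd28_response <- sample(fg_cd28, min(set_size, length(fg_cd28)))
  for (i in seq_len(n_null_sets)) {
    sets[[sprintf("null_set_%02d", i)]] <-
      sample(nulls, min(set_size, length(nulls)))
  }
  sets
}
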