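# Classification of activation-upregulated genes as TCR- or CD28-sensitive
# under a linear (dose) or switch (presence) NB model, with linear-model
# prioritisation, per cell type.

#' Upregulated gene set for one cell type
#'
#' Union of genes passing the pairwise Wald test (fold-change and FDR
#' gates) in at least one stimulated-vs-resting contrast. All six
#' stimulated conditions must be present.
#'
#' @param de Wald results from [wald_de_test()] for one cell type.
#' @return Character vector of gene ids.
#' @export
upregulated_gene_set <- function(de) {
  expected <- setdiff(condition_grid()$condition, "resting")
  miss <- setdiff(expected, unique(de$contrast))
  if (length(miss)) stopf("missing contrast(s) vs resting: %s",
                          paste(miss, collapse = ", "))
  sort(unique(de$gene_id[de$upregulated]))
}

# build the per-stimulus LRT designs; the other stimulus is absorbed into
# the intercept (not modelled), per the grouping rule: when testing CD28,
# highTCR-alone sits at CD28 dose 0 together with resting.
stimulus_designs <- function(design, stimulus, model) {
  dose <- dose_encoding(design, stimulus)
  if (length(unique(dose)) < 2)
    stopf("stimulus %s has < 2 distinct dose levels in the design", stimulus)
  covar <- if (model == "linear") dose else as.integer(dose > 0)
  batch <- factor(design$batch)
  if (nlevels(batch) > 1) {
    full <- model.matrix(~covar + batch)
    reduced <- model.matrix(~batch)
  } else {
    full <- model.matrix(~covar)
    reduced <- matrix(1, nrow(design), 1, dimnames = list(NULL, "(Intercept)"))
  }
  list(full = full, reduced = reduced)
}

#' Dose-model LRT for one stimulus
#'
#' Linear model: NB LRT of `~ dose + batch` versus `~ batch` with the
#' stimulus dose as a numeric 0/1/2 covariate, so the coefficient is the
#' per-increment log fold-change. Switch model: the covariate is the
#' presence indicator `dose > 0`. All seven conditions are used.
#'
#' @param counts genes x samples matrix (one cell type), already reduced
#'   to the genes under test.
#' @param design validated design rows for those samples.
#' @param stimulus `"TCR"` or `"CD28"`.
#' @param model `"linear"` or `"switch"`.
#' @param size_factors per-sample size factors.
#' @param dispersions optional [estimate_dispersions()] result; when
#'   `NULL` (recommended) dispersions are estimated under this test's own
#'   full design, which keeps the chi-squared reference calibrated.
#' @param prior_var dispersion-shrinkage prior variance; `NULL`
#'   estimates it from the data (see [estimate_dispersions()]).
#' @return Data frame: `gene_id`, `stat`, `p`, `log2fc` (per increment or
#'   switch).
#' @export
stimulus_lrt <- function(counts, design, stimulus, model = c("linear", "switch"),
                         size_factors, dispersions = NULL, prior_var = NULL) {
  model <- match.arg(model)
  d <- stimulus_designs(design, stimulus, model)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, size_factors, d$full,
                                        prior_var = prior_var)
  res <- lrt_test(counts, d$full, d$reduced, size_factors, dispersions)
  data.frame(gene_id = res$gene_id, stat = res$stat, p = res$p,
             log2fc = res$beta_covar / log(2), stringsAsFactors = FALSE)
}

pass_rule <- function(res, q, fc_min) {
  !is.na(q) & q <= 0.05 & res$log2fc >= log2(fc_min) & res$log2fc > 0
}

#' Classify upregulated genes for one cell type
#'
#' For each stimulus, upregulated genes are tested under the linear model
#' (BH across tested genes; pass requires q <= 0.05, per-increment
#' fold-change >= `linear_fc` and a positive coefficient). Genes failing
#' the linear model are then tested under the switch model (BH across
#' switch-stage genes; fold-change gate `switch_fc`). Each gene receives
#' exactly one stimulus label: the single passing stimulus, `both` when
#' TCR and CD28 both pass (reported but excluded from the unique set), or
#' `none`.
#'
#' @param counts genes x samples matrix for one cell type.
#' @param design validated design rows for those samples.
#' @param config configuration list ([default_config()]).
#' @param size_factors,dispersions optional precomputed values; estimated
#'   when `NULL`.
#' @param de optional precomputed [wald_de_test()] results.
#' @return List: `calls` (one row per upregulated gene), `upregulated`,
#'   `de`, `stage_results`, `size_factors`, `dispersions`.
#' @export
classify_cell_type <- function(counts, design, config = default_config(),
                               size_factors = NULL, dispersions = NULL,
                               de = NULL) {
  cell_type <- unique(design$cell_type)
  if (length(cell_type) != 1) stopf("expected a single cell type")
  if (is.null(size_factors))
    size_factors <- robust_size_factors(counts, design$condition)
  if (is.null(dispersions))
    dispersions <- estimate_dispersions(counts, size_factors,
                                        design_condition_batch(design),
                                        fallback_prior_var = config$dispersion_prior_var)
  if (is.null(de))
    de <- wald_de_test(counts, design, size_factors, dispersions,
                       de_fc = config$de_fc, de_fdr = config$de_fdr)
  upreg <- upregulated_gene_set(de)
  sub <- counts[upreg, , drop = FALSE]
  stage <- list()
  pass <- list(); effect <- list(); pq <- list()
  for (stim in c("TCR", "CD28")) {
    lin <- stimulus_lrt(sub, design, stim, "linear", size_factors)
    lin$q <- p.adjust(lin$p, method = "BH")
    lin$pass <- pass_rule(lin, lin$q, config$linear_fc)
    sw_genes <- lin$gene_id[!lin$pass]
    if (length(sw_genes)) {
      sw <- stimulus_lrt(sub[sw_genes, , drop = FALSE], design, stim,
                         "switch", size_factors)
      sw$q <- p.adjust(sw$p, method = "BH")
      sw$pass <- pass_rule(sw, sw$q, config$switch_fc)
    } else {
      sw <- data.frame(gene_id = character(), stat = numeric(), p = numeric(),
                       log2fc = numeric(), q = numeric(), pass = logical())
    }
    stage[[paste0(stim, "_linear")]] <- lin
    stage[[paste0(stim, "_switch")]] <- sw
    m <- match(upreg, lin$gene_id)
    lin_pass <- lin$pass[m]
    sw_m <- match(upreg, sw$gene_id)
    sw_pass <- !is.na(sw_m) & sw$pass[sw_m]
    pass[[stim]] <- list(linear = lin_pass, switch = sw_pass)
    effect[[stim]] <- ifelse(lin_pass, lin$log2fc[m], sw$log2fc[sw_m])
    pq[[stim]] <- list(p = ifelse(lin_pass, lin$p[m], sw$p[sw_m]),
                       q = ifelse(lin_pass, lin$q[m], sw$q[sw_m]))
  }
  tcr_hit <- pass$TCR$linear | pass$TCR$switch
  cd28_hit <- pass$CD28$linear | pass$CD28$switch
  stimulus <- ifelse(tcr_hit & cd28_hit, "both",
                     ifelse(tcr_hit, "TCR", ifelse(cd28_hit, "CD28", "none")))
  model_of <- function(stim) ifelse(pass[[stim]]$linear, "linear",
                                    ifelse(pass[[stim]]$switch, "switch", "none"))
  tcr_model <- model_of("TCR"); cd28_model <- model_of("CD28")
  # for "both" genes report the stimulus with the larger effect
  eff_tcr <- ifelse(tcr_hit, effect$TCR, NA_real_)
  eff_cd28 <- ifelse(cd28_hit, effect$CD28, NA_real_)
  main <- ifelse(stimulus == "both",
                 ifelse(eff_tcr >= eff_cd28, "TCR", "CD28"), stimulus)
  pick <- function(field) {
    v <- rep(NA_real_, length(upreg))
    for (stim in c("TCR", "CD28")) {
      sel <- main == stim
      v[sel] <- if (field == "effect") effect[[stim]][sel]
      else pq[[stim]][[field]][sel]
    }
    v
  }
  calls <- data.frame(
    gene_id = upreg, cell_type = cell_type, stimulus = stimulus,
    model = ifelse(stimulus == "none", "none",
                   ifelse(main == "TCR", tcr_model, cd28_model)),
    log2fc = pick("effect"), p = pick("p"), q = pick("q"),
    tcr_model = tcr_model, cd28_model = cd28_model,
    stronger_stimulus = main,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  list(calls = calls, upregulated = upreg, de = de, stage_results = stage,
       size_factors = size_factors, dispersions = dispersions)
}

#' Classify both cell types
#'
#' Runs [classify_cell_type()] on the naive and memory samples and binds
#' the calls.
#'
#' @param counts filtered genes x samples matrix (both cell types).
#' @param design validated design for all samples.
#' @param config configuration list.
#' @return List: `calls` (both cell types), per-cell-type results in
#'   `naive` / `memory`.
#' @export
classify_experiment <- function(counts, design, config = default_config()) {
  out <- list()
  for (ct in c("naive", "memory")) {
    idx <- design$cell_type == ct
    out[[ct]] <- classify_cell_type(counts[, idx, drop = FALSE],
                                    design[idx, , drop = FALSE], config)
  }
  out$calls <- rbind(out$naive$calls, out$memory$calls)
  out
}

#' Unique single-stimulus sensitivity calls
#'
#' Genes assigned exactly one stimulus (`TCR` or `CD28`); `both` genes are
#' excluded (configurable alternative: `both_stimuli = "stronger"` keeps
#' them under their larger-effect stimulus).
#'
#' @param calls calls data frame.
#' @param both_stimuli `"exclude"` or `"stronger"`.
#' @return Subset of `calls`.
#' @export
unique_sensitivity <- function(calls, both_stimuli = "exclude") {
  if (both_stimuli == "stronger") {
    both <- calls$stimulus == "both"
    calls$stimulus[both] <- calls$stronger_stimulus[both]
  }
  calls[calls$stimulus %in% c("TCR", "CD28"), , drop = FALSE]
}

#' Switcher genes between cell types
#'
#' Genes with unique TCR sensitivity in naive cells and CD28 sensitivity
#' in memory cells (and the converse set).
#'
#' @param calls_naive,calls_memory calls data frames for the two cell
#'   types.
#' @return List: `tcr_to_cd28`, `cd28_to_tcr` (character vectors).
#' @export
find_switchers <- function(calls_naive, calls_memory) {
  un <- unique_sensitivity(calls_naive)
  um <- unique_sensitivity(calls_memory)
  stim_n <- setNames(un$stimulus, un$gene_id)
  stim_m <- setNames(um$stimulus, um$gene_id)
  shared <- intersect(names(stim_n), names(stim_m))
  list(
    tcr_to_cd28 = sort(shared[stim_n[shared] == "TCR" & stim_m[shared] == "CD28"]),
    cd28_to_tcr = sort(shared[stim_n[shared] == "CD28" & stim_m[shared] == "TCR"])
  )
}

#' Summarise sensitivity calls
#'
#' Per cell type: counts of TCR / CD28 / both / none among upregulated
#' genes, the fraction with unique single-stimulus sensitivity, and the
#' linear vs switch split among uniquely sensitive genes.
#'
#' @param calls calls data frame (one or both cell types).
#' @return Data frame, one row per cell type.
#' @export
summarize_sensitivity <- function(calls) {
  do.call(rbind, lapply(split(calls, calls$cell_type), function(cc) {
    n <- nrow(cc)
    tab <- table(factor(cc$stimulus, levels = c("TCR", "CD28", "both", "none")))
    uni <- cc[cc$stimulus %in% c("TCR", "CD28"), ]
    data.frame(cell_type = unique(cc$cell_type), n_upregulated = n,
               n_tcr = unname(tab["TCR"]), n_cd28 = unname(tab["CD28"]),
               n_both = unname(tab["both"]), n_none = unname(tab["none"]),
               frac_unique = nrow(uni) / max(n, 1),
               frac_linear = if (nrow(uni)) mean(uni$model == "linear") else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
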