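#' Default run configuration
#'
#' All thresholds and priors used across the pipeline, in one list.
#' Fold-change gates: pairwise DE requires fold-change >= `de_fc` at BH FDR
#' `de_fdr`; the linear dose model requires a per-increment fold-change >=
#' `linear_fc`; the switch (presence) model requires fold-change >=
#' `switch_fc`. GWAS loci are built from index SNPs at `gwas_p`, expanded
#' to LD proxies at r^2 > `ld_r2` and extended by `locus_extend` bp per
#' side; `window_flank` is the per-side flank of gene windows used in the
#' chromatin analyses. `beta_prior_var` and `dispersion_prior_var` are the
#' normal prior variances (log scale) for optional LFC shrinkage and for
#' dispersion shrinkage toward the mean-dispersion trend.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    de_fc = 2, de_fdr = 0.05,
    linear_fc = 1.5, switch_fc = 2,
    ld_r2 = 0.8, locus_extend = 150000L, gwas_p = 5e-8,
    proxy_radius = 1000000L,
    mhc_chrom = "chr6", mhc_start = 25000000L, mhc_end = 34000000L,
    n_perm_gwas = 10000L, n_perm_gsea = 10000L,
    gsea_min_size = 5L, gsea_max_size = 500L,
    window_flank = 150000L, window_per_side = TRUE,
    beta_prior_var = 0.661, dispersion_prior_var = 0.761,
    pwm_pseudocount = 1, pwm_background = c(0.25, 0.25, 0.25, 0.25),
    pwm_hit_frac = 0.8, tfbs_delta_min = 1,
    coverage_pseudomass = 1,
    annotation_one_based = FALSE,
    allow_custom_grid = FALSE,
    both_stimuli = "exclude",
    seed = 1L
  )
}

#' Read a YAML run configuration
#'
#' Values in the file override [default_config()]; unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path YAML file path.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) stopf("unknown config key(s): %s",
                             paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num <- c("de_fc", "de_fdr", "linear_fc", "switch_fc", "ld_r2",
           "locus_extend", "gwas_p", "window_flank")
  for (k in num) if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
    stopf("config '%s' must be strictly positive", k)
  for (k in c("de_fc", "linear_fc", "switch_fc"))
    if (cfg[[k]] < 1) stopf("fold-change threshold '%s' must be >= 1", k)
  if (cfg$ld_r2 >= 1) stopf("ld_r2 must be < 1")
  cfg
}
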