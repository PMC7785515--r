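# Per-gene Wald and likelihood-ratio differential-expression tests on the
# seven-condition grid. One GLM per gene on the full condition-factor +
# batch design; each stimulated condition is contrasted against resting
# from the coefficient covariance (so all samples inform the error model).

design_condition_batch <- function(design) {
  cond <- factor(design$condition,
                 levels = intersect(condition_grid()$condition,
                                    unique(design$condition)))
  batch <- factor(design$batch)
  if (nlevels(batch) > 1) model.matrix(~cond + batch)
  else model.matrix(~cond)
}

#' Pairwise Wald differential expression against resting
#'
#' Fits, per gene, an NB GLM with condition (factor) and batch covariates
#' on all samples of one cell type, and tests each stimulated condition
#' against resting with a Wald statistic on the condition coefficient.
#' p-values are two-sided from a t reference with `n - p` degrees of
#' freedom (a small-sample correction for the estimated dispersion; the
#' normal reference is anticonservative at four donors per condition).
#' BH correction is applied within each
#' (cell type, contrast) family. A gene is flagged `upregulated` in a
#' contrast when `log2FC >= log2(de_fc)` and `q <= de_fdr`.
#'
#' @param counts genes x samples matrix (one cell type).
#' @param design validated design rows matching the columns of `counts`.
#' @param size_factors per-sample size factors.
#' @param dispersions data frame from [estimate_dispersions()] aligned to
#'   `counts` rows.
#' @param de_fc,de_fdr fold-change and FDR gates for the upregulated flag.
#' @return Data frame: one row per gene x contrast with `log2fc`, `se`,
#'   `stat`, `p`, `q`, `upregulated`.
#' @export
wald_de_test <- function(counts, design, size_factors, dispersions,
                         de_fc = 2, de_fdr = 0.05) {
  if (!identical(design$sample_id, colnames(counts)))
    stopf("design rows must match count columns")
  conds <- setdiff(unique(design$condition), "resting")
  if (!"resting" %in% design$condition) stopf("no resting samples in design")
  for (co in c("resting", conds))
    if (sum(design$condition == co) < 2)
      stopf("condition '%s' has < 2 samples", co)
  X <- design_condition_batch(design)
  cond_cols <- paste0("cond", conds)
  alpha <- dispersions$alpha[match(rownames(counts), dispersions$gene_id)]
  res <- vector("list", nrow(counts))
  ln2 <- log(2)
  tdf <- nrow(X) - ncol(X)
  for (g in seq_len(nrow(counts))) {
    fit <- fit_nb_glm(counts[g, ], X, size_factors, alpha = alpha[g])
    idx <- match(cond_cols, colnames(X))
    lfc <- fit$beta[idx] / ln2
    se <- fit$se[idx] / ln2
    stat <- fit$beta[idx] / fit$se[idx]
    res[[g]] <- data.frame(gene_id = rownames(counts)[g], contrast = conds,
                           log2fc = unname(lfc), se = unname(se),
                           stat = unname(stat),
                           p = 2 * pt(abs(unname(stat)), df = tdf,
                                      lower.tail = FALSE),
                           converged = fit$converged,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- NA_real_
  for (co in conds) {
    idx <- out$contrast == co
    out$q[idx] <- p.adjust(out$p[idx], method = "BH")
  }
  out$upregulated <- !is.na(out$q) & out$log2fc >= log2(de_fc) & out$q <= de_fdr
  rownames(out) <- NULL
  out
}

#' Gene-wise likelihood-ratio tests
#'
#' Runs [nb_lrt()] for every gene at its estimated dispersion and returns
#' the per-gene statistic, chi-squared p-value and the full-model
#' coefficients.
#'
#' @param counts genes x samples matrix.
#' @param X_full,X_reduced nested design matrices.
#' @param size_factors per-sample size factors.
#' @param dispersions data frame from [estimate_dispersions()].
#' @return Data frame: `gene_id`, `stat`, `df`, `p`, one column per full
#'   model coefficient (prefixed `beta_`).
#' @export
lrt_test <- function(counts, X_full, X_reduced, size_factors, dispersions) {
  alpha <- dispersions$alpha[match(rownames(counts), dispersions$gene_id)]
  G <- nrow(counts)
  stats <- numeric(G); ps <- numeric(G); dfs <- integer(G)
  betas <- matrix(NA_real_, G, ncol(X_full),
                  dimnames = list(NULL, paste0("beta_", colnames(X_full))))
  for (g in seq_len(G)) {
    lr <- nb_lrt(counts[g, ], X_full, X_reduced, size_factors, alpha[g])
    stats[g] <- lr$stat; ps[g] <- lr$p; dfs[g] <- lr$df
    betas[g, ] <- lr$fit_full$beta
  }
  cbind(data.frame(gene_id = rownames(counts), stat = stats, df = dfs,
                   p = ps, stringsAsFactors = FALSE),
        as.data.frame(betas))
}
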