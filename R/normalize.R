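#' Filter genes by chromosome and expression support
#'
#' Keeps genes located on autosomes or chromosome X with at least
#' `min_count` reads in at least `min_samples` samples. Genes missing from
#' the annotation are dropped with a warning.
#'
#' @param counts genes x samples integer matrix.
#' @param annotation gene annotation data frame (`gene_id`, `chrom`).
#' @param min_count,min_samples expression support thresholds.
#' @return Filtered count matrix, original gene order preserved.
#' @export
filter_genes <- function(counts, annotation, min_count = 20, min_samples = 3) {
  unann <- setdiff(rownames(counts), annotation$gene_id)
  if (length(unann)) {
    warnf("dropping %d gene(s) absent from the annotation", length(unann))
    counts <- counts[setdiff(rownames(counts), unann), , drop = FALSE]
  }
  chrom <- annotation$chrom[match(rownames(counts), annotation$gene_id)]
  chrom <- sub("^chr", "", chrom)
  keep_chrom <- chrom %in% c(as.character(1:22), "X")
  keep_expr <- rowSums(counts >= min_count) >= min_samples
  out <- counts[keep_chrom & keep_expr, , drop = FALSE]
  if (nrow(out) == 0) stopf("all genes filtered")
  out
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: for each sample, the median across genes of
#' the ratio of its count to the gene's geometric mean, rescaled so the
#' size factors themselves have geometric mean 1. Genes with a zero count
#' anywhere are excluded from the medians; if no gene is positive in every
#' sample, `fallback = TRUE` computes geometric means over positive counts
#' only (the "poscounts" variant).
#'
#' @param counts genes x samples matrix.
#' @param fallback use positive-count geometric means when no gene is
#'   expressed everywhere.
#' @param exclude gene ids to leave out of the medians (e.g. genes known
#'   or suspected to respond to the conditions); the ratio definition is
#'   unchanged, only the gene set the medians run over.
#' @return Named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(counts, fallback = TRUE, exclude = NULL) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  if (!is.null(exclude)) {
    keep <- !(rownames(counts) %in% exclude)
    # never base the medians on fewer than 10% of genes
    if (mean(keep) >= 0.1 && sum(keep) >= 10)
      counts <- counts[keep, , drop = FALSE]
  }
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (any(allpos)) {
    loggeo <- rowMeans(log(counts[allpos, , drop = FALSE]))
    logratio <- log(counts[allpos, , drop = FALSE]) - loggeo
  } else if (fallback) {
    lc <- log(counts)
    lc[!is.finite(lc)] <- NA
    loggeo <- rowMeans(lc, na.rm = TRUE)
    keep <- is.finite(loggeo)
    if (!any(keep)) stopf("cannot estimate size factors: all-zero matrix")
    logratio <- lc[keep, , drop = FALSE] - loggeo[keep]
  } else {
    stopf("no gene with all-positive counts and fallback disabled")
  }
  s <- exp(apply(logratio, 2, median, na.rm = TRUE))
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(counts))
}

#' Condition-robust size factors
#'
#' Median-of-ratios normalization assumes most genes do not change across
#' samples; in strong activation experiments the induced fraction can
#' exceed one half, which drags the medians toward induced genes and
#' attenuates every fold-change. This two-pass variant first estimates
#' plain size factors, then scores each gene by the spread of its log2
#' normalized condition means *studentized* by the gene's own sampling
#' noise (within-condition variance, delta method on the log scale), and
#' recomputes the medians over the condition-stable genes only (score
#' below `score_max`; under no condition effect the spread of seven
#' condition means is about 2.7 noise units). Falls back to the plain
#' estimate when fewer than 10% of genes are stable.
#'
#' @param counts genes x samples matrix.
#' @param conditions per-sample condition labels.
#' @param score_max maximal studentized condition-mean spread for a gene
#'   to count as stable.
#' @return Named numeric vector of positive size factors.
#' @export
robust_size_factors <- function(counts, conditions, score_max = 4.5) {
  s0 <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, s0, "/")
  cond <- factor(conditions)
  G <- nrow(counts)
  cm <- vapply(levels(cond), function(l)
    rowMeans(norm[, cond == l, drop = FALSE]), numeric(G))
  vw <- vapply(levels(cond), function(l)
    apply(norm[, cond == l, drop = FALSE], 1, var), numeric(G))
  n_per <- as.numeric(table(cond))
  range_g <- apply(log2(cm + 0.5), 1, max) - apply(log2(cm + 0.5), 1, min)
  mu_g <- pmax(rowMeans(norm), 0.5)
  v_g <- pmax(rowMeans(vw), mu_g)  # at least Poisson
  sd_log2 <- sqrt(v_g / mean(n_per)) / (mu_g * log(2))
  score <- range_g / pmax(sd_log2, 1e-6)
  responsive <- rownames(counts)[score > score_max]
  if ((G - length(responsive)) / G < 0.1) return(s0)
  estimate_size_factors(counts, exclude = responsive)
}

#' Normalized log2 expression
#'
#' `log2(count / size_factor + 1)`, the working scale for PCA and the
#' variance decomposition.
#'
#' @param counts genes x samples matrix.
#' @param size_factors per-sample size factors.
#' @return Numeric matrix of the same shape.
#' @export
log_norm_counts <- function(counts, size_factors) {
  log2(sweep(counts, 2, size_factors, "/") + 1)
}

#' Variance explained by a single design factor
#'
#' Per-gene R-squared of a one-factor linear model on the normalized log2
#' scale; the summary is the mean R-squared over non-constant genes.
#'
#' @param log_norm genes x samples matrix from [log_norm_counts()].
#' @param factor_values per-sample factor (>= 2 levels present).
#' @return List: `r2` (per gene), `mean_r2`.
#' @export
variance_explained <- function(log_norm, factor_values) {
  f <- factor(factor_values)
  if (nlevels(f) < 2) stopf("factor must have >= 2 levels")
  const <- apply(log_norm, 1, function(x) var(x) == 0)
  if (any(const)) {
    warnf("excluding %d constant gene(s) from variance decomposition",
          sum(const))
    log_norm <- log_norm[!const, , drop = FALSE]
  }
  centered <- log_norm - rowMeans(log_norm)
  sst <- rowSums(centered^2)
  ssb <- Reduce(`+`, lapply(levels(f), function(l) {
    idx <- f == l
    sum(idx) * rowMeans(centered[, idx, drop = FALSE])^2
  }))
  r2 <- ssb / sst
  list(r2 = setNames(r2, rownames(log_norm)), mean_r2 = mean(r2))
}

#' Principal components of normalized expression
#'
#' Gene-centred SVD of the normalized log2 matrix, optionally after
#' regressing a batch indicator out of each gene (a light-weight
#' replacement for empirical-Bayes batch correction, applied only for
#' visualisation/decomposition, never inside the GLM tests, where batch is
#' a design covariate instead).
#'
#' @param log_norm genes x samples matrix.
#' @param batch optional per-sample batch labels.
#' @return List: `scores` (samples x PC), `var_frac`.
#' @export
pca_expression <- function(log_norm, batch = NULL) {
  if (ncol(log_norm) < 3) stopf("PCA needs >= 3 samples")
  x <- log_norm
  if (!is.null(batch)) {
    b <- factor(batch)
    if (nlevels(b) > 1) {
      mm <- model.matrix(~b)
      x <- t(qr.resid(qr(mm), t(x))) + rowMeans(x)
    }
  }
  x <- x - rowMeans(x)
  sv <- svd(t(x))
  var_frac <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u %*% diag(sv$d, length(sv$d))
  rownames(scores) <- colnames(log_norm)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  list(scores = scores, var_frac = var_frac)
}
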