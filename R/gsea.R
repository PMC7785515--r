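# Preranked gene-set enrichment: the weighted Kolmogorov-Smirnov running
# sum on a model-derived fold-change ranking, with a gene-label
# permutation null.

#' Build a ranked gene list
#'
#' Sorted descending by the statistic; ties broken by gene id for
#' determinism. Duplicate genes are rejected.
#'
#' @param gene_ids character vector.
#' @param stat ranking statistic (e.g. linear-model log2 fold-change).
#' @return Named numeric vector (names = gene ids), sorted.
#' @export
ranked_list <- function(gene_ids, stat) {
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids in ranking")
  ord <- order(-stat, gene_ids)
  setNames(stat[ord], gene_ids[ord])
}

#' Weighted KS enrichment score
#'
#' Walking down the ranking, the running sum gains
#' `|stat|^p / sum_set |stat|^p` at set members and loses `1/(N - m)` at
#' non-members; the enrichment score is the extremum. The leading edge is
#' the set members at or before the extremum (after it for negative ES).
#'
#' @param ranking named statistic vector from [ranked_list()].
#' @param set character vector of gene ids.
#' @param p weight exponent (1 = classic weighted statistic).
#' @return List: `es`, `running` (length N), `leading_edge`.
#' @export
enrichment_score <- function(ranking, set, p = 1) {
  N <- length(ranking)
  hits <- names(ranking) %in% set
  m <- sum(hits)
  if (m == 0) stopf("set not represented in the ranking")
  if (m == N) stopf("set covers the entire ranking")
  w <- abs(ranking)^p
  wsum <- sum(w[hits])
  inc <- ifelse(hits, if (wsum > 0) w / wsum else 1 / m, -1 / (N - m))
  if (wsum == 0) inc[!hits] <- -1 / (N - m)
  running <- unname(cumsum(inc))
  imax <- which.max(running); imin <- which.min(running)
  es <- if (running[imax] >= -running[imin]) running[imax] else running[imin]
  peak <- if (es >= 0) imax else imin
  leading <- if (es >= 0) names(ranking)[seq_len(peak)][hits[seq_len(peak)]]
  else names(ranking)[peak:N][hits[peak:N]]
  list(es = es, running = running, leading_edge = leading)
}

# ES for a set given as positions in the ranking; O(m) per call, used by
# the permutation loop. Matches enrichment_score exactly.
es_from_positions <- function(pos, w, N) {
  pos <- sort(pos)
  m <- length(pos)
  wh <- w[pos]
  wsum <- sum(wh)
  gain <- if (wsum > 0) wh / wsum else rep(1 / m, m)
  miss <- 1 / (N - m)
  cum_gain <- cumsum(gain)
  # value just after hit i, and just before hit i
  after <- cum_gain - (pos - seq_len(m)) * miss
  before <- after - gain
  hi <- max(after, 0)
  lo <- min(before, 0)
  if (hi >= -lo) hi else lo
}

#' Permutation preranked GSEA
#'
#' For each gene set, the null ES distribution comes from `n_perm` random
#' gene sets of the same size drawn from the ranking (gene-label
#' permutation). `p = (1 + #{same-sign null |ES| >= |ES_obs|}) /
#' (1 + #same-sign nulls)`; NES divides ES by the mean |null ES| of the
#' same sign;
#' BH across tested sets. Sets smaller than `min_size` (after
#' intersection) or larger than `max_size` are skipped with a warning.
#'
#' @param ranking named statistic vector from [ranked_list()].
#' @param sets named list of gene-id vectors.
#' @param n_perm permutations (>= 100).
#' @param seed integer seed.
#' @param p weight exponent.
#' @param min_size,max_size set-size filters.
#' @return Data frame: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `leading_edge` (comma-separated).
#' @export
gsea_test <- function(ranking, sets, n_perm = 1000, seed = 1L, p = 1,
                      min_size = 5, max_size = 500) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  set.seed(seed %% 2147480000)
  N <- length(ranking)
  w <- abs(ranking)^p
  keep <- vapply(sets, function(s) {
    k <- sum(names(ranking) %in% s)
    k >= min_size && k <= max_size && k < N
  }, TRUE)
  if (any(!keep)) warnf("skipping %d set(s) outside size limits [%d, %d]",
                        sum(!keep), min_size, max_size)
  sets <- sets[keep]
  res <- lapply(names(sets), function(nm) {
    obs <- enrichment_score(ranking, sets[[nm]], p)
    m <- sum(names(ranking) %in% sets[[nm]])
    null_es <- vapply(seq_len(n_perm), function(i)
      es_from_positions(sample.int(N, m), w, N), 0)
    same <- null_es[sign(null_es) == sign(obs$es) | null_es == 0]
    pval <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
    denom <- mean(abs(same))
    data.frame(set = nm, size = m, es = obs$es,
               nes = if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_,
               p = pval,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(out)) out$q <- p.adjust(out$p, method = "BH")
  out
}
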