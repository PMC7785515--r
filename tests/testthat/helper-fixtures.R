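# Shared fixture builders; everything is generated in code at test time.

tiny_counts <- function() {
  m <- matrix(c(10L, 20L, 30L, 60L, 5L, 10L), 3, 2, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  m
}

tiny_design <- function(cell_type = "naive", n_donors = 2) {
  grid <- condition_grid()
  do.call(rbind, lapply(seq_len(n_donors), function(d) {
    data.frame(sample_id = sprintf("%s_%s_d%d", cell_type, grid$condition, d),
               cell_type = cell_type, tcr_dose = grid$tcr_dose,
               cd28_dose = grid$cd28_dose, donor = sprintf("d%d", d),
               batch = sprintf("b%d", 1 + (d %% 2)),
               stringsAsFactors = FALSE)
  }))
}

tiny_annotation <- function(gene_ids, chrom = "chr1") {
  n <- length(gene_ids)
  start <- seq(0, by = 300000L, length.out = n)
  data.frame(gene_id = gene_ids, chrom = chrom, start = start,
             end = start + 10000L, strand = "+", length = 10000L,
             stringsAsFactors = FALSE)
}

# direct O(N * |S|) enrichment-score oracle: recomputes the running sum at
# every rank with sum() rather than incrementally
es_oracle <- function(ranking, set, p = 1) {
  N <- length(ranking)
  hits <- names(ranking) %in% set
  w <- abs(ranking)^p
  wsum <- sum(w[hits])
  inc <- ifelse(hits, w / wsum, -1 / (N - sum(hits)))
  running <- vapply(seq_len(N), function(i) sum(inc[seq_len(i)]), 0)
  imax <- which.max(running); imin <- which.min(running)
  if (running[imax] >= -running[imin]) running[imax] else running[imin]
}
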