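test_that("ld_r2 matches the hand-computed value and edge cases", {
  # cov = 0.375, var1 = 0.6875, var2 = 0.25 -> r2 = 0.375^2 / (0.6875 * 0.25)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)),
               0.375^2 / (0.6875 * 0.25), tolerance = 1e-12)
  expect_equal(round(ld_r2(c(0, 1, 2, 0), c(0, 1, 1, 0)), 4), 0.8182)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_warning(r <- ld_r2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_true(is.na(r))
  expect_error(ld_r2(c(0, 1), c(1, 0)), ">= 3 samples")
  set.seed(501)
  g1 <- rbinom(1000, 2, 0.3); g2 <- rbinom(1000, 2, 0.3)
  expect_lt(ld_r2(g1, g2), 0.01)
})

test_that("locus construction arithmetic, merging and MHC exclusion", {
  dos <- cbind(rs1 = c(0, 1, 2, 0, 1, 2), rs2 = c(0, 1, 2, 0, 1, 2),
               rs3 = c(0, 1, 2, 0, 1, 2))
  rownames(dos) <- paste0("s", 1:6)
  snp_pos <- data.frame(rsid = c("rs1", "rs2", "rs3"), chrom = "chr1",
                        pos = c(1000000L, 990000L, 1020000L))
  idx <- data.frame(trait = "t1", rsid = "rs1", chrom = "chr1",
                    pos = 1000000L, ref = "A", alt = "G", pvalue = 1e-9,
                    stringsAsFactors = FALSE)
  loci <- build_loci(idx, dos, snp_pos)
  expect_equal(loci$start, 840000)
  expect_equal(loci$end, 1170001)
  expect_setequal(strsplit(loci$members, ",")[[1]], c("rs1", "rs2", "rs3"))

  # overlapping spans merge per trait; merging is idempotent
  idx2 <- rbind(idx, data.frame(trait = "t1", rsid = "rs9", chrom = "chr1",
                                pos = 1100000L, ref = "A", alt = "G",
                                pvalue = 1e-9))
  expect_warning(loci2 <- build_loci(idx2, dos, snp_pos), "singleton")
  expect_equal(nrow(loci2), 1)
  expect_equal(loci2$end, 1250001)
  # different traits do not merge
  idx3 <- idx2; idx3$trait <- c("t1", "t2")
  expect_warning(loci3 <- build_loci(idx3, dos, snp_pos))
  expect_equal(nrow(loci3), 2)

  # non-significant and MHC index SNPs are dropped
  idx4 <- rbind(idx, data.frame(trait = "t1", rsid = "rs8", chrom = "chr6",
                                pos = 30000000L, ref = "A", alt = "G",
                                pvalue = 1e-9),
                data.frame(trait = "t1", rsid = "rs7", chrom = "chr1",
                           pos = 5000000L, ref = "A", alt = "G",
                           pvalue = 1e-4))
  loci4 <- build_loci(idx4, dos, snp_pos)
  expect_equal(nrow(loci4), 1)
  expect_error(build_loci(idx4[2:3, ], dos, snp_pos), "no index SNPs")
})

test_that("locus construction is order-independent", {
  sim <- simulate_experiment(simulation_params(n_genes = 60, seed = 502))
  g <- simulate_gwas_panel(n_loci = 8, n_traits = 2, genes = sim$annotation,
                           truth = sim$truth, seed = 3)
  l1 <- build_loci(g$snp_table, g$dosage, g$snp_pos)
  perm <- sample(nrow(g$snp_table))
  l2 <- build_loci(g$snp_table[perm, ], g$dosage, g$snp_pos)
  expect_equal(l1[, c("trait", "chrom", "start", "end")],
               l2[, c("trait", "chrom", "start", "end")])
})

test_that("matching bins partition the universe by quantiles", {
  genes <- tiny_annotation(sprintf("g%03d", 1:100))
  genes$length <- seq_len(100) * 1000L
  expr <- setNames(rnorm(100), genes$gene_id)
  bins <- assign_match_bins(genes, expr)
  expect_length(bins, 100)
  sizes <- table(sub("_.*", "", bins))
  expect_true(all(sizes == 20))  # 20 genes per size quintile
  # degenerate universe collapses to one bin
  genes$length <- 1000L
  b2 <- assign_match_bins(genes, setNames(rep(1, 100), genes$gene_id))
  expect_equal(length(unique(b2)), 1)
  expect_warning(assign_match_bins(genes[1:10, ], expr[1:10]), "coarsening")
})

test_that("permutation p matches exhaustive enumeration on a tiny universe", {
  genes <- tiny_annotation(sprintf("g%02d", 1:12))
  loci <- data.frame(trait = "t1", chrom = "chr1",
                     start = genes$start[c(1, 5, 9)] - 1000,
                     end = genes$end[c(1, 5, 9)] + 1000,
                     index_snps = "rs", members = "rs",
                     locus_id = paste0("locus_", 1:3))
  bins <- setNames(rep("b1", 12), genes$gene_id)
  query <- genes$gene_id[c(1, 5, 9, 2)]  # 3 of 4 in loci
  inloc <- stimgrid:::genes_in_loci(genes, loci)
  combos <- combn(12, 4)
  null_exact <- apply(combos, 2, function(ix) sum(inloc[ix]))
  p_exact <- mean(null_exact >= 3)
  res <- permutation_enrichment(query, loci, genes, bins, B = 10000, seed = 7)
  expect_equal(res$observed, 3)
  expect_lt(abs(res$p - p_exact), 0.02)
  # impossible matching is an error
  expect_error(permutation_enrichment(genes$gene_id, loci, genes[1:3, ],
                                      bins, B = 10),
               "outside the universe")
})

test_that("null-query permutation p-values are uniform", {
  set.seed(503)
  sim <- simulate_experiment(simulation_params(n_genes = 400, seed = 504))
  # enough loci that the overlap statistic takes many values, keeping the
  # permutation p fine-grained
  g <- simulate_gwas_panel(n_loci = 60, n_traits = 3, genes = sim$annotation,
                           truth = sim$truth, enrichment_factor = 1, seed = 5)
  loci <- build_loci(g$snp_table, g$dosage, g$snp_pos)
  genes <- sim$annotation
  bins <- setNames(rep("b1", nrow(genes)), genes$gene_id)
  queries <- lapply(1:200, function(i) sample(genes$gene_id, 100))
  ps <- vapply(1:200, function(i)
    permutation_enrichment(queries[[i]], loci, genes, bins,
                           B = 500, seed = 1000 + i)$p, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("driver genes and SNP-peak overlap follow half-open conventions", {
  genes <- tiny_annotation(c("gA", "gB", "gC"))
  loci <- data.frame(trait = "t1", chrom = "chr1",
                     start = c(genes$start[1] - 10L),
                     end = c(genes$start[1] + 1L),  # 1 bp overlap with gA
                     index_snps = "rs1", members = "rs1,rs2",
                     locus_id = "locus_001")
  drv <- driver_genes(c("gA", "gB", "gC"), loci, genes)
  expect_identical(drv$gene_id, "gA")
  # SNP exactly at peak start is inside; at peak end is not
  snp_pos <- data.frame(rsid = c("rs1", "rs2"), chrom = "chr1",
                        pos = c(100L, 200L))
  peaks <- data.frame(chrom = "chr1", start = 100L, end = 200L, score = 1,
                      condition = "c", peak_id = "p1")
  ov <- snp_peak_overlap(drv, loci, snp_pos, peaks, genes)
  expect_true(ov$per_gene$snp_in_peak[1])
  expect_equal(ov$fraction, 1)
  # move the only inside-SNP to the end coordinate: no overlap
  snp_pos$pos <- c(200L, 300L)
  ov2 <- snp_peak_overlap(drv, loci, snp_pos, peaks, genes)
  expect_false(any(ov2$per_gene$snp_in_peak))
  ov3 <- snp_peak_overlap(drv, loci, snp_pos, peaks[0, ], genes)
  expect_equal(ov3$fraction, 0)
})

test_that("TFBS disruption scoring is monotone in the base substitution", {
  pwm <- pwm_from_counts(consensus_counts("TGACTCA"), name = "ap1")
  win <- paste0("AAAAAA", "TGACTCA", "AAAAAA")
  # SNP at the central consensus base (0-based pos 9 = C of the motif)
  snp <- list(chrom = "chr1", pos = 9L, ref = "C", alt = "A")
  r <- tfbs_disruption(snp, pwm, win, window_start = 0)
  expect_lt(r$delta, 0)
  expect_true(r$disrupting)
  # ref == alt placement: delta 0, not disrupting
  snp2 <- list(chrom = "chr1", pos = 9L, ref = "C", alt = "C")
  r2 <- tfbs_disruption(snp2, pwm, win, window_start = 0)
  expect_equal(r2$delta, 0)
  expect_false(r2$disrupting)
  # mismatched reference allele is skipped with a warning
  snp3 <- list(chrom = "chr1", pos = 9L, ref = "G", alt = "A")
  expect_warning(r3 <- tfbs_disruption(snp3, pwm, win, 0), "mismatch")
  expect_true(r3$ref_mismatch)
  # window too short
  expect_error(tfbs_disruption(snp, pwm, "TGACTCA", 6), "too short")
})

test_that("planted consensus SNPs are flagged as disrupting", {
  set.seed(505)
  pwm <- pwm_from_counts(consensus_counts("TGACTCAT"), name = "m")
  hits <- 0
  for (i in 1:100) {
    flank1 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    flank2 <- paste(sample(c("A", "C", "G", "T"), 10, TRUE), collapse = "")
    win <- paste0(flank1, "TGACTCAT", flank2)
    pos <- 10 + sample(8, 1) - 1          # 0-based SNP inside the motif
    ref <- substr(win, pos + 1, pos + 1)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[sample(3, 1)]
    r <- tfbs_disruption(list(chrom = "c", pos = pos, ref = ref, alt = alt),
                         pwm, win, 0)
    if (r$disrupting) hits <- hits + 1
  }
  expect_gte(hits, 95)
})
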