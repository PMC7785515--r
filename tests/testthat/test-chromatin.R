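test_that("gene windows are flanked and clipped correctly", {
  gene <- list(chrom = "chr1", start = 300000L, end = 310000L)
  w <- gene_window(gene, flank = 150000,
                   genome = data.frame(chrom = "chr1", length = 50000000L))
  expect_equal(w$start, 150000)
  expect_equal(w$end, 460000)
  # clipping at chromosome start and end
  w2 <- gene_window(list(chrom = "chr1", start = 50000L, end = 60000L),
                    flank = 150000)
  expect_equal(w2$start, 0)
  w3 <- gene_window(list(chrom = "chr1", start = 49990000L, end = 49995000L),
                    flank = 150000,
                    genome = data.frame(chrom = "chr1", length = 50000000L))
  expect_equal(w3$end, 50000000)
  # zero flank returns the gene body
  w4 <- gene_window(gene, flank = 0)
  expect_equal(c(w4$start, w4$end), c(300000, 310000))
})

test_that("coverage enrichment recovers exact and planted ratios", {
  genes <- sprintf("g%02d", 1:20)
  rest <- data.frame(gene_id = genes, mass = 1000, total = 1e6)
  stim <- rest
  stim$mass <- 2 * rest$mass + 1  # exact 2x after the +1 pseudo-mass
  ce <- coverage_enrichment(stim, rest, genes, eps = 1)
  expect_equal(ce$ratios$log2_ratio, rep(1, 20))
  expect_lt(ce$p, 1e-6)
  # identical conditions: ratios 0, p ~ 1 (or NA when sd is 0)
  ce0 <- coverage_enrichment(rest, rest, genes)
  expect_equal(ce0$ratios$log2_ratio, rep(0, 20))
  # library-size invariance: scaling both totals leaves ratios unchanged
  stim2 <- stim; stim2$total <- stim2$total * 5
  rest2 <- rest; rest2$total <- rest2$total * 5
  expect_equal(coverage_enrichment(stim2, rest2, genes)$ratios$log2_ratio,
               ce$ratios$log2_ratio)
  # planted 2x with noise
  set.seed(601)
  stim3 <- rest
  stim3$mass <- round(2 * rest$mass * 2^rnorm(20, 0, 0.26))
  ce3 <- coverage_enrichment(stim3, rest, genes)
  expect_gt(ce3$mean_log2_ratio, 0.8)
  expect_lt(ce3$mean_log2_ratio, 1.2)
  # tiny sets skip the t-test
  expect_true(is.na(coverage_enrichment(stim, rest, genes[1:2])$p))
})

test_that("PWM scanning matches a brute-force rescan and strand symmetry", {
  set.seed(602)
  pwm <- pwm_from_counts(matrix(rpois(32, 5), 4), name = "m8")
  seqs <- random_sequences(5, 2000)
  brute_hits <- function(seq, pwm, frac) {
    thr <- frac * pwm$max_score
    n <- nchar(seq); L <- pwm$length
    score1 <- function(s) sum(vapply(seq_len(L), function(j) {
      b <- substr(s, j, j)
      if (b %in% rownames(pwm$mat)) pwm$mat[b, j] else 0
    }, 0))
    hits <- 0L
    for (i in seq_len(n - L + 1)) {
      sub <- substr(seq, i, i + L - 1)
      if (score1(sub) >= thr) hits <- hits + 1L
      if (score1(revcomp(sub)) >= thr) hits <- hits + 1L
    }
    hits
  }
  for (s in seqs) {
    got <- nrow(scan_pwm(s, pwm, 0.8))
    expect_identical(got, brute_hits(s, pwm, 0.8))
  }
  # consensus and its reverse complement give one maximal hit each
  h1 <- scan_pwm(pwm$consensus, pwm, 0.99)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$score, pwm$max_score)
  expect_equal(h1$strand, "+")
  h2 <- scan_pwm(revcomp(pwm$consensus), pwm, 0.99)
  expect_equal(nrow(h2), 1)
  expect_equal(h2$strand, "-")
  expect_equal(h2$score, h1$score)
  # ambiguous bases contribute zero bits
  hN <- scan_pwm(gsub("N", "N", paste0("NN", pwm$consensus, "NN")), pwm, 0.99)
  expect_equal(nrow(hN), 1)
})

test_that("fg/bg peak selection gives foreground precedence", {
  genes <- tiny_annotation(c("sens", "nde", "far"))
  genes$start <- c(0L, 1000000L, 3000000L)
  genes$end <- genes$start + 10000L
  peaks <- data.frame(chrom = "chr1",
                      start = c(5000L, 1005000L, 2000000L, 2500000L),
                      end = c(5500L, 1005500L, 2000500L, 2500500L),
                      score = 1, condition = "c",
                      peak_id = paste0("p", 1:4))
  sel <- select_fg_bg_peaks(peaks, "sens", "nde", genes, flank = 150000)
  expect_identical(sel$fg$peak_id, "p1")
  expect_identical(sel$bg$peak_id, "p2")
  # overlapping both windows -> foreground only
  genes2 <- genes
  genes2$start <- c(0L, 4000L, 3000000L)  # nde window now covers p1 too
  genes2$end <- genes2$start + 10000L
  sel2 <- select_fg_bg_peaks(peaks, "sens", "nde", genes2, flank = 150000)
  expect_true("p1" %in% sel2$fg$peak_id)
  expect_false("p1" %in% sel2$bg$peak_id)
  expect_error(select_fg_bg_peaks(peaks, "far2", "nde", genes, flank = 1),
               "no peaks intersect")
})

test_that("motif enrichment detects planted fg/bg rate differences", {
  set.seed(603)
  pwm <- pwm_from_counts(consensus_counts("TGACTCATGC"), name = "planted")
  fg <- data.frame(chrom = "chr1", start = 1:200 * 1000L,
                   end = 1:200 * 1000L + 300L, score = 1, condition = "c",
                   peak_id = sprintf("fg%03d", 1:200))
  bg <- data.frame(chrom = "chr2", start = 1:1000 * 1000L,
                   end = 1:1000 * 1000L + 300L, score = 1, condition = "c",
                   peak_id = sprintf("bg%04d", 1:1000))
  seqs <- random_sequences(1200, 300, names = c(fg$peak_id, bg$peak_id))
  fg_emb <- embed_motif(seqs[1:200], pwm$consensus, 0.5)
  bg_emb <- embed_motif(seqs[201:1200], pwm$consensus, 0.05)
  seqs <- c(fg_emb$seqs, bg_emb$seqs)
  res <- motif_enrichment(fg, bg, seqs, list(planted = pwm))
  expect_lt(res$q[1], 0.01)
  expect_gt(res$fg_rate, res$bg_rate)
  # absent motif: p = 1
  pwm2 <- pwm_from_counts(consensus_counts("ACGTACGTACGTACGTACGT"),
                          name = "absent")
  res2 <- motif_enrichment(fg, bg, seqs, list(absent = pwm2))
  expect_equal(res2$p, 1)
  expect_error(motif_enrichment(fg[0, ], bg, seqs, list(planted = pwm)),
               "non-empty")
})

test_that("null motif enrichment is calibrated when fg and bg match", {
  set.seed(604)
  pwms <- lapply(1:15, function(i) {
    pwm_from_counts(matrix(rpois(24, 4), 4), name = sprintf("m%02d", i))
  })
  names(pwms) <- vapply(pwms, `[[`, "", "name")
  fg <- data.frame(chrom = "chr1", start = 1:100 * 1000L,
                   end = 1:100 * 1000L + 200L, score = 1, condition = "c",
                   peak_id = sprintf("f%03d", 1:100))
  bg <- data.frame(chrom = "chr2", start = 1:400 * 1000L,
                   end = 1:400 * 1000L + 200L, score = 1, condition = "c",
                   peak_id = sprintf("b%03d", 1:400))
  seqs <- random_sequences(500, 250, names = c(fg$peak_id, bg$peak_id))
  res <- motif_enrichment(fg, bg, seqs, pwms)
  expect_gt(min(res$q), 0.05)  # nothing should light up
})

test_that("peak QC statistics compute FRiP and count differences", {
  pk <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 600L),
                   score = c(12, 5), condition = "c", peak_id = c("p1", "p2"))
  reads_in <- data.frame(chrom = "chr1", start = c(110L, 510L, 150L),
                         end = c(160L, 560L, 190L))
  qc <- peak_qc_stats(list(s1 = pk), list(s1 = reads_in))
  expect_equal(qc$per_sample$frip, 1)
  expect_equal(qc$per_sample$frac_signal_gt_10, 0.5)
  # scores (12, 5, 11, 9) -> 0.5
  pk2 <- pk[c(1, 2, 1, 2), ]; pk2$score <- c(12, 5, 11, 9)
  qc2 <- peak_qc_stats(list(s1 = pk2), list(s1 = reads_in))
  expect_equal(qc2$per_sample$frac_signal_gt_10, 0.5)
  # reads outside peaks lower FRiP
  reads_half <- rbind(reads_in,
                      data.frame(chrom = "chr1", start = c(10000L, 20000L,
                                                           30000L),
                                 end = c(10100L, 20100L, 30100L)))
  qc3 <- peak_qc_stats(list(s1 = pk), list(s1 = reads_half))
  expect_equal(qc3$per_sample$frip, 0.5)
  # paired group comparison: counts exactly 1.1x -> relative difference 0.1
  mk <- function(n) data.frame(chrom = "chr1", start = 1:n * 1000L,
                               end = 1:n * 1000L + 100L, score = 1,
                               condition = "c",
                               peak_id = sprintf("q%03d", 1:n))
  qc4 <- peak_qc_stats(list(a1 = mk(110), a2 = mk(220), b1 = mk(100),
                            b2 = mk(200)),
                       list(a1 = reads_in, a2 = reads_in, b1 = reads_in,
                            b2 = reads_in),
                       group_a = c("a1", "a2"), group_b = c("b1", "b2"))
  expect_equal(qc4$relative_diff, c(0.1, 0.1))
  expect_error(peak_qc_stats(list(s1 = pk), list(s1 = reads_in[0, ])),
               "zero reads")
})
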