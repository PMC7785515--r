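test_that("gene filter applies chromosome and support rules", {
  counts <- rbind(g1 = c(19L, 19L, 19L, 19L),
                  g2 = c(20L, 20L, 20L, 0L),
                  g3 = c(1000L, 1000L, 1000L, 1000L),
                  g4 = c(50L, 50L, 50L, 50L))
  colnames(counts) <- paste0("s", 1:4)
  ann <- tiny_annotation(c("g1", "g2", "g3", "g4"))
  ann$chrom[3] <- "chrY"
  kept <- filter_genes(counts, ann)
  expect_identical(rownames(kept), c("g2", "g4"))  # g1 below, g3 on Y
  expect_warning(filter_genes(rbind(counts, gX = c(99L, 99L, 99L, 99L)), ann),
                 "absent from the annotation")
  expect_error(filter_genes(counts[1, , drop = FALSE], ann), "all genes filtered")
})

test_that("size factors follow the median-of-ratios identities", {
  # doubled sample: forced to (1/sqrt(2), sqrt(2)) by the geometric-mean-1
  # constraint
  m <- tiny_counts()
  expect_equal(unname(estimate_size_factors(m)), c(1 / sqrt(2), sqrt(2)))
  # single sample: identity
  expect_equal(unname(estimate_size_factors(m[, 1, drop = FALSE])), 1)
  # 3x2 toy with one zero: that gene drops out of the medians
  m2 <- rbind(g1 = c(10L, 0L), g2 = c(4L, 16L), g3 = c(9L, 36L))
  colnames(m2) <- c("s1", "s2")
  s <- estimate_size_factors(m2)
  # remaining genes have ratios (1/2, 2) around their geomeans
  expect_equal(unname(s), c(1 / 2, 2))
  expect_true(all(is.finite(s)))
  # equivariance: scaling one sample scales its factor
  m3 <- tiny_counts()
  m3[, 2] <- m3[, 2] * 3L
  s3 <- estimate_size_factors(m3)
  s0 <- estimate_size_factors(tiny_counts())
  expect_equal(s3[["s2"]] / s3[["s1"]], 3 * s0[["s2"]] / s0[["s1"]])
  # geometric mean 1 by construction
  expect_lt(abs(mean(log(s3))), 1e-6)
})

test_that("NB GLM matches glm.nb and the Poisson closed form", {
  set.seed(71)
  x <- rep(0:1, each = 15)
  y <- rnbinom(30, size = 5, mu = exp(2 + x))
  X <- cbind(`(Intercept)` = 1, x = x)
  fit <- fit_nb_glm(y, X, alpha = 0.2)
  ref <- MASS::glm.nb(y ~ x, init.theta = 5)
  fit2 <- fit_nb_glm(y, X, alpha = 1 / ref$theta)
  expect_equal(unname(fit2$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_true(fit$converged)
  # intercept-only at alpha -> 0 equals the log weighted mean of y/s
  s <- runif(30, 0.5, 2)
  f0 <- fit_nb_glm(y, matrix(1, 30, 1), s = s, alpha = 1e-10)
  expect_equal(unname(exp(f0$beta)), sum(y) / sum(s), tolerance = 1e-6)
  # identical groups: coefficient ~ 0
  y2 <- rep(c(5L, 9L, 7L), 10)
  f2 <- fit_nb_glm(y2, X, alpha = 0.1)
  expect_lt(abs(f2$beta[2]), 1e-4)
  # rank-deficient design names the aliased column
  Xbad <- cbind(X, x2 = x)
  expect_error(fit_nb_glm(y, Xbad, alpha = 0.1), "x2")
})

test_that("LRT respects nesting, identity and non-negativity", {
  set.seed(72)
  y <- rnbinom(20, size = 10, mu = 50)
  X <- cbind(1, rep(0:1, each = 10))
  Xr <- X[, 1, drop = FALSE]
  lr <- nb_lrt(y, X, Xr, alpha = 0.1)
  expect_gte(lr$stat, 0)
  expect_equal(lr$df, 1)
  # reduced = full: stat 0, p 1
  lr0 <- nb_lrt(y, X, X, alpha = 0.1)
  expect_equal(lr0$stat, 0)
  expect_equal(lr0$p, 1)
  # non-nested designs rejected
  Xother <- cbind(rep(c(0, 1), 10))
  expect_error(nb_lrt(y, X, Xother, alpha = 0.1), "not nested")
  # full-model likelihood >= reduced on the same data
  expect_gte(lr$fit_full$loglik, lr$fit_reduced$loglik)
})

test_that("dispersion estimation recovers the truth and hits bounds", {
  set.seed(73)
  G <- 120; n <- 50
  counts <- t(vapply(seq_len(G), function(g)
    rnbinom(n, size = 10, mu = 200), numeric(n)))
  rownames(counts) <- sprintf("g%03d", seq_len(G))
  disp <- estimate_dispersions(counts, rep(1, n), shrink = FALSE)
  expect_gt(median(disp$alpha_mle), 0.07)
  expect_lt(median(disp$alpha_mle), 0.14)
  # Poisson data pinned at the lower bound
  pois <- t(vapply(1:30, function(g) rpois(n, 100), numeric(n)))
  rownames(pois) <- sprintf("p%02d", 1:30)
  dp <- estimate_dispersions(pois, rep(1, n), shrink = FALSE)
  expect_gt(mean(dp$alpha_mle < 1e-3), 0.5)
  # prior_var -> 0 collapses estimates onto the trend
  d0 <- estimate_dispersions(counts, rep(1, n), prior_var = 1e-8)
  trend <- attr(d0, "trend")
  expected <- trend["a1"] / d0$mean_norm + trend["a0"]
  expect_equal(unname(d0$alpha), unname(pmax(expected, 1e-8)),
               tolerance = 0.02)
  # all-zero gene flagged at the upper bound
  z <- rbind(counts[1:5, ], zz = rep(0L, n))
  dz <- estimate_dispersions(z, rep(1, n), shrink = FALSE)
  expect_true(dz$flag_allzero[dz$gene_id == "zz"])
  expect_equal(dz$alpha[dz$gene_id == "zz"], 10)
})

test_that("variance decomposition matches exact and null expectations", {
  set.seed(74)
  # expression differing only by cell type, zero noise
  x <- matrix(rep(c(1, 1, 5, 5), each = 10), 10, 4, byrow = FALSE)
  x <- x + matrix(rnorm(40, 0, 0), 10, 4)
  x[1, ] <- x[1, ] + c(0, 0.001, 0, 0.001)  # avoid constant-row warning
  ct <- c("a", "a", "b", "b")
  ve <- variance_explained(x[1:2, , drop = FALSE] + rnorm(8, 0, 1e-9), ct)
  expect_gt(ve$mean_r2, 0.99)
  # pure noise: mean R2 ~ (k-1)/(n-1)
  noise <- matrix(rnorm(400 * 8), 400, 8)
  vn <- variance_explained(noise, rep(c("a", "b"), each = 4))
  expect_lt(abs(vn$mean_r2 - 1 / 7), 0.03)
  expect_error(variance_explained(noise, rep("a", 8)), ">= 2 levels")
})

test_that("PCA behaves as an SVD should", {
  set.seed(75)
  x <- matrix(rnorm(50 * 6), 50, 6)
  x[, 4:6] <- x[, 1:3]  # duplicated samples
  colnames(x) <- paste0("s", 1:6)
  pc <- pca_expression(x)
  expect_equal(pc$scores[1, ], pc$scores[4, ], tolerance = 1e-9)
  expect_true(all(diff(pc$var_frac) <= 1e-12))
  expect_lte(sum(pc$var_frac), 1 + 1e-9)
  # planted clusters separate on PC1
  y <- matrix(rnorm(100 * 10, 0, 0.2), 100, 10)
  y[1:50, 6:10] <- y[1:50, 6:10] + 5
  colnames(y) <- paste0("s", 1:10)
  py <- pca_expression(y)
  grp <- rep(1:2, each = 5)
  between <- abs(diff(tapply(py$scores[, 1], grp, mean)))
  within <- mean(tapply(py$scores[, 1], grp, sd))
  expect_gt(between / within, 10)
  expect_error(pca_expression(y[, 1:2]), ">= 3 samples")
})

test_that("Wald test flags planted fold-changes and stays quiet on nulls", {
  p <- simulation_params(
    n_genes = 300, seed = 76,
    class_fractions = c(tcr_linear = 0, cd28_linear = 0.3, tcr_switch = 0,
                        cd28_switch = 0, both = 0, null = 0.7),
    per_increment_log2fc = 1, dispersion_meanlog = log(0.05),
    dispersion_sdlog = 0)
  sim <- simulate_experiment(p)
  counts <- filter_genes(sim$counts, sim$annotation)
  idx <- sim$design$cell_type == "naive"
  des <- sim$design[idx, ]
  counts <- counts[, idx]
  sf <- estimate_size_factors(counts)
  disp <- estimate_dispersions(counts, sf,
                               stimgrid:::design_condition_batch(des))
  de <- wald_de_test(counts, des, sf, disp)
  cls <- sim$truth$class_naive[match(de$gene_id, sim$truth$gene_id)]
  hi <- de$contrast == "highCD28" & cls == "cd28_linear"
  expect_gt(mean(de$upregulated[hi]), 0.8)  # planted 4x at dose 2
  null_up <- de$upregulated[cls == "null"]
  expect_lt(mean(null_up), 0.02)
  # BH q mapping is stable under gene reordering
  perm <- sample(nrow(counts))
  de2 <- wald_de_test(counts[perm, ], des, sf, disp)
  key <- paste(de$gene_id, de$contrast)
  key2 <- paste(de2$gene_id, de2$contrast)
  expect_equal(de2$q[match(key, key2)], de$q)
})

test_that("Wald and LRT p-values agree at large n", {
  set.seed(78)
  n <- 200
  x <- rep(0:1, each = n / 2)
  X <- cbind(`(Intercept)` = 1, x = x)
  Xr <- X[, 1, drop = FALSE]
  lfc <- rnorm(60, 0, 0.3)
  pw <- pl <- numeric(60)
  for (g in 1:60) {
    y <- rnbinom(n, size = 10, mu = exp(4 + lfc[g] * x))
    f <- fit_nb_glm(y, X, alpha = 0.1)
    pw[g] <- 2 * pnorm(abs(f$beta[2] / f$se[2]), lower.tail = FALSE)
    pl[g] <- nb_lrt(y, X, Xr, alpha = 0.1)$p
  }
  expect_gt(cor(rank(pw), rank(pl)), 0.95)
})
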