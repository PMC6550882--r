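# Normalization, PCA, composite loadings and the label-permutation machinery.

test_that("size factors follow the median-of-ratios arithmetic", {
  m <- cbind(s1 = c(5, 9, 13), s2 = c(5, 9, 13))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))

  # two genes, two samples: ratios to geometric means are sqrt(1/2), sqrt(2)
  m <- cbind(s1 = c(2, 4), s2 = c(4, 8))
  expect_equal(unname(round(estimate_size_factors(m), 4)), c(0.7071, 1.4142))

  set.seed(1)
  base <- matrix(rpois(200, 50), 100, 2)
  m <- cbind(base[, 1], base[, 1] * 3)
  sf <- estimate_size_factors(m)
  expect_equal(sf[[2]] / sf[[1]], 3)

  expect_error(estimate_size_factors(matrix(c(0, 1, 1, 0), 2)), "no gene")
})

test_that("variance stabilization is a shifted scaled log", {
  expect_equal(variance_stabilize(matrix(0), 1)[1, 1], 0)
  expect_equal(variance_stabilize(matrix(1), 1)[1, 1], 1)
  m <- matrix(c(3, 17), 1)
  expect_equal(variance_stabilize(m, c(1, 1)),
               variance_stabilize(2 * m, c(2, 2)))
})

test_that("covariance PCA matches a brute-force eigendecomposition", {
  # samples on a line: one PC carries all variance
  line <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8))
  colnames(line) <- paste0("s", 1:4)
  pca <- run_pca(line)
  expect_equal(pca$pve[1], 1)

  set.seed(42)
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  pca <- run_pca(m)
  cov_s <- stats::cov(t(m))                  # gene-space covariance oracle
  ev <- eigen(cov_s, symmetric = TRUE)
  n_pc <- length(pca$pve)
  expect_equal(pca$pve[1:2], (ev$values / sum(ev$values))[1:2], tolerance = 1e-10)
  for (i in 1:2) {                           # loadings match up to sign
    expect_equal(abs(sum(pca$loadings[, i] * ev$vectors[, i])), 1,
                 tolerance = 1e-8)
  }

  perm <- run_pca(m[, c(3, 1, 4, 2)])
  expect_equal(perm$loadings, pca$loadings)

  expect_error(run_pca(matrix(1, 3, 4,
                              dimnames = list(NULL, paste0("s", 1:4)))),
               "constant")
})

test_that("ecotype PCs are found, oriented, and combined into composite loadings", {
  set.seed(7)
  eco <- rep(c("marine", "freshwater"), each = 4)
  base <- matrix(rnorm(800), 100, 8)
  base[1:10, eco == "marine"] <- base[1:10, eco == "marine"] + 3
  rownames(base) <- paste0("g", 1:100); colnames(base) <- paste0("s", 1:8)
  pca <- run_pca(base)
  idx <- identify_ecotype_pcs(pca$scores, eco, 1)
  expect_equal(idx, 1L)
  expect_error(identify_ecotype_pcs(pca$scores, eco, 99), "exceeds")

  # worked example: w = (0.145, 0.063), l = (0.2, -0.1), signs (+, +)
  L <- composite_loadings(matrix(c(0.2, -0.1), 1), c(0.145, 0.063), 1:2,
                          c(1, 1))
  expect_equal(L, 0.0227)
  expect_equal(composite_loadings(matrix(0, 1, 2), c(0.5, 0.5), 1:2), 0)

  # flipping a PC's raw sign is undone by re-derived orientation
  ori <- orient_ecotype_pcs(pca$scores, eco, idx)
  L1 <- composite_loadings(pca$loadings, pca$pve, idx, ori)
  flipped_scores <- pca$scores; flipped_scores[, idx] <- -flipped_scores[, idx]
  flipped_load <- pca$loadings; flipped_load[, idx] <- -flipped_load[, idx]
  ori2 <- orient_ecotype_pcs(flipped_scores, eco, idx)
  L2 <- composite_loadings(flipped_load, pca$pve, idx, ori2)
  expect_equal(L1, L2)
})

test_that("projection reproduces core scores and centers the mean profile", {
  set.seed(8)
  m <- matrix(rnorm(300), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  pca <- run_pca(m)
  proj <- project_samples(m[, 3, drop = FALSE], pca)
  expect_equal(unname(proj[1, ]), unname(pca$scores[3, ]))
  mean_prof <- matrix(pca$center, ncol = 1,
                      dimnames = list(rownames(m), "avg"))
  expect_equal(max(abs(project_samples(mean_prof, pca))), 0, tolerance = 1e-10)
  dup <- m[, c(5, 5)]
  colnames(dup) <- c("a", "b")
  pr <- project_samples(dup, pca)
  expect_equal(pr[1, ], pr[2, ])
})

test_that("outlier selection takes both 1% tails deterministically", {
  L <- stats::setNames(seq_len(1000) / 1000, sprintf("t%04d", 1:1000))
  out <- select_parallel_loci(L, 0.01)
  expect_length(out, 20)
  expect_setequal(out, c(sprintf("t%04d", 1:10), sprintf("t%04d", 991:1000)))
  expect_length(select_parallel_loci(L, 0.5), 1000)
  expect_warning(sel <- select_parallel_loci(stats::setNames(rep(1, 10),
                                                             letters[1:10])),
                 "degenerate")
  expect_length(sel, 0)
})

test_that("balanced label splits are counted and enumerated without duplicates", {
  expect_equal(n_label_splits(16, 8), 6435)
  expect_equal(n_label_splits(16, 8), choose(16, 8) / 2)
  expect_equal(n_label_splits(10, 4), choose(10, 4))
  sp <- enumerate_splits(8, 4)
  expect_equal(nrow(sp), n_label_splits(8, 4))
  expect_false(anyDuplicated(apply(sp, 1, paste, collapse = "")) > 0)
  expect_true(all(rowSums(sp) == 4))
})

test_that("permutation p-values separate planted structure from noise", {
  cfg <- sim_config(n_genes = 400, seed = 17, samples_per_group = 4,
                    parallel_frac = 0.02, parallel_effect = 3, noise_sd = 0.5)
  pe <- simulate_population_expression(cfg)
  cp <- composite_pc(pe$counts, pe$samples)
  planted <- pe$truth$transcript_id[pe$truth$parallel]
  null_ids <- setdiff(pe$truth$transcript_id, planted)[1:8]
  fdr <- permutation_fdr(cp$vst, pe$samples, c(planted, null_ids), cp$pca,
                         cp$pc_indices, max_perms = 800, seed = 1)
  p_planted <- fdr$p[fdr$transcript_id %in% planted]
  p_null <- fdr$p[fdr$transcript_id %in% null_ids]
  expect_lt(median(p_planted), 0.05)
  expect_lt(mean(p_planted), mean(p_null))
  expect_gt(mean(p_null), 0.15)
  # observed loading reproduced through the rank-2 update path
  expect_equal(fdr$L, unname(cp$L[fdr$transcript_id]), tolerance = 1e-12)

  # a constant gene has a degenerate (zero-spread) null: flagged, p = 1
  vst2 <- cp$vst
  vst2["TCONS_00001", ] <- 5
  pca2 <- run_pca(vst2, cp$pca$core_samples)
  fdr2 <- permutation_fdr(vst2, pe$samples, "TCONS_00001", pca2,
                          cp$pc_indices, max_perms = 50, seed = 2)
  expect_true(fdr2$degenerate)
  expect_equal(fdr2$p, 1)
})
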