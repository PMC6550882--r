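# FST/Pi estimators against independent oracles, CSS windows, TSS profiles
# and the proximity randomization.

test_that("Weir-Cockerham FST agrees with the variance-components oracle on all 3+3 configurations", {
  genos <- expand.grid(a = 0:2, b = 0:2, c = 0:2)
  worst <- 0
  for (i in seq_len(nrow(genos))) {
    for (j in seq_len(nrow(genos))) {
      g1 <- as.integer(genos[i, ]); g2 <- as.integer(genos[j, ])
      ours <- fst_weir_cockerham(matrix(c(g1, g2), 1), rep(c("m", "f"), each = 3),
                                 clamp = FALSE)
      oracle <- wc_fst_oracle(g1, g2)
      if (is.na(oracle)) {
        expect_true(is.na(ours))
      } else {
        worst <- max(worst, abs(ours - oracle))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("FST hits the boundary cases and respects the missing cap", {
  eco <- rep(c("m", "f"), each = 6)
  fixed <- matrix(rep(c(0L, 2L), each = 6), 1)
  expect_equal(fst_weir_cockerham(fixed, eco), 1)

  same <- matrix(rep(c(0L, 1L, 2L, 1L, 0L, 2L), 2), 1)   # identical pops
  expect_equal(fst_weir_cockerham(same, eco), 0)          # clamped at zero

  mono <- matrix(rep(0L, 12), 1)
  expect_true(is.na(fst_weir_cockerham(mono, eco)))

  with_missing <- matrix(c(0L, 0L, NA, NA, NA, 0L, 2L, 2L, NA, NA, 2L, 2L), 1)
  expect_true(is.na(fst_weir_cockerham(with_missing, eco, max_missing = 4)))
  expect_equal(fst_weir_cockerham(with_missing, eco, max_missing = 5), 1)
})

test_that("per-site Pi equals pairwise enumeration for all configurations up to n = 8 alleles", {
  for (n_ind in 1:4) {
    cfgs <- as.matrix(expand.grid(rep(list(0:2), n_ind)))
    for (r in seq_len(nrow(cfgs))) {
      g <- cfgs[r, , drop = TRUE]
      alleles <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
      ours <- pi_per_site(matrix(g, 1), max_missing = n_ind)
      expect_equal(unname(ours), unname(pi_oracle(alleles)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(pi_per_site(matrix(c(1L, 1L), 1)), 2 / 3)  # n=4, j=2
  expect_equal(pi_per_site(matrix(c(0L, 0L, 0L), 1)), 0)
  expect_equal(pi_per_site(matrix(1L, 1, 1)), 1)          # n=2, j=1
  expect_true(is.na(pi_per_site(matrix(c(1L, NA, NA, NA), 1),
                                max_missing = 2)))
})

test_that("CSS contrasts between- and within-ecotype distances after MDS", {
  # perfect separation: within-ecotype distance 0, between d > 0
  D <- matrix(0.4, 8, 8); diag(D) <- 0
  D[1:4, 1:4] <- 0; D[5:8, 5:8] <- 0
  css <- css_from_distances(D, rep(c(TRUE, FALSE), each = 4))
  expect_equal(unname(css["raw"]), 0.4, tolerance = 1e-6)
  expect_equal(unname(css["raw"]), unname(css["norm"]))

  # oracle: direct double-centering eigendecomposition for a 4x4 toy matrix
  D4 <- matrix(c(0, 1, 2, 3,
                 1, 0, 2.5, 2,
                 2, 2.5, 0, 1.5,
                 3, 2, 1.5, 0), 4, 4)
  B <- -0.5 * (diag(4) - 1 / 4) %*% (D4^2) %*% (diag(4) - 1 / 4)
  ev <- eigen(B, symmetric = TRUE)
  pts <- ev$vectors[, 1:2] %*% diag(sqrt(pmax(ev$values[1:2], 0)))
  E <- as.matrix(dist(pts))
  in1 <- c(TRUE, TRUE, FALSE, FALSE)
  raw_oracle <- mean(E[1:2, 3:4]) - (E[1, 2] + E[3, 4]) / 2
  expect_equal(unname(css_from_distances(D4, in1)["raw"]), raw_oracle,
               tolerance = 1e-8)

  # planted fixed difference yields the top window
  gt <- simulate_genotypes(sim_config(seed = 77, n_sites = 1000, n_tss = 4,
                                      chrom_length = 2e5, sweep_tss_frac = 0.5,
                                      sweep_width = 1e4, missing_rate = 0))
  cw <- css_windows(gt$geno, gt$sites, gt$samples$ecotype, window = 2e4,
                    top_frac = 0.1)
  sweep_tss <- gt$transcripts$tss[gt$truth$sweep]
  top <- cw[which.max(cw$css_raw), ]
  expect_true(any(sweep_tss >= top$start & sweep_tss <= top$end))
})

test_that("TSS profiles are flat for constant statistics and strand-oriented", {
  tr <- data.frame(transcript_id = c("t1", "t2"), locus_id = c("t1", "t2"),
                   chrom = "chr1", strand = c("+", "+"),
                   start = c(50000L, 50000L), end = c(50999L, 50999L),
                   tss = c(50000L, 50000L), stringsAsFactors = FALSE)
  st <- data.frame(chrom = "chr1", pos = seq(30000L, 70000L, by = 250L),
                   fst = 0.25, stringsAsFactors = FALSE)
  grp <- c(t1 = "g", t2 = "g")
  prof <- tss_profiles(st, tr, grp, stat_cols = "fst", span = 2e4,
                       window = 1e3)
  expect_true(all(prof$mean == 0.25))
  expect_true(all(prof$sem == 0))          # duplicated loci: zero spread

  # minus strand flips the profile around the TSS
  st$fst <- ifelse(st$pos > 50000, 0.9, 0.1)
  tr_minus <- tr[1, ]; tr_minus$strand <- "-"; tr_minus$tss <- 50999L
  p_plus <- tss_profiles(st, tr[1, ], c(t1 = "g"), stat_cols = "fst",
                         span = 2e4, window = 1e3)
  p_minus <- tss_profiles(st, tr_minus, c(t1 = "g"), stat_cols = "fst",
                          span = 2e4, window = 1e3)
  expect_gt(mean(p_plus$mean[p_plus$offset > 2000]), 0.8)
  expect_lt(mean(p_minus$mean[p_minus$offset > 2000]), 0.2)
})

test_that("transcripts placed in outlier windows exceed the proximity null at zero distance", {
  gt <- simulate_genotypes(sim_config(seed = 78, n_sites = 500, n_tss = 30,
                                      chrom_length = 3e6, sweep_tss_frac = 0.2,
                                      missing_rate = 0))
  win <- data.frame(chrom = "chrSim",
                    start = gt$transcripts$start[gt$truth$sweep] - 100,
                    end = gt$transcripts$end[gt$truth$sweep] + 100)
  focal <- gt$transcripts$transcript_id[gt$truth$sweep]
  pr <- proximity_randomization(gt$transcripts, win, focal,
                                n_random = 200, seed = 3)
  expect_equal(pr$observed[1], 1)                       # all overlap: d = 0
  expect_gt(pr$observed[1], pr$null_hi[1])
  expect_error(proximity_randomization(gt$transcripts, win[0, ], focal),
               "no outlier windows")

  # a random focal set stays inside the 95% band most of the time
  set.seed(9)
  inside <- replicate(20, {
    f <- sample(gt$transcripts$transcript_id, 6)
    p <- proximity_randomization(gt$transcripts, win, f, n_random = 100)
    all(p$observed >= p$null_lo & p$observed <= p$null_hi)
  })
  expect_gt(mean(inside), 0.7)
})
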