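# Synthetic-data generators: planted-truth identities, determinism, and
# configuration validation.

test_that("config validation rejects impossible study designs", {
  expect_error(sim_config(class_props = c(cis = 0.5)), "sum to 1")
  expect_error(sim_config(mapping_bias = 0.4), "mapping_bias")
  expect_error(sim_config(depth_snp = 0), "depth")
  expect_error(sim_config(samples_per_group = 1), "samples per ecotype")
  expect_error(sim_config(sweep_width = 1e7, chrom_length = 1e6), "sweep width")
  expect_error(sim_config(salinities = 3.5), "salinity")
})

test_that("null architecture gives balanced allelic fractions; pure cis gives 2:1", {
  cfg <- sim_config(n_genes = 300, seed = 1, class_props = c(conserved = 1),
                    mapping_bias = 0.5, depth_snp = 200)
  cr <- simulate_cross(cfg)
  f1 <- cr$allele_counts[grepl("^F1", cr$allele_counts$sample), ]
  frac <- sum(f1$refCount) / sum(f1$refCount + f1$altCount)
  expect_lt(abs(frac - 0.5), 0.005)

  # pure cis, c = 1: F1 allelic ratio and parental ratio both 2:1 in expectation
  cfg <- sim_config(n_genes = 200, seed = 2, class_props = c(cis = 1),
                    cis_effect = 1, depth_snp = 1e4, lib_size_sd = 0)
  cr <- simulate_cross(cfg)
  s <- sign(cr$truth$cis_effect)[match(cr$snp_truth$transcript_id,
                                       cr$truth$transcript_id)]
  ac <- cr$allele_counts
  for (who in c("F1_1", "marine_parent")) {
    d <- ac[ac$sample == who, ]
    mref <- cr$snp_truth$marine_is_ref
    M <- ifelse(mref, d$refCount, d$altCount)
    Fc <- ifelse(mref, d$altCount, d$refCount)
    if (who == "marine_parent") {
      # parent expresses marine allele only; compare against freshwater parent
      df <- ac[ac$sample == "fresh_parent", ]
      Fc <- ifelse(mref, df$altCount, df$refCount)
    }
    ratio <- sum(M[s > 0]) / sum(Fc[s > 0])
    expect_lt(abs(log2(ratio) - 1), 0.05)
  }
})

test_that("pure trans divergence appears in parents but not in F1 allelic ratios", {
  cfg <- sim_config(n_genes = 400, seed = 3, class_props = c(trans = 1),
                    trans_effect = 1, depth_snp = 1e4, lib_size_sd = 0)
  cr <- simulate_cross(cfg)
  s <- sign(cr$truth$trans_effect)[match(cr$snp_truth$transcript_id,
                                         cr$truth$transcript_id)]
  ac <- cr$allele_counts
  mref <- cr$snp_truth$marine_is_ref
  f1 <- ac[ac$sample == "F1_1", ]
  M <- ifelse(mref, f1$refCount, f1$altCount)
  Fc <- ifelse(mref, f1$altCount, f1$refCount)
  f1_log2 <- mean(log2((M[s > 0] + 0.5) / (Fc[s > 0] + 0.5)))
  expect_lt(abs(f1_log2), 0.05)

  pm <- ac[ac$sample == "marine_parent", ]
  pf <- ac[ac$sample == "fresh_parent", ]
  tot_m <- pm$refCount + pm$altCount
  tot_f <- pf$refCount + pf$altCount
  par_log2 <- log2(sum(tot_m[s > 0]) / sum(tot_f[s > 0]))
  expect_lt(abs(par_log2 - 1), 0.05)
})

test_that("round-trip: parental ratio converges to c+t and F1 ratio to c at high depth", {
  cfg <- sim_config(n_genes = 60, seed = 4, depth_snp = 1e6, lib_size_sd = 0,
                    class_props = c("cis+trans" = 0.5, "cis-trans" = 0.5))
  cr <- simulate_cross(cfg)
  ac <- cr$allele_counts
  mref <- cr$snp_truth$marine_is_ref
  gidx <- match(cr$snp_truth$transcript_id, cr$truth$transcript_id)
  f1 <- ac[ac$sample == "F1_2", ]
  M <- ifelse(mref, f1$refCount, f1$altCount)
  Fc <- ifelse(mref, f1$altCount, f1$refCount)
  r_f1 <- tapply(log2(M / Fc), gidx, mean)
  expect_lt(max(abs(r_f1 - cr$truth$cis_effect)), 1e-2)

  pm <- ac[ac$sample == "marine_parent", ]
  pf <- ac[ac$sample == "fresh_parent", ]
  r_p <- tapply(log2((pm$refCount + pm$altCount) / (pf$refCount + pf$altCount)),
                gidx, mean)
  expect_lt(max(abs(r_p - (cr$truth$cis_effect + cr$truth$trans_effect))), 1e-2)
})

test_that("generators are deterministic given seed and hit the configured depth", {
  cfg <- sim_config(n_genes = 1000, seed = 99)
  a <- simulate_cross(cfg)
  b <- simulate_cross(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$allele_counts, b$allele_counts)
  expect_lt(abs(mean(a$counts) / cfg$depth_gene - 1), 0.05)

  pe1 <- simulate_population_expression(sim_config(n_genes = 300, seed = 7))
  pe2 <- simulate_population_expression(sim_config(n_genes = 300, seed = 7))
  expect_identical(pe1$counts, pe2$counts)
  expect_equal(sum(pe1$truth$parallel), round(0.01 * 300))
})

test_that("planted sweeps fix alternate alleles and erase diversity at the TSS", {
  cfg <- sim_config(seed = 5, n_sites = 2000, n_tss = 10, chrom_length = 1e6,
                    sweep_tss_frac = 0.5, sweep_intensity = 1,
                    missing_rate = 0)
  gt <- simulate_genotypes(cfg)
  sweep_tss <- gt$transcripts$tss[gt$truth$sweep]
  at_tss <- vapply(gt$sites$pos,
                   function(p) any(abs(p - sweep_tss) < 500), TRUE)
  eco <- gt$samples$ecotype
  fst <- fst_weir_cockerham(gt$geno, eco)
  expect_true(all(fst[at_tss] == 1))
  pi_f <- pi_per_site(gt$geno[, eco == "freshwater", drop = FALSE])
  expect_true(all(pi_f[at_tss] == 0))

  # zero intensity: no systematic FST difference near vs far from sweep TSSs
  cfg0 <- sim_config(seed = 6, n_sites = 4000, n_tss = 10, chrom_length = 1e6,
                     sweep_tss_frac = 0.5, sweep_intensity = 0,
                     missing_rate = 0)
  gt0 <- simulate_genotypes(cfg0)
  sweep_tss0 <- gt0$transcripts$tss[gt0$truth$sweep]
  near <- vapply(gt0$sites$pos,
                 function(p) any(abs(p - sweep_tss0) < cfg0$sweep_width), TRUE)
  fst0 <- fst_weir_cockerham(gt0$geno, gt0$samples$ecotype)
  expect_lt(abs(mean(fst0[near], na.rm = TRUE) -
                  mean(fst0[!near], na.rm = TRUE)), 0.02)
})

test_that("salinity F1s keep allelic ratios stable while expression shifts", {
  cfg <- sim_config(n_genes = 150, seed = 8, class_props = c(cis = 1),
                    cis_effect = 1, depth_snp = 2000, plastic_frac = 1,
                    plasticity_shift = 1, lib_size_sd = 0)
  sal <- simulate_salinity_f1s(cfg)
  ac <- sal$allele_counts
  mref <- sal$snp_truth$marine_is_ref
  s <- sign(sal$truth$cis_effect)[match(sal$snp_truth$transcript_id,
                                        sal$truth$transcript_id)]
  for (grp in unique(sal$samples$salinity)) {
    ids <- sal$samples$sample_id[sal$samples$salinity == grp]
    d <- ac[ac$sample %in% ids, ]
    mref_rep <- rep(mref, length(ids))
    s_rep <- rep(s, length(ids))
    M <- ifelse(mref_rep, d$refCount, d$altCount)
    Fc <- ifelse(mref_rep, d$altCount, d$refCount)
    ratio <- sum(M[s_rep > 0]) / sum(Fc[s_rep > 0])
    expect_lt(abs(log2(ratio) - 1), 0.05)   # 2:1 in every salinity
  }
  # expression moves in opposite directions at the salinity extremes
  lo <- sal$samples$sample_id[sal$samples$salinity == min(cfg$salinities)]
  hi <- sal$samples$sample_id[sal$samples$salinity == max(cfg$salinities)]
  dir_pos <- sal$truth$transcript_id[sal$truth$plastic_dir > 0]
  lfc <- log2(rowMeans(sal$counts[dir_pos, lo]) /
                rowMeans(sal$counts[dir_pos, hi]))
  expect_gt(mean(lfc), 1.5)                 # planted total swing is 2 log2 units
})
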