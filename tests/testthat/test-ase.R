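# Exact tests, SNP filters, decision table and aggregation for the ASE
# classifier.

test_that("two-sided binomial p matches pmf summation and R's exact test", {
  expect_equal(binomial_two_sided(5, 10, 0.5), 1)
  expect_equal(binomial_two_sided(10, 10, 0.5), 0.001953125)  # 2 * (1/2)^10
  expect_equal(binomial_two_sided(0, 10, 0.5),
               binomial_two_sided(10, 10, 0.5))
  expect_true(is.na(binomial_two_sided(0, 0, 0.5)))

  for (p0 in c(0.3, 0.5, 0.52)) {
    for (n in c(1:10, 17, 25)) {
      k <- 0:n
      ours <- binomial_two_sided(k, n, p0)
      oracle <- vapply(k, function(kk) binom.test(kk, n, p0)$p.value, 0)
      expect_equal(ours, oracle, tolerance = 1e-12,
                   info = sprintf("n=%d p0=%g", n, p0))
    }
  }
})

test_that("Fisher ratio test equals hypergeometric enumeration", {
  expect_equal(fisher_ratio_test(10, 10, 10, 10), 1)
  expect_equal(fisher_ratio_test(20, 0, 0, 20), 2 / choose(40, 20))
  expect_equal(fisher_ratio_test(5, 5, 50, 50), 1)

  set.seed(3)
  for (i in 1:200) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    cc <- sample(0:12, 1); d <- sample(0:12, 1)
    if (a + b + cc + d == 0) next
    oracle <- fisher.test(matrix(c(a, cc, b, d), 2))$p.value
    expect_equal(fisher_ratio_test(a, b, cc, d), oracle, tolerance = 1e-9,
                 info = sprintf("table %d %d %d %d", a, b, cc, d))
  }
})

test_that("informative SNPs need opposite-homozygous parents at DNA depth >= 10", {
  tr <- data.frame(transcript_id = "t1", locus_id = "t1", chrom = "chr1",
                   strand = "+", start = 100L, end = 200L, tss = 100L,
                   stringsAsFactors = FALSE)
  pc <- data.frame(
    chrom = "chr1", pos = c(110L, 120L, 130L, 140L, 999L),
    refAllele = "A", altAllele = "T",
    gt_marine = c("0/0", "0/0", "0/1", "0/0", "0/0"),
    gt_fresh = c("1/1", "1/1", "1/1", "1/1", "1/1"),
    dp_marine = c(12L, 8L, 15L, 15L, 30L),
    dp_fresh = c(15L, 15L, 15L, 15L, 30L),
    stringsAsFactors = FALSE)
  out <- select_informative_snps(pc, tr)
  # kept: deep hom-opposite inside the transcript; dropped: low depth (8x),
  # heterozygous parent, and the SNP outside any transcript
  expect_equal(out$pos, c(110L, 140L))
  expect_true(all(out$marine_is_ref))
})

test_that("coverage filter is strict and monoallelic exclusion follows the threshold", {
  total <- rbind(c(11, 2), c(10, 10), c(500, 3))
  colnames(total) <- c("F1_1", "F1_2")
  expect_equal(unname(filter_expression_coverage(total, c("F1_1", "F1_2"))),
               c(TRUE, FALSE, TRUE))

  # columns: F1, marine parent (expresses ref), freshwater parent (alt)
  ref <- rbind(c(40, 100, 0), c(40, 100, 0), c(10, 100, 0))
  alt <- rbind(c(0, 0, 100), c(1, 0, 100), c(9, 10, 100))
  colnames(ref) <- colnames(alt) <- c("F1_1", "marine_parent", "fresh_parent")
  keep <- exclude_monoallelic(ref, alt, "F1_1",
                              marine_is_ref = c(TRUE, TRUE, TRUE),
                              marine_id = "marine_parent",
                              fresh_id = "fresh_parent")
  # row 1: F1 40/0 at >= 20 reads -> dropped; row 2: 40/1 kept;
  # row 3: marine parent expressing freshwater allele -> dropped
  expect_equal(unname(keep), c(FALSE, TRUE, FALSE))
})

test_that("the bias null is the F1-wide reference read fraction", {
  ref <- matrix(c(520, 100), 2, 1, dimnames = list(NULL, "F1_1"))
  alt <- matrix(c(480, 100), 2, 1, dimnames = list(NULL, "F1_1"))
  expect_equal(estimate_null_ratio(ref, alt, "F1_1"), 620 / 1200)
  ref2 <- matrix(500, 1, 1, dimnames = list(NULL, "F1_1"))
  expect_equal(estimate_null_ratio(ref2, ref2, "F1_1"), 0.5)
})

test_that("simulated mapping bias is recovered by the null-ratio estimator", {
  cfg <- sim_config(n_genes = 400, seed = 31, class_props = c(conserved = 1),
                    mapping_bias = 0.52, depth_snp = 100)
  cr <- simulate_cross(cfg)
  res <- ase_classify(cr$allele_counts, cr$parent_calls, cr$transcripts,
                      cr$samples)
  # each F1 carries >= 1e5 reads here; estimate must recover b within 0.005
  expect_true(all(abs(res$p0 - 0.52) < 0.005))
})

test_that("parent test folds size factors into the null", {
  r <- parent_expression_test(20, 20)
  expect_equal(r$p_parent, 1)
  expect_equal(r$R_P, 0)
  r <- parent_expression_test(20, 0)
  expect_equal(r$p_parent, 2 * 0.5^20)
  r <- parent_expression_test(20, 20, sf_M = 2, sf_F = 1)
  expect_lt(abs(r$R_P - (-1)), 0.05)
  expect_lt(r$p_parent, 0.05)   # equal counts are unexpected at 2:1 null
})

test_that("the decision table maps flags and signs to the seven classes", {
  expect_equal(classify_regulatory(TRUE, TRUE, FALSE, 1, 1), "cis")
  expect_equal(classify_regulatory(TRUE, FALSE, TRUE, 0, 1), "trans")
  expect_equal(classify_regulatory(TRUE, TRUE, TRUE, 1, 2), "cis+trans")
  expect_equal(classify_regulatory(TRUE, TRUE, TRUE, 2, 1), "cis-trans")
  expect_equal(classify_regulatory(FALSE, TRUE, TRUE, 1, 0), "compensatory")
  expect_equal(classify_regulatory(FALSE, FALSE, FALSE, 0, 0), "conserved")
  expect_equal(classify_regulatory(TRUE, FALSE, FALSE, 0, 1), "ambiguous")
  expect_equal(classify_regulatory(FALSE, TRUE, FALSE, 1, 0), "ambiguous")
})

test_that("BH flags behave across a family", {
  expect_false(any(bh_flags(rep(1, 10))))
  p <- c(0.001, rep(1, 10))
  flags <- bh_flags(p, 0.10)
  expect_true(flags[1] && !any(flags[-1]))
  expect_length(bh_flags(numeric(0)), 0)
})

test_that("aggregation picks the lowest p-product SNP with coordinate ties", {
  res <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2", "t3"),
    f1 = "F1_1",
    pos = c(10L, 20L, 10L, 5L, 42L),
    p_parent = c(0.1, 0.2, 0.5, 0.5, 0.9),
    p_ase = c(0.01, 0.1, 0.4, 0.4, 0.9),
    p_fisher = c(1, 1, 1, 1, 0.8),
    stringsAsFactors = FALSE)
  agg <- aggregate_to_transcript(res)
  expect_equal(agg$pos[agg$transcript_id == "t1"], 10L)   # smaller product
  expect_equal(agg$pos[agg$transcript_id == "t2"], 5L)    # tie: lower coord
  expect_equal(agg$pos[agg$transcript_id == "t3"], 42L)   # single SNP
})

test_that("SNPs on the same exon agree with themselves", {
  res <- data.frame(
    transcript_id = "t1", exon_id = "t1:e1",
    pos = rep(c(10L, 20L), each = 2),
    f1 = rep(c("F1_1", "F1_2"), 2),
    R_F1 = c(1.0, 1.2, 1.0, 1.2),     # identical counts at both SNPs
    class = rep("cis", 4),
    stringsAsFactors = FALSE)
  cc <- snp_concordance(res, "exon_id")
  expect_equal(cc$mean_correlation, 1)
  expect_equal(cc$class_agreement, 1)
  # singleton groups are skipped
  res1 <- res[res$pos == 10L, ]
  expect_null(snp_concordance(res1, "exon_id"))
})

test_that("excluded (sex-biased) transcripts never appear in calls", {
  cr <- tiny_cross(n_genes = 60)
  drop_ids <- cr$truth$transcript_id[1:10]
  res <- ase_classify(cr$allele_counts, cr$parent_calls, cr$transcripts,
                      cr$samples, exclude_transcripts = drop_ids)
  expect_false(any(res$calls$transcript_id %in% drop_ids))
  expect_false(any(res$snp_results$transcript_id %in% drop_ids))
})

test_that("cis + trans magnitudes recompose the parental ratio exactly", {
  cr <- tiny_cross(n_genes = 80)
  res <- ase_classify(cr$allele_counts, cr$parent_calls, cr$transcripts,
                      cr$samples)
  expect_equal(res$calls$cis_mag + res$calls$trans_mag, res$calls$R_P,
               tolerance = 1e-15)
})
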