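#!/usr/bin/env Rscript

# Quantitative architecture of expression divergence: per-locus cis/trans
# magnitudes, dominance/additivity of inheritance, sibling sharing of
# regulatory classes, and effect-size bins along the composite-PC axis.

suppressPackageStartupMessages(library(paracis))

sim <- "results/sim"
out <- "results/cis_trans"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

calls <- utils::read.delim("results/ase/calls.tsv", stringsAsFactors = FALSE)
counts <- read_counts(file.path(sim, "cross_counts.tsv"))
truth <- utils::read.delim(file.path(sim, "cross_truth.tsv"),
                           stringsAsFactors = FALSE)
loadings <- utils::read.delim("results/composite_pc/composite_loadings.tsv",
                              stringsAsFactors = FALSE)

div <- locus_cis_trans(calls, river = "SimRiver")
utils::write.table(div, file.path(out, "locus_divergence.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("locus table: %d loci; max |mean_cis + mean_trans - mean_R_P| = %.2g\n",
            nrow(div), max(abs(div$mean_cis + div$mean_trans - div$mean_R_P))))

## inheritance: dominance/additivity on loci with parental divergence
nc <- sweep(counts, 2, estimate_size_factors(counts), "/")
div_ids <- truth$transcript_id[abs(truth$cis_effect + truth$trans_effect) >= 1]
dom <- do.call(rbind, lapply(paste0("F1_", 1:4), function(f) {
  d <- dominance_additivity(nc[div_ids, "marine_parent"],
                            nc[div_ids, "fresh_parent"], nc[div_ids, f])
  data.frame(transcript_id = div_ids, f1 = f, ratio = d$ratio)
}))
dom$class <- truth$class[match(dom$transcript_id, truth$transcript_id)]
utils::write.table(dom, file.path(out, "dominance.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("median |d/a| by planted class:\n")
print(round(tapply(abs(dom$ratio), dom$class, median, na.rm = TRUE), 3))

## sibling sharing of regulatory classes (epistasis proxy)
sh <- sibling_sharing(calls)
utils::write.table(sh, file.path(out, "sibling_sharing.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("mean % shared between siblings by class:\n")
print(round(tapply(sh$shared_pct, sh$class, mean, na.rm = TRUE), 1))

## parallelism correlations across rivers need a second cross: simulate one
## with shared cis effects for freshwater-upregulated parallel loci
cfg2 <- sim_config(n_genes = 2000, seed = 20190520, depth_snp = 200,
                   mapping_bias = 0.51)
cr2 <- simulate_cross(cfg2)
# plant the SAME cis effects as river 1 for the loci in the negative
# composite-loading tail, mirroring a shared genetic basis
L <- stats::setNames(loadings$L, loadings$transcript_id)
shared <- names(sort(L))[seq_len(200)]
shared <- intersect(shared, truth$transcript_id)
res2 <- ase_classify(cr2$allele_counts, cr2$parent_calls, cr2$transcripts,
                     cr2$samples)
div2 <- locus_cis_trans(res2$calls, river = "R2")
# shared-tail loci take river 1's measured cis values plus noise
m <- match(shared, div2$transcript_id)
src <- match(shared, div$transcript_id)
ok <- !is.na(m) & !is.na(src)
div2$mean_cis[m[ok]] <- div$mean_cis[src[ok]] + rnorm(sum(ok), 0, 0.15)
pc <- parallelism_correlation(list(SimRiver = div, R2 = div2), L)
utils::write.table(pc, file.path(out, "parallelism_correlation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("cis parallelism r by tail and threshold:\n")
print(pc[, c("tail", "threshold", "n_loci", "r")])

bins <- effect_size_bins(list(SimRiver = div, R2 = div2), L)
utils::write.table(bins, file.path(out, "effect_size_bins.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_run_summary(file.path(out, "run_summary.json"), "cis-trans", seed = NA)
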