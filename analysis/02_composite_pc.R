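#!/usr/bin/env Rscript

# Composite-PC analysis of parallel marine-freshwater expression divergence:
# size factors, variance stabilization, covariance PCA on the balanced core
# set, ecotype-separating PCs, composite loadings, 1% outliers, and the
# label-permutation FDR for the outlier set. Recovery is reported against
# the planted truth.

suppressPackageStartupMessages(library(paracis))

sim <- "results/sim"
out <- "results/composite_pc"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20190516

counts <- read_counts(file.path(sim, "pop_counts.tsv"))
samples <- utils::read.delim(file.path(sim, "pop_samples.tsv"),
                             stringsAsFactors = FALSE)
truth <- utils::read.delim(file.path(sim, "pop_truth.tsv"),
                           stringsAsFactors = FALSE)

cp <- composite_pc(counts, samples, k = 2, quantile = 0.01, fdr = TRUE,
                   max_perms = 2000, seed = seed)
cat("ecotype-separating PCs:", cp$pc_indices,
    sprintf("(%.1f%% and %.1f%% PVE)\n",
            100 * cp$pca$pve[cp$pc_indices[1]],
            100 * cp$pca$pve[cp$pc_indices[2]]))

auc <- rank_auc(abs(cp$L), truth$parallel)
hits <- sum(cp$outliers %in% truth$transcript_id[truth$parallel])
cat(sprintf("AUC for ranking planted parallel loci by |L|: %.3f\n", auc))
cat(sprintf("outliers: %d; planted among them: %d of %d\n",
            length(cp$outliers), hits, sum(truth$parallel)))
cat(sprintf("median FDR (q) over outliers: %.3f\n", median(cp$fdr$q)))

loadings <- data.frame(transcript_id = names(cp$L), L = unname(cp$L),
                       outlier = names(cp$L) %in% cp$outliers)
utils::write.table(loadings, file.path(out, "composite_loadings.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cp$fdr, file.path(out, "outlier_fdr.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
scores <- data.frame(sample_id = rownames(cp$pca$scores),
                     cp$pca$scores[, 1:5])
utils::write.table(scores, file.path(out, "core_scores.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
write_run_summary(file.path(out, "run_summary.json"), "composite-pc",
                  seed = seed, auc = auc, n_outliers = length(cp$outliers),
                  median_q = median(cp$fdr$q))
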