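#!/usr/bin/env Rscript

# Are parallel diverged loci enriched for particular regulatory classes?
# Randomization test against 1000 equal-size draws from the background set of
# ecotype-divergent testable loci, plus the hypergeometric overlap of the
# parallel set with an independent locus set.

suppressPackageStartupMessages(library(paracis))

out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20190517

calls <- utils::read.delim("results/ase/calls.tsv", stringsAsFactors = FALSE)
loadings <- utils::read.delim("results/composite_pc/composite_loadings.tsv",
                              stringsAsFactors = FALSE)

# the cross and the population matrix are simulated independently, so map
# parallel/background status onto the cross's testable loci by rank: the
# parallel set are the strongest |L| among testable loci, the background the
# 10% tails (the "expression divergence between ecotypes" set)
testable <- sort(unique(calls$transcript_id))
L <- stats::setNames(loadings$L, loadings$transcript_id)[testable]
L <- L[!is.na(L)]
parallel_set <- names(sort(abs(L), decreasing = TRUE))[seq_len(60)]
background_set <- union(select_parallel_loci(L, 0.10), parallel_set)

res <- overrepresentation_test(calls, parallel_set, background_set,
                               n_draws = 1000, seed = seed)
utils::write.table(res, file.path(out, "overrepresentation.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("overrepresentation of classes among parallel loci (F1_1):\n")
print(res[res$f1 == "F1_1",
          c("class", "observed", "null_median", "p_empirical", "significant")])

# overlap of the parallel set with a second, independently defined locus set
other <- names(sort(L))[seq_len(100)]
ov <- hypergeometric_overlap(parallel_set, other, names(L))
cat(sprintf("hypergeometric overlap: %d of %d vs %d in a universe of %d, p = %.3g\n",
            ov$overlap, ov$nA, ov$nB, ov$universe, ov$p))
write_run_summary(file.path(out, "run_summary.json"), "enrich", seed = seed,
                  overlap_p = ov$p)
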