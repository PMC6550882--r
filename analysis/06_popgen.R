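#!/usr/bin/env Rscript

# Selection signatures around transcription start sites: per-site
# Weir-Cockerham FST and nucleotide diversity from the simulated VCF, CSS in
# 10 kb windows with top-1% outliers, strand-oriented TSS profiles for sweep
# vs control loci, and the transcript-to-outlier-window proximity
# randomization.

suppressPackageStartupMessages(library(paracis))

sim <- "results/sim"
out <- "results/popgen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20190518

gt <- read_genotypes(file.path(sim, "pop_genotypes.vcf"))
geno_samples <- utils::read.delim(file.path(sim, "pop_geno_samples.tsv"),
                                  stringsAsFactors = FALSE)
transcripts <- read_tss(file.path(sim, "pop_tss.bed"))
truth <- utils::read.delim(file.path(sim, "sweep_truth.tsv"),
                           stringsAsFactors = FALSE)
eco <- geno_samples$ecotype[match(colnames(gt$geno),
                                  geno_samples$sample_id)]

st <- site_stats(gt$geno, gt$sites, eco)
utils::write.table(st, file.path(out, "site_stats.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("sites: %d; FST computed at %d; genome-wide mean FST %.3f\n",
            nrow(st), sum(!is.na(st$fst)), mean(st$fst, na.rm = TRUE)))

grp <- ifelse(truth$sweep, "sweep", "control")
names(grp) <- truth$transcript_id
prof <- tss_profiles(st, transcripts, grp, span = 4e5, window = 1e3)
utils::write.table(prof, file.path(out, "tss_profiles.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
for (g in c("sweep", "control")) {
  f <- prof[prof$group == g & prof$stat == "fst", ]
  cat(sprintf("%s loci: mean FST %.3f at |offset| < 5 kb, %.3f beyond 100 kb\n",
              g, mean(f$mean[abs(f$offset) < 5e3], na.rm = TRUE),
              mean(f$mean[abs(f$offset) > 1e5], na.rm = TRUE)))
}

cw <- css_windows(gt$geno, gt$sites, eco, window = 1e4, top_frac = 0.01)
utils::write.table(cw, file.path(out, "css_windows.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("CSS windows: %d; outliers (top 1%%): %d\n",
            nrow(cw), sum(cw$outlier)))

pr <- proximity_randomization(transcripts, cw[cw$outlier, ],
                              names(grp)[grp == "sweep"],
                              n_random = 1000, seed = seed)
utils::write.table(pr, file.path(out, "proximity_randomization.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("sweep transcripts within 0 bp of a CSS outlier window: %.2f (null 95%% band %.2f-%.2f)\n",
            pr$observed[1], pr$null_lo[1], pr$null_hi[1]))
write_run_summary(file.path(out, "run_summary.json"), "popgen", seed = seed)
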