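#!/usr/bin/env Rscript

# Generate the synthetic study: a marine x freshwater cross with four F1
# hybrids (allele-specific counts at informative SNPs), population expression
# across two river systems, diploid population genotypes with planted
# selective sweeps around a quarter of the TSSs, and F1 siblings acclimated
# to three salinities. All planted truth is written alongside the data so
# every downstream analysis can be checked against it.

suppressPackageStartupMessages(library(paracis))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20190515

## cross for ASE classification (realistic class mix, depth 200 per SNP)
cfg_cross <- sim_config(n_genes = 2000, seed = seed, depth_snp = 200,
                        mapping_bias = 0.51)
cr <- simulate_cross(cfg_cross)
write_sim_config(cfg_cross, file.path(out, "config_cross.yaml"))
write_counts(cr$counts, file.path(out, "cross_counts.tsv"))
write_allele_counts(cr$allele_counts, file.path(out, "cross_allele_counts.tsv"))
write_tss_bed(cr$transcripts, file.path(out, "cross_transcripts.bed"))
utils::write.table(cr$parent_calls, file.path(out, "cross_parent_calls.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cr$samples, file.path(out, "cross_samples.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cr$truth, file.path(out, "cross_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(cr$snp_truth, file.path(out, "cross_snp_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("cross:", nrow(cr$counts), "genes,",
    nrow(cr$allele_counts), "allele-count records\n")

## population expression for the composite-PC analysis (8v8 core)
cfg_pop <- sim_config(n_genes = 5000, seed = seed + 1, n_rivers = 2,
                      samples_per_group = 4, parallel_frac = 0.01,
                      parallel_effect = 1, noise_sd = 0.5)
pe <- simulate_population_expression(cfg_pop)
write_counts(pe$counts, file.path(out, "pop_counts.tsv"))
utils::write.table(pe$samples, file.path(out, "pop_samples.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pe$truth, file.path(out, "pop_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("population expression:", nrow(pe$counts), "genes x",
    ncol(pe$counts), "samples;", sum(pe$truth$parallel), "planted parallel\n")

## genotypes with planted sweeps (6v6 diploids)
cfg_gt <- sim_config(seed = seed + 2, n_sites = 8000, chrom_length = 4e6,
                     n_tss = 40, sweep_tss_frac = 0.25, sweep_width = 2e4)
gt <- simulate_genotypes(cfg_gt)
write_genotypes_vcf(gt$geno, gt$sites, file.path(out, "pop_genotypes.vcf"))
write_tss_bed(gt$transcripts, file.path(out, "pop_tss.bed"))
utils::write.table(gt$samples, file.path(out, "pop_geno_samples.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(gt$truth, file.path(out, "sweep_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("genotypes:", nrow(gt$geno), "sites x", ncol(gt$geno), "individuals;",
    sum(gt$truth$sweep), "sweep TSSs\n")

## salinity acclimation of F1 siblings
cfg_sal <- sim_config(n_genes = 500, seed = seed + 3, depth_snp = 1000,
                      class_props = c(cis = 0.5, conserved = 0.5),
                      effect_jitter_sd = 0.5, plastic_frac = 0.3,
                      plasticity_shift = 1)
sal <- simulate_salinity_f1s(cfg_sal)
write_counts(sal$counts, file.path(out, "salinity_counts.tsv"))
write_allele_counts(sal$allele_counts,
                    file.path(out, "salinity_allele_counts.tsv"))
utils::write.table(sal$samples, file.path(out, "salinity_samples.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sal$truth, file.path(out, "salinity_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(sal$snp_truth, file.path(out, "salinity_snp_truth.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("salinity:", nrow(sal$counts), "genes;",
    sum(sal$truth$plastic), "plastic\n")

write_run_summary(file.path(out, "run_summary.json"), "simulate",
                  seed = seed)
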