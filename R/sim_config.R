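#' Simulation configuration
#'
#' Builds and validates the configuration object shared by all synthetic-data
#' generators. Defaults define the study conditions the generators emulate:
#' a marine x freshwater cross with two homozygous parents and four F1
#' hybrids, RNA-seq read counts at informative SNPs, population expression
#' across rivers, diploid population genotypes with planted selective sweeps,
#' and F1 siblings acclimated to three salinities.
#'
#' @param n_genes Number of transcribed loci to simulate.
#' @param class_props Named numeric vector of regulatory-class proportions over
#'   `c("cis","trans","cis+trans","cis-trans","compensatory","conserved")`;
#'   must sum to 1.
#' @param cis_effect,trans_effect Magnitudes (log2) of planted cis and trans
#'   effects; signs are drawn at random per gene.
#' @param effect_jitter_sd SD (log2) of a log-normal spread applied to the
#'   per-gene effect magnitudes; 0 (default) plants the exact configured
#'   magnitudes, positive values give a continuous effect-size distribution
#'   (needed by rank-based stability statistics, which degenerate when all
#'   loci share one magnitude). `cis+trans` uses equal signs,
#'   `compensatory` uses `t = -c`, and `cis-trans` (opposing) uses
#'   `t = -sign(c) * (cis_effect + trans_effect)` so the parental ratio stays
#'   nonzero as the class definition requires.
#' @param depth_snp Mean RNA-seq reads per SNP per individual.
#' @param depth_gene Mean gene-level counts per sample.
#' @param dispersion Negative-binomial dispersion of count noise (variance =
#'   mu + dispersion * mu^2); the default 0 gives Poisson read sampling, which
#'   keeps the planted parental ratio `2^(c+t)` exact in expectation and the
#'   conditional allele fractions binomial; biological across-individual
#'   variance is carried by `noise_sd` instead.
#' @param mapping_bias Reference-mapping bias b in \[0.5, 1): a heterozygous
#'   site with true reference fraction r is observed with reference fraction
#'   `b*r / (b*r + (1-b)*(1-r))`.
#' @param snps_per_transcript Informative SNPs per transcript.
#' @param dna_depth Mean parental DNA sequencing depth per SNP (genotype
#'   support).
#' @param n_f1 Number of F1 hybrids per cross.
#' @param lib_size_sd SD (log2) of per-sample library-size factors.
#' @param inheritance `"additive"` (F1 total expression = midparent in
#'   expectation) or `"multiplicative"` (geometric mean parent level with the
#'   allelic-sum correction).
#' @param n_rivers Number of river systems for the population-expression
#'   generator.
#' @param samples_per_group Samples per ecotype per river.
#' @param parallel_frac Fraction of genes with a planted parallel ecotype
#'   effect.
#' @param parallel_effect Parallel effect size, log2 units (split +/- half
#'   between ecotypes); default 2 * `noise_sd`.
#' @param noise_sd SD (log2) of biological across-sample expression noise.
#' @param river_sd SD (log2) of gene-by-river offsets.
#' @param base_log2_mean Mean of per-gene baseline log2 expression.
#' @param n_ind_per_ecotype Diploid individuals per ecotype for genotype
#'   simulation (study design: 6).
#' @param n_sites Number of biallelic SNP sites.
#' @param chrom_length Simulated chromosome length (bp).
#' @param n_tss Number of transcripts/TSSs placed on the chromosome.
#' @param sweep_tss_frac Fraction of TSSs sitting in a planted sweep.
#' @param sweep_width Sweep half-width (bp): divergence/diversity distortion
#'   decays linearly to zero over this distance from the TSS.
#' @param sweep_intensity Sweep intensity in \[0, 1\]; 1 fixes alternate
#'   ecotype alleles at the TSS.
#' @param missing_rate Per-genotype missing rate.
#' @param salinities Salinity levels (ppt) for the plasticity generator.
#' @param f1_per_salinity F1 siblings per salinity group.
#' @param plastic_frac Fraction of genes with a trans-mediated salinity
#'   response.
#' @param plasticity_shift Magnitude (log2) of the salinity trans shift.
#' @param seed Optional RNG seed applied by each generator.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       class_props = c("cis" = 0.12, "trans" = 0.06,
                                       "cis+trans" = 0.04, "cis-trans" = 0.03,
                                       "compensatory" = 0.05, "conserved" = 0.70),
                       cis_effect = 1, trans_effect = 1,
                       effect_jitter_sd = 0,
                       depth_snp = 200, depth_gene = 500,
                       dispersion = 0, mapping_bias = 0.5,
                       snps_per_transcript = 3, dna_depth = 30, n_f1 = 4,
                       lib_size_sd = 0.15, inheritance = c("additive", "multiplicative"),
                       n_rivers = 2, samples_per_group = 4,
                       parallel_frac = 0.01, parallel_effect = NULL,
                       noise_sd = 0.5, river_sd = 0.5, base_log2_mean = 8,
                       n_ind_per_ecotype = 6, n_sites = 5000,
                       chrom_length = 5e6, n_tss = 40,
                       sweep_tss_frac = 0.25, sweep_width = 2e4,
                       sweep_intensity = 1, missing_rate = 0.02,
                       salinities = c(0.2, 3.5, 35), f1_per_salinity = 4,
                       plastic_frac = 0.3, plasticity_shift = 1,
                       seed = NULL) {
  inheritance <- match.arg(inheritance)
  cfg <- list(
    n_genes = n_genes, class_props = class_props,
    cis_effect = cis_effect, trans_effect = trans_effect,
    effect_jitter_sd = effect_jitter_sd,
    depth_snp = depth_snp, depth_gene = depth_gene,
    dispersion = dispersion, mapping_bias = mapping_bias,
    snps_per_transcript = snps_per_transcript, dna_depth = dna_depth,
    n_f1 = n_f1, lib_size_sd = lib_size_sd, inheritance = inheritance,
    n_rivers = n_rivers, samples_per_group = samples_per_group,
    parallel_frac = parallel_frac,
    parallel_effect = parallel_effect %||% (2 * noise_sd),
    noise_sd = noise_sd, river_sd = river_sd, base_log2_mean = base_log2_mean,
    n_ind_per_ecotype = n_ind_per_ecotype, n_sites = n_sites,
    chrom_length = chrom_length, n_tss = n_tss,
    sweep_tss_frac = sweep_tss_frac, sweep_width = sweep_width,
    sweep_intensity = sweep_intensity, missing_rate = missing_rate,
    salinities = salinities, f1_per_salinity = f1_per_salinity,
    plastic_frac = plastic_frac, plasticity_shift = plasticity_shift,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg A `sim_config` object to validate.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pr <- cfg$class_props
  classes <- regulatory_classes()[1:6]
  if (is.null(names(pr)) || !all(names(pr) %in% classes))
    stop("class_props must be named with a subset of: ", paste(classes, collapse = ", "))
  if (any(pr < 0) || abs(sum(pr) - 1) > 1e-8)
    stop("class proportions must be non-negative and sum to 1")
  if (cfg$depth_snp <= 0 || cfg$depth_gene <= 0) stop("depth must be > 0")
  if (cfg$mapping_bias < 0.5 || cfg$mapping_bias >= 1)
    stop("mapping_bias must be in [0.5, 1)")
  if (cfg$dispersion < 0) stop("dispersion must be >= 0")
  if (cfg$n_rivers < 2) stop("need >= 2 rivers")
  if (cfg$samples_per_group < 2) stop("need >= 2 samples per ecotype per river")
  if (cfg$sweep_width > cfg$chrom_length) stop("sweep width exceeds chromosome length")
  if (cfg$sweep_intensity < 0 || cfg$sweep_intensity > 1)
    stop("sweep_intensity must be in [0, 1]")
  if (length(cfg$salinities) < 2) stop("need >= 2 salinity levels")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) stop("invalid missing_rate")
  cfg
}

#' Regulatory divergence class labels
#'
#' The seven classes used throughout: allele-specific (`cis`), non
#' allele-specific (`trans`), same-sign (`cis+trans`) and opposing
#' (`cis-trans`) combinations, cancelling (`compensatory`), no divergence
#' (`conserved`), and unclassifiable test-flag combinations (`ambiguous`).
#'
#' @return Character vector of class labels.
#' @export
regulatory_classes <- function() {
  c("cis", "trans", "cis+trans", "cis-trans", "compensatory", "conserved",
    "ambiguous")
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config` returns a `sim_config`; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  lst <- unclass(cfg)
  lst$class_props <- as.list(lst$class_props)   # keep names in the YAML map
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$class_props <- unlist(lst$class_props)
  lst$salinities <- unlist(lst$salinities)
  cfg <- structure(lst, class = "sim_config")
  validate_sim_config(cfg)
}
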