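# Synthetic-data generators. Every downstream stage of the pipeline is
# exercised on these outputs, with planted truth recorded per gene/SNP/site.

# overdispersed count draw: variance = mu + phi * mu^2 (Poisson when phi = 0)
nb_draw <- function(n, mu, phi) {
  if (phi <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# per-gene baseline multipliers, lognormal with mean exactly 1 so that the
# configured depth is the marginal mean count
gene_multipliers <- function(n, sd_log2 = 0.8) {
  2^stats::rnorm(n, 0, sd_log2) / exp((sd_log2 * log(2))^2 / 2)
}

# mapping-bias distortion of a true reference-allele fraction r
bias_ref_fraction <- function(r, b) {
  b * r / (b * r + (1 - b) * (1 - r))
}

# draw per-class cis (c) and trans (t) log2 effects honouring the class
# sign constraints
class_effects <- function(classes, cfg) {
  n <- length(classes)
  s <- sample(c(-1, 1), n, replace = TRUE)
  jit <- cfg$effect_jitter_sd %||% 0
  # per-gene magnitudes: fixed at the configured effect size, or spread
  # log-normally around it (continuous effect-size distribution)
  ce <- cfg$cis_effect * 2^stats::rnorm(n, 0, jit)
  te <- cfg$trans_effect * 2^stats::rnorm(n, 0, jit)
  c_eff <- rep(0, n)
  t_eff <- rep(0, n)
  c_eff[classes == "cis"] <- (s * ce)[classes == "cis"]
  t_eff[classes == "trans"] <- (s * te)[classes == "trans"]
  i <- classes == "cis+trans"
  c_eff[i] <- (s * ce)[i]; t_eff[i] <- (s * te)[i]
  i <- classes == "cis-trans"           # opposing signs, parental ratio nonzero
  c_eff[i] <- (s * ce)[i]; t_eff[i] <- (-s * (ce + te))[i]
  i <- classes == "compensatory"        # cancels exactly in the parents
  c_eff[i] <- (s * ce)[i]; t_eff[i] <- (-s * ce)[i]
  data.frame(class = classes, cis_effect = c_eff, trans_effect = t_eff,
             stringsAsFactors = FALSE)
}

# lay transcripts along a synthetic chromosome, one exon per transcript
sim_transcripts <- function(n, spacing = 2000L, width = 1000L, chrom = "chrSim") {
  start <- 1L + (seq_len(n) - 1L) * spacing
  strand <- rep(c("+", "-"), length.out = n)
  data.frame(
    transcript_id = sprintf("TCONS_%05d", seq_len(n)),
    locus_id = sprintf("XLOC_%05d", seq_len(n)),
    chrom = chrom, strand = strand,
    start = start, end = start + width - 1L,
    tss = ifelse(strand == "+", start, start + width - 1L),
    stringsAsFactors = FALSE
  )
}

#' Simulate a marine x freshwater cross with allele-specific counts
#'
#' Generates two homozygous parents and `n_f1` F1 hybrids for one cross.
#' Per gene, a regulatory class is drawn from `class_props` and its cis (`c`)
#' and trans (`t`) log2 effects planted so that the expected parental
#' marine/freshwater expression ratio is `2^(c + t)` and the expected F1
#' marine/freshwater allelic ratio is `2^c`. Read counts at informative SNPs
#' are overdispersed (negative binomial) around expected depths, and the
#' observed reference-allele fraction at heterozygous sites is distorted by
#' the mapping-bias parameter `b`.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{allele_counts}{long data frame: chrom, pos, refAllele, altAllele,
#'       sample, refCount, altCount for both parents and all F1s}
#'     \item{counts}{gene-level count matrix (transcripts x samples)}
#'     \item{samples}{sample table (id, ecotype, role, family)}
#'     \item{parent_calls}{parental genotypes and DNA depths per SNP}
#'     \item{transcripts}{transcript models with TSSs}
#'     \item{snp_truth}{per-SNP bookkeeping incl. which allele is marine}
#'     \item{truth}{per-gene class and planted c, t effects}
#'   }
#' @export
simulate_cross <- function(cfg) {
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_genes
  phi <- cfg$dispersion
  b <- cfg$mapping_bias

  truth <- class_effects(
    sample(names(cfg$class_props), n, replace = TRUE, prob = cfg$class_props), cfg)
  tr <- sim_transcripts(n)
  truth <- cbind(transcript_id = tr$transcript_id, truth, stringsAsFactors = FALSE)

  sample_ids <- c("marine_parent", "fresh_parent", paste0("F1_", seq_len(cfg$n_f1)))
  samples <- data.frame(
    sample_id = sample_ids,
    river = "SimRiver",
    ecotype = c("marine", "freshwater", rep("hybrid", cfg$n_f1)),
    sex = NA_character_,
    role = c("parent", "parent", rep("F1", cfg$n_f1)),
    family = "cross1",
    salinity = NA_real_,
    stringsAsFactors = FALSE
  )
  lib <- 2^stats::rnorm(length(sample_ids), 0, cfg$lib_size_sd)
  names(lib) <- sample_ids

  # expected expression multipliers (relative to per-gene baseline)
  mult_m <- 2^((truth$cis_effect + truth$trans_effect) / 2)
  mult_f <- 2^(-(truth$cis_effect + truth$trans_effect) / 2)
  mult_f1 <- if (cfg$inheritance == "additive") {
    (mult_m + mult_f) / 2
  } else {
    (2^(truth$cis_effect / 2) + 2^(-truth$cis_effect / 2)) / 2
  }
  frac_marine_f1 <- 2^truth$cis_effect / (1 + 2^truth$cis_effect)

  base_g <- gene_multipliers(n)
  mu_gene <- cbind(mult_m, mult_f, matrix(mult_f1, n, cfg$n_f1)) * base_g * cfg$depth_gene
  counts <- matrix(nb_draw(length(mu_gene), sweep(mu_gene, 2, lib, "*"), phi),
                   n, length(sample_ids),
                   dimnames = list(tr$transcript_id, sample_ids))

  # informative SNPs inside each transcript's exon
  k <- cfg$snps_per_transcript
  offs <- round(seq(50, 950, length.out = k))
  snp <- data.frame(
    transcript_id = rep(tr$transcript_id, each = k),
    exon_id = paste0(rep(tr$transcript_id, each = k), ":e1"),
    chrom = "chrSim",
    pos = rep(tr$start, each = k) + rep(offs, n),
    gene_index = rep(seq_len(n), each = k),
    stringsAsFactors = FALSE
  )
  nsnp <- nrow(snp)
  alleles <- c("A", "C", "G", "T")
  snp$refAllele <- sample(alleles, nsnp, replace = TRUE)
  snp$altAllele <- vapply(snp$refAllele,
                          function(a) sample(setdiff(alleles, a), 1L), "")
  snp$marine_is_ref <- sample(c(TRUE, FALSE), nsnp, replace = TRUE)

  g <- snp$gene_index
  mu_snp <- base_g[g] * cfg$depth_snp
  # parents express only their own allele
  tot_m <- nb_draw(nsnp, mu_snp * mult_m[g] * lib["marine_parent"], phi)
  tot_f <- nb_draw(nsnp, mu_snp * mult_f[g] * lib["fresh_parent"], phi)
  ac <- list(
    data.frame(snp[c("chrom", "pos", "refAllele", "altAllele")],
               sample = "marine_parent",
               refCount = ifelse(snp$marine_is_ref, tot_m, 0L),
               altCount = ifelse(snp$marine_is_ref, 0L, tot_m),
               stringsAsFactors = FALSE),
    data.frame(snp[c("chrom", "pos", "refAllele", "altAllele")],
               sample = "fresh_parent",
               refCount = ifelse(snp$marine_is_ref, 0L, tot_f),
               altCount = ifelse(snp$marine_is_ref, tot_f, 0L),
               stringsAsFactors = FALSE)
  )
  r_marine <- frac_marine_f1[g]
  r_ref <- ifelse(snp$marine_is_ref, r_marine, 1 - r_marine)
  r_obs <- bias_ref_fraction(r_ref, b)
  for (j in seq_len(cfg$n_f1)) {
    sid <- paste0("F1_", j)
    tot <- nb_draw(nsnp, mu_snp * mult_f1[g] * lib[sid], phi)
    refc <- stats::rbinom(nsnp, tot, r_obs)
    ac[[length(ac) + 1L]] <- data.frame(
      snp[c("chrom", "pos", "refAllele", "altAllele")],
      sample = sid, refCount = refc, altCount = tot - refc,
      stringsAsFactors = FALSE)
  }
  allele_counts <- do.call(rbind, ac)
  rownames(allele_counts) <- NULL

  parent_calls <- data.frame(
    snp[c("chrom", "pos", "refAllele", "altAllele")],
    gt_marine = ifelse(snp$marine_is_ref, "0/0", "1/1"),
    gt_fresh = ifelse(snp$marine_is_ref, "1/1", "0/0"),
    dp_marine = stats::rpois(nsnp, cfg$dna_depth),
    dp_fresh = stats::rpois(nsnp, cfg$dna_depth),
    stringsAsFactors = FALSE
  )

  list(allele_counts = allele_counts, counts = counts, samples = samples,
       parent_calls = parent_calls, transcripts = tr,
       snp_truth = snp[c("chrom", "pos", "transcript_id", "exon_id",
                         "refAllele", "altAllele", "marine_is_ref")],
       truth = truth)
}

#' Simulate population expression across rivers and ecotypes
#'
#' Gene-level log2 means are baseline + gene-by-river offset + ecotype x
#' parallel effect + Gaussian biological noise; counts are drawn around
#' `2^mean` with the configured overdispersion. A fraction `parallel_frac` of
#' genes carries a parallel ecotype effect (`parallel_effect` log2 units,
#' split half up in marine, half down, with a random sign per gene) shared
#' across all rivers; these genes are flagged in the returned truth table.
#'
#' @param cfg A [sim_config()] object (needs >= 2 rivers and >= 2 samples per
#'   ecotype per river).
#' @return A list: `counts` (matrix genes x samples), `samples` (sample
#'   table with river and ecotype), `truth` (per-gene parallel effect and
#'   flag).
#' @export
simulate_population_expression <- function(cfg) {
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_genes
  rivers <- paste0("R", seq_len(cfg$n_rivers))
  grid <- expand.grid(rep = seq_len(cfg$samples_per_group),
                      ecotype = c("marine", "freshwater"), river = rivers,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("%s_%s_%d", grid$river, substr(grid$ecotype, 1, 1), grid$rep),
    river = grid$river, ecotype = grid$ecotype,
    sex = NA_character_, role = "pure", family = NA_character_,
    salinity = NA_real_, stringsAsFactors = FALSE
  )
  m <- nrow(samples)

  base <- stats::rnorm(n, cfg$base_log2_mean, 1)
  river_eff <- matrix(stats::rnorm(n * cfg$n_rivers, 0, cfg$river_sd), n,
                      dimnames = list(NULL, rivers))
  n_par <- round(cfg$parallel_frac * n)
  parallel_effect <- rep(0, n)
  if (n_par > 0) {
    idx <- sample.int(n, n_par)
    parallel_effect[idx] <- cfg$parallel_effect * sample(c(-1, 1), n_par, TRUE)
  }
  eco_sign <- ifelse(samples$ecotype == "marine", 0.5, -0.5)

  log2_mu <- base + river_eff[, samples$river] +
    outer(parallel_effect, eco_sign) +
    matrix(stats::rnorm(n * m, 0, cfg$noise_sd), n, m)
  counts <- matrix(nb_draw(n * m, 2^log2_mu, cfg$dispersion), n, m,
                   dimnames = list(sprintf("TCONS_%05d", seq_len(n)),
                                   samples$sample_id))
  truth <- data.frame(transcript_id = rownames(counts),
                      parallel_effect = parallel_effect,
                      parallel = parallel_effect != 0,
                      stringsAsFactors = FALSE)
  list(counts = counts, samples = samples, truth = truth)
}

#' Simulate diploid population genotypes with planted selective sweeps
#'
#' Neutral sites share allele frequencies between ecotypes; sites near a sweep
#' TSS are pushed toward alternate-allele fixation within each ecotype (marine
#' toward reference, freshwater toward alternate), with the distortion decaying
#' linearly over `sweep_width` from the TSS. This plants a local elevation of
#' FST and depression of within-ecotype nucleotide diversity around sweep
#' TSSs. Missing genotypes are injected at `missing_rate`.
#'
#' @param cfg A [sim_config()] object (needs >= 6 diploids per ecotype).
#' @return A list: `geno` (sites x individuals matrix of 0/1/2/NA), `sites`
#'   (chrom, pos, ref, alt), `samples` (id, ecotype), `transcripts`
#'   (transcript models with TSS), `truth` (per-transcript sweep flag).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_ind_per_ecotype < 6)
    stop("need >= 6 diploid individuals per ecotype")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  L <- cfg$chrom_length
  margin <- min(2.5e5, L / 10)
  tss_pos <- round(seq(margin, L - margin, length.out = cfg$n_tss))
  n_sweep <- round(cfg$sweep_tss_frac * cfg$n_tss)
  sweep_idx <- sort(sample.int(cfg$n_tss, n_sweep))
  transcripts <- data.frame(
    transcript_id = sprintf("TCONS_%05d", seq_len(cfg$n_tss)),
    locus_id = sprintf("XLOC_%05d", seq_len(cfg$n_tss)),
    chrom = "chrSim", strand = "+",
    start = tss_pos, end = tss_pos + 999L, tss = tss_pos,
    stringsAsFactors = FALSE
  )
  truth <- data.frame(transcript_id = transcripts$transcript_id,
                      sweep = seq_len(cfg$n_tss) %in% sweep_idx,
                      stringsAsFactors = FALSE)

  pos <- sort(sample.int(L, cfg$n_sites))
  p0 <- stats::runif(cfg$n_sites, 0.1, 0.9)
  d <- if (n_sweep > 0) {
    vapply(pos, function(x) min(abs(x - tss_pos[sweep_idx])), 0)
  } else rep(Inf, cfg$n_sites)
  w <- cfg$sweep_intensity * pmax(0, 1 - d / cfg$sweep_width)
  p_marine <- p0 * (1 - w)            # alt freq, swept toward ref in marine
  p_fresh <- p0 + w * (1 - p0)        # swept toward alt in freshwater

  n_ind <- cfg$n_ind_per_ecotype
  samples <- data.frame(
    sample_id = c(paste0("M", seq_len(n_ind)), paste0("F", seq_len(n_ind))),
    ecotype = rep(c("marine", "freshwater"), each = n_ind),
    stringsAsFactors = FALSE
  )
  geno <- cbind(
    matrix(stats::rbinom(cfg$n_sites * n_ind, 2, rep(p_marine, n_ind)),
           cfg$n_sites, n_ind),
    matrix(stats::rbinom(cfg$n_sites * n_ind, 2, rep(p_fresh, n_ind)),
           cfg$n_sites, n_ind)
  )
  colnames(geno) <- samples$sample_id
  if (cfg$missing_rate > 0) {
    geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA_integer_
  }
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, cfg$n_sites, replace = TRUE)
  alt <- vapply(ref, function(a) sample(setdiff(alleles, a), 1L), "")
  sites <- data.frame(chrom = "chrSim", pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  list(geno = geno, sites = sites, samples = samples,
       transcripts = transcripts, truth = truth)
}

#' Simulate F1 siblings acclimated to different salinities
#'
#' Salinity shifts total expression of plastic genes through trans-acting
#' regulation: both alleles move equally, so the allelic (cis) ratio stays at
#' `2^c` in every salinity. The planted shift is `+plasticity_shift * dir` at
#' the lowest salinity, 0 at intermediate levels and `-plasticity_shift * dir`
#' at the highest, with a random direction `dir` per plastic gene, so
#' freshwater- and seawater-acclimated siblings show opposite expression
#' profiles.
#'
#' @param cfg A [sim_config()] object (needs >= 2 salinity levels).
#' @return A list: `counts` (genes x samples), `allele_counts` (long table as
#'   in [simulate_cross()]), `samples` (with salinity), `snp_truth`, `truth`
#'   (class, c, plastic flag and direction).
#' @export
simulate_salinity_f1s <- function(cfg) {
  validate_sim_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_genes
  phi <- cfg$dispersion
  b <- cfg$mapping_bias
  sal <- sort(cfg$salinities)
  n_sal <- length(sal)

  truth <- class_effects(
    sample(names(cfg$class_props), n, replace = TRUE, prob = cfg$class_props), cfg)
  tr <- sim_transcripts(n)
  truth <- cbind(transcript_id = tr$transcript_id, truth, stringsAsFactors = FALSE)
  truth$plastic <- stats::runif(n) < cfg$plastic_frac
  truth$plastic_dir <- ifelse(truth$plastic, sample(c(-1, 1), n, TRUE), 0)

  # salinity coefficient: +1 at the lowest level down to -1 at the highest
  sal_coef <- seq(1, -1, length.out = n_sal)
  names(sal_coef) <- as.character(sal)

  grid <- expand.grid(rep = seq_len(cfg$f1_per_salinity), salinity = sal)
  samples <- data.frame(
    sample_id = sprintf("F1_s%g_%d", grid$salinity, grid$rep),
    river = "SimRiver", ecotype = "hybrid", sex = NA_character_,
    role = "F1", family = "cross1", salinity = grid$salinity,
    stringsAsFactors = FALSE
  )
  m <- nrow(samples)
  lib <- 2^stats::rnorm(m, 0, cfg$lib_size_sd)

  base_g <- gene_multipliers(n)
  shift <- outer(truth$plastic_dir * cfg$plasticity_shift,
                 sal_coef[as.character(samples$salinity)])
  mu <- base_g * cfg$depth_gene * 2^shift
  counts <- matrix(nb_draw(n * m, sweep(mu, 2, lib, "*"), phi), n, m,
                   dimnames = list(tr$transcript_id, samples$sample_id))

  k <- cfg$snps_per_transcript
  offs <- round(seq(50, 950, length.out = k))
  snp <- data.frame(
    transcript_id = rep(tr$transcript_id, each = k),
    exon_id = paste0(rep(tr$transcript_id, each = k), ":e1"),
    chrom = "chrSim",
    pos = rep(tr$start, each = k) + rep(offs, n),
    gene_index = rep(seq_len(n), each = k),
    stringsAsFactors = FALSE
  )
  nsnp <- nrow(snp)
  alleles <- c("A", "C", "G", "T")
  snp$refAllele <- sample(alleles, nsnp, replace = TRUE)
  snp$altAllele <- vapply(snp$refAllele,
                          function(a) sample(setdiff(alleles, a), 1L), "")
  snp$marine_is_ref <- sample(c(TRUE, FALSE), nsnp, replace = TRUE)
  g <- snp$gene_index
  r_marine <- 2^truth$cis_effect[g] / (1 + 2^truth$cis_effect[g])
  r_obs <- bias_ref_fraction(ifelse(snp$marine_is_ref, r_marine, 1 - r_marine), b)

  ac <- vector("list", m)
  for (j in seq_len(m)) {
    mu_snp <- base_g[g] * cfg$depth_snp * 2^shift[g, j] * lib[j]
    tot <- nb_draw(nsnp, mu_snp, phi)
    refc <- stats::rbinom(nsnp, tot, r_obs)
    ac[[j]] <- data.frame(
      snp[c("chrom", "pos", "refAllele", "altAllele")],
      sample = samples$sample_id[j], refCount = refc, altCount = tot - refc,
      stringsAsFactors = FALSE)
  }
  allele_counts <- do.call(rbind, ac)
  rownames(allele_counts) <- NULL

  list(counts = counts, allele_counts = allele_counts, samples = samples,
       transcripts = tr,
       snp_truth = snp[c("chrom", "pos", "transcript_id", "exon_id",
                         "refAllele", "altAllele", "marine_is_ref")],
       truth = truth)
}
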