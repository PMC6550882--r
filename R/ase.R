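# Allele-specific expression analysis: informative-SNP selection, coverage and
# monoallelic filters, mapping-bias-adjusted binomial null, the three exact
# tests (F1 ASE, parent-vs-parent, F1-vs-parent Fisher), BH flags per test
# family, the seven-class decision table, lowest-p-product aggregation to
# transcripts, and SNP concordance.

#' Exact two-sided binomial test p-value
#'
#' Minimum-likelihood ("minlike") definition: the sum of probabilities of all
#' outcomes no more likely than the observed one under `Binomial(n, p0)`.
#' This matches the classical exact two-sided convention and is well defined
#' for the asymmetric mapping-bias null `p0 != 0.5`. The `"central"`
#' alternative doubles the smaller tail (capped at 1).
#'
#' @param k Successes (vector).
#' @param n Trials (vector); `n = 0` yields `NA` (SNP skipped).
#' @param p0 Null success probability in (0,1) (vector or scalar).
#' @param alternative `"minlike"` (default) or `"central"`.
#' @return Vector of p-values in \[0,1\].
#' @export
binomial_two_sided <- function(k, n, p0, alternative = c("minlike", "central")) {
  alternative <- match.arg(alternative)
  m <- max(length(k), length(n), length(p0))
  k <- rep_len(k, m); n <- rep_len(n, m); p0 <- rep_len(p0, m)
  stopifnot(all(k >= 0 & k <= n, na.rm = TRUE), all(p0 > 0 & p0 < 1))
  rel_err <- 1 + 1e-7
  vapply(seq_len(m), function(i) {
    if (is.na(n[i]) || n[i] == 0L) return(NA_real_)
    d <- stats::dbinom(0:n[i], n[i], p0[i])
    d_obs <- d[k[i] + 1L]
    if (alternative == "minlike") {
      min(1, sum(d[d <= d_obs * rel_err]))
    } else {
      min(1, 2 * min(stats::pbinom(k[i], n[i], p0[i]),
                     stats::pbinom(k[i] - 1L, n[i], p0[i], lower.tail = FALSE)))
    }
  }, 0)
}

#' Fisher's exact test for allele-ratio versus parental-ratio
#'
#' Two-sided (minimum-likelihood) Fisher exact p for the 2x2 table
#' `[[f1_M, f1_F], [parent_M, parent_F]]`, computed by hypergeometric
#' enumeration conditional on the margins. Vectorized over tables.
#'
#' @param f1_M,f1_F F1 marine- and freshwater-allele read counts.
#' @param parent_M,parent_F Parental marine and freshwater read counts.
#' @return Vector of p-values; `NA` when a margin is zero on both rows.
#' @export
fisher_ratio_test <- function(f1_M, f1_F, parent_M, parent_F) {
  m <- max(length(f1_M), length(f1_F), length(parent_M), length(parent_F))
  a <- rep_len(f1_M, m); b <- rep_len(f1_F, m)
  cc <- rep_len(parent_M, m); d <- rep_len(parent_F, m)
  rel_err <- 1 + 1e-7
  vapply(seq_len(m), function(i) {
    n1 <- a[i] + b[i]; n2 <- cc[i] + d[i]; m1 <- a[i] + cc[i]
    if (n1 + n2 == 0L || is.na(n1) || is.na(n2)) return(NA_real_)
    lo <- max(0L, m1 - n2); hi <- min(n1, m1)
    dd <- stats::dhyper(lo:hi, n1, n2, m1)
    d_obs <- dd[a[i] - lo + 1L]
    min(1, sum(dd[dd <= d_obs * rel_err]))
  }, 0)
}

#' Select SNPs fully informative for allele-specific analysis
#'
#' Keeps SNPs where both parents are homozygous for different alleles with
#' genotypes supported by at least `min_dna_depth` DNA-sequencing reads each,
#' and assigns each SNP to the overlapping transcript and exon; SNPs outside
#' transcript models are dropped.
#'
#' @param parent_calls Data frame with chrom, pos, refAllele, altAllele,
#'   gt_marine, gt_fresh (`"0/0"`/`"0/1"`/`"1/1"`), dp_marine, dp_fresh.
#' @param transcripts Transcript models (see [read_tss()]).
#' @param min_dna_depth Minimum parental DNA depth (default 10).
#' @return Data frame of informative SNPs with transcript_id, exon_id and
#'   `marine_is_ref`.
#' @export
select_informative_snps <- function(parent_calls, transcripts,
                                    min_dna_depth = 10) {
  hom_opposite <- (parent_calls$gt_marine == "0/0" & parent_calls$gt_fresh == "1/1") |
    (parent_calls$gt_marine == "1/1" & parent_calls$gt_fresh == "0/0")
  deep <- parent_calls$dp_marine >= min_dna_depth &
    parent_calls$dp_fresh >= min_dna_depth
  snp <- parent_calls[hom_opposite & deep, , drop = FALSE]
  if (!nrow(snp)) return(cbind(snp, transcript_id = character(0),
                               exon_id = character(0), marine_is_ref = logical(0)))
  snp_gr <- GenomicRanges::GRanges(snp$chrom, IRanges::IRanges(snp$pos, snp$pos))
  tx_gr <- transcripts_to_granges(transcripts)
  hits <- GenomicRanges::findOverlaps(snp_gr, tx_gr, ignore.strand = TRUE)
  snp <- snp[S4Vectors::queryHits(hits), , drop = FALSE]
  snp$transcript_id <- transcripts$transcript_id[S4Vectors::subjectHits(hits)]
  snp$exon_id <- paste0(snp$transcript_id, ":e1")
  snp$marine_is_ref <- snp$gt_marine == "0/0"
  rownames(snp) <- NULL
  snp
}

# long allele-count table -> list of SNP x sample matrices (ref, alt, total)
allele_count_matrices <- function(allele_counts, snp_key) {
  key <- paste(allele_counts$chrom, allele_counts$pos)
  keep <- key %in% snp_key
  ac <- allele_counts[keep, , drop = FALSE]
  key <- key[keep]
  s_ids <- unique(ac$sample)
  ref <- matrix(0, length(snp_key), length(s_ids),
                dimnames = list(snp_key, s_ids))
  alt <- ref
  ref[cbind(match(key, snp_key), match(ac$sample, s_ids))] <- ac$refCount
  alt[cbind(match(key, snp_key), match(ac$sample, s_ids))] <- ac$altCount
  list(ref = ref, alt = alt, total = ref + alt)
}

#' Coverage filter for testable SNPs
#'
#' Retains SNPs covered by more than `min_reads` RNA-seq reads in at least one
#' F1 (strictly greater), to avoid underpowered ASE tests at unexpressed loci.
#'
#' @param total SNP x sample matrix of total read counts.
#' @param f1_ids Column names of the F1 samples.
#' @param min_reads Threshold (default 10; kept iff coverage > 10 in some F1).
#' @return Logical vector over SNPs.
#' @export
filter_expression_coverage <- function(total, f1_ids, min_reads = 10) {
  apply(total[, f1_ids, drop = FALSE], 1L, max) > min_reads
}

#' Monoallelic-expression and parental-concordance filter
#'
#' Flags SNPs for exclusion when (a) any F1 shows zero reads for one allele
#' while carrying at least `mono_total` total reads (sampling zeros at low
#' coverage are kept; consistent zeros at high coverage indicate mappability
#' artifacts), or (b) a parent shows more than `parent_tol` of its reads on
#' the allele it should not carry.
#'
#' @param ref,alt SNP x sample count matrices.
#' @param f1_ids F1 column names.
#' @param marine_is_ref Logical per SNP.
#' @param marine_id,fresh_id Parent column names.
#' @param mono_total Total-read threshold for calling monoallelic (default 20).
#' @param parent_tol Maximum tolerated wrong-allele fraction in a parent
#'   (default 0.01).
#' @return Logical vector: TRUE = keep.
#' @export
exclude_monoallelic <- function(ref, alt, f1_ids, marine_is_ref,
                                marine_id, fresh_id,
                                mono_total = 20, parent_tol = 0.01) {
  f1r <- ref[, f1_ids, drop = FALSE]
  f1a <- alt[, f1_ids, drop = FALSE]
  tot <- f1r + f1a
  mono <- ((f1r == 0) | (f1a == 0)) & (tot >= mono_total)
  mono_any <- apply(mono, 1L, any)

  m_tot <- ref[, marine_id] + alt[, marine_id]
  f_tot <- ref[, fresh_id] + alt[, fresh_id]
  m_wrong <- ifelse(marine_is_ref, alt[, marine_id], ref[, marine_id])
  f_wrong <- ifelse(marine_is_ref, ref[, fresh_id], alt[, fresh_id])
  bad_parent <- (m_tot > 0 & m_wrong / m_tot > parent_tol) |
    (f_tot > 0 & f_wrong / f_tot > parent_tol)
  !(mono_any | bad_parent)
}

#' Mapping-bias-adjusted binomial null per F1
#'
#' The null reference-allele fraction for the ASE binomial test: the ratio of
#' all reference reads over all reads of that F1 across its informative SNPs.
#' Values above 0.5 indicate residual preferential mapping of reference
#' alleles.
#'
#' @param ref,alt SNP x sample count matrices (informative SNPs only).
#' @param f1_id F1 sample (column) name.
#' @return Scalar p0 in (0,1).
#' @export
estimate_null_ratio <- function(ref, alt, f1_id) {
  r <- sum(ref[, f1_id]); a <- sum(alt[, f1_id])
  if (r + a == 0) stop("no reads for F1 ", f1_id)
  p0 <- r / (r + a)
  if (p0 <= 0 || p0 >= 1) stop("degenerate null ratio for F1 ", f1_id)
  p0
}

#' Parent-vs-parent expression test at a SNP
#'
#' Exact binomial test of the marine parent's read count against the total,
#' with the null fraction `sM / (sM + sF)` given by the parents' library size
#' factors (folding normalization into the null keeps the test exact on
#' integer counts). The parental log2 ratio `R_P` uses size-factor-scaled
#' counts with a 0.5 pseudocount.
#'
#' @param parent_M,parent_F Parental read counts (vectors).
#' @param sf_M,sf_F Parental size factors.
#' @param alternative Passed to [binomial_two_sided()].
#' @return Data frame with `p_parent` and `R_P`.
#' @export
parent_expression_test <- function(parent_M, parent_F, sf_M = 1, sf_F = 1,
                                   alternative = "minlike") {
  p <- binomial_two_sided(parent_M, parent_M + parent_F,
                          sf_M / (sf_M + sf_F), alternative)
  data.frame(p_parent = p,
             R_P = log2_ratio(parent_M / sf_M, parent_F / sf_F))
}

#' Regulatory divergence decision table
#'
#' Maps the three significance flags and the signs of the cis (`R_F1`) and
#' trans (`R_P - R_F1`) components to the seven divergence classes:
#' \tabular{llll}{
#'   parent \tab ASE \tab Fisher \tab class \cr
#'   yes \tab yes \tab no  \tab cis \cr
#'   yes \tab no  \tab yes \tab trans \cr
#'   yes \tab yes \tab yes \tab cis+trans (same sign) / cis-trans (opposite) \cr
#'   no  \tab yes \tab yes \tab compensatory \cr
#'   no  \tab no  \tab no  \tab conserved \cr
#'   \tab \tab \tab anything else: ambiguous \cr
#' }
#'
#' @param sig_parent,sig_ase,sig_fisher Logical vectors of test flags.
#' @param R_F1 F1 allelic log2 ratio (cis component).
#' @param R_P Parental log2 ratio.
#' @return Character vector of class labels.
#' @export
classify_regulatory <- function(sig_parent, sig_ase, sig_fisher, R_F1, R_P) {
  trans_comp <- R_P - R_F1
  out <- rep("ambiguous", length(sig_parent))
  out[sig_parent & sig_ase & !sig_fisher] <- "cis"
  out[sig_parent & !sig_ase & sig_fisher] <- "trans"
  both <- sig_parent & sig_ase & sig_fisher
  same <- sign(R_F1) == sign(trans_comp)
  out[both & same] <- "cis+trans"
  out[both & !same] <- "cis-trans"
  out[!sig_parent & sig_ase & sig_fisher] <- "compensatory"
  out[!sig_parent & !sig_ase & !sig_fisher] <- "conserved"
  out[is.na(sig_parent) | is.na(sig_ase) | is.na(sig_fisher)] <- NA_character_
  out
}

#' Aggregate per-SNP results to one call per transcript per F1
#'
#' The representative SNP minimizes the product of the three test p-values
#' (ties broken by genomic coordinate); its class and magnitudes become the
#' transcript's call for that F1.
#'
#' @param snp_results Long per-SNP, per-F1 results (from [ase_classify()]).
#' @return Data frame with one row per transcript per F1.
#' @export
aggregate_to_transcript <- function(snp_results) {
  ok <- !is.na(snp_results$p_parent) & !is.na(snp_results$p_ase) &
    !is.na(snp_results$p_fisher)
  res <- snp_results[ok, , drop = FALSE]
  if (!nrow(res)) return(res)
  res$p_product <- res$p_parent * res$p_ase * res$p_fisher
  ord <- order(res$transcript_id, res$f1, res$p_product, res$pos)
  res <- res[ord, , drop = FALSE]
  res[!duplicated(res[c("transcript_id", "f1")]), , drop = FALSE]
}

#' SNP concordance within exons and transcripts
#'
#' For groups (exons or transcripts) with at least two testable SNPs, reports
#' the mean pairwise Pearson correlation of the F1 allelic log2 ratios across
#' F1s, and the rate at which SNP pairs agree on the divergence class within
#' an F1.
#'
#' @param snp_results Long per-SNP per-F1 results.
#' @param group Column to group by (`"exon_id"` or `"transcript_id"`).
#' @return Data frame: group, n_snps, mean pairwise correlation, class
#'   agreement rate.
#' @export
snp_concordance <- function(snp_results, group = c("exon_id", "transcript_id")) {
  group <- match.arg(group)
  res <- snp_results[!is.na(snp_results$R_F1), , drop = FALSE]
  out <- lapply(split(res, res[[group]]), function(gdat) {
    snps <- unique(gdat$pos)
    if (length(snps) < 2L) return(NULL)
    wide_r <- tapply(gdat$R_F1, list(gdat$pos, gdat$f1), identity)
    cors <- stats::cor(t(wide_r), use = "pairwise.complete.obs")
    mean_cor <- mean(cors[upper.tri(cors)], na.rm = TRUE)
    wide_c <- tapply(gdat$class, list(gdat$pos, gdat$f1), identity)
    agree <- c()
    for (i in seq_len(nrow(wide_c) - 1L)) {
      for (j in seq(i + 1L, nrow(wide_c))) {
        cmp <- wide_c[i, ] == wide_c[j, ]
        agree <- c(agree, mean(cmp, na.rm = TRUE))
      }
    }
    data.frame(group = gdat[[group]][1L], n_snps = length(snps),
               mean_correlation = mean_cor,
               class_agreement = mean(agree, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Allele-specific expression classification pipeline
#'
#' Runs the full ASE analysis for one cross: informative-SNP selection,
#' coverage and monoallelic filters, size factors (median-of-ratios over the
#' per-SNP totals of all individuals, so tests are equally powered across
#' F1s), the bias-adjusted binomial ASE test, the parent-vs-parent binomial
#' test, Fisher's allele-ratio-vs-parental-ratio test, BH flags per (F1,
#' test) family at `fdr_level`, the decision table, and aggregation to one
#' call per transcript per F1.
#'
#' @param allele_counts Long allele-count table (see [read_allele_counts()]).
#' @param parent_calls Parental genotypes/depths (see
#'   [select_informative_snps()]).
#' @param transcripts Transcript models.
#' @param samples Sample table; parents need role `"parent"` with ecotype
#'   marine/freshwater, F1s role `"F1"`.
#' @param fdr_level BH FDR level per test family (default 0.10).
#' @param exclude_transcripts Transcript IDs to drop (e.g. sex-biased loci).
#' @param size_factors Optional named per-sample factors; estimated from the
#'   SNP totals when NULL.
#' @param mono_total,parent_tol Passed to [exclude_monoallelic()].
#' @param alternative Two-sidedness convention for the binomial tests.
#' @return List: `snp_results` (long per-SNP per-F1), `calls` (per transcript
#'   per F1), `p0` (per-F1 null ratios), `size_factors`, `informative`
#'   (retained SNP table), `filter_counts`.
#' @export
ase_classify <- function(allele_counts, parent_calls, transcripts, samples,
                         fdr_level = 0.10, exclude_transcripts = NULL,
                         size_factors = NULL, mono_total = 20,
                         parent_tol = 0.01, alternative = "minlike") {
  marine_id <- samples$sample_id[samples$role == "parent" &
                                   samples$ecotype == "marine"]
  fresh_id <- samples$sample_id[samples$role == "parent" &
                                  samples$ecotype == "freshwater"]
  f1_ids <- samples$sample_id[samples$role == "F1"]
  stopifnot(length(marine_id) == 1L, length(fresh_id) == 1L,
            length(f1_ids) >= 1L)

  info <- select_informative_snps(parent_calls, transcripts)
  n_info <- nrow(info)
  if (!is.null(exclude_transcripts))
    info <- info[!info$transcript_id %in% exclude_transcripts, , drop = FALSE]
  n_sex <- n_info - nrow(info)
  if (!nrow(info)) stop("no informative SNPs left")
  key <- paste(info$chrom, info$pos)

  mats <- allele_count_matrices(allele_counts, key)
  covered <- filter_expression_coverage(mats$total, f1_ids)
  kept <- exclude_monoallelic(mats$ref, mats$alt, f1_ids, info$marine_is_ref,
                              marine_id, fresh_id, mono_total, parent_tol)
  keep <- covered & kept
  info <- info[keep, , drop = FALSE]
  key <- key[keep]
  ref <- mats$ref[keep, , drop = FALSE]
  alt <- mats$alt[keep, , drop = FALSE]
  if (!nrow(info)) stop("no SNPs pass coverage/monoallelic filters")

  sf <- size_factors %||% estimate_size_factors(ref + alt)
  p0 <- vapply(f1_ids, function(j) estimate_null_ratio(ref, alt, j), 0)

  # parent test per SNP (shared across F1s)
  pM <- ref[, marine_id] + alt[, marine_id]
  pF <- ref[, fresh_id] + alt[, fresh_id]
  par_res <- parent_expression_test(pM, pF, sf[[marine_id]], sf[[fresh_id]],
                                    alternative)
  par_res$sig_parent <- bh_flags(par_res$p_parent, fdr_level)

  snp_results <- do.call(rbind, lapply(f1_ids, function(j) {
    f1_ref <- ref[, j]; f1_alt <- alt[, j]
    n <- f1_ref + f1_alt
    p_ase <- binomial_two_sided(f1_ref, n, p0[[j]], alternative)
    M <- ifelse(info$marine_is_ref, f1_ref, f1_alt)
    Fc <- ifelse(info$marine_is_ref, f1_alt, f1_ref)
    p_fisher <- fisher_ratio_test(M, Fc, pM, pF)
    data.frame(
      transcript_id = info$transcript_id, exon_id = info$exon_id,
      chrom = info$chrom, pos = info$pos, f1 = j,
      f1_M = M, f1_F = Fc, parent_M = pM, parent_F = pF,
      R_F1 = log2_ratio(M, Fc), R_P = par_res$R_P,
      p_parent = par_res$p_parent, p_ase = p_ase, p_fisher = p_fisher,
      sig_parent = par_res$sig_parent,
      sig_ase = bh_flags(p_ase, fdr_level),
      sig_fisher = bh_flags(p_fisher, fdr_level),
      stringsAsFactors = FALSE)
  }))
  snp_results$p_ase[snp_results$f1_M + snp_results$f1_F == 0] <- NA_real_
  snp_results$class <- classify_regulatory(
    snp_results$sig_parent, snp_results$sig_ase, snp_results$sig_fisher,
    snp_results$R_F1, snp_results$R_P)
  snp_results$class[is.na(snp_results$p_ase) | is.na(snp_results$p_parent) |
                      is.na(snp_results$p_fisher)] <- NA_character_

  calls <- aggregate_to_transcript(snp_results)
  calls$cis_mag <- calls$R_F1
  calls$trans_mag <- calls$R_P - calls$R_F1

  list(snp_results = snp_results, calls = calls, p0 = p0, size_factors = sf,
       informative = info,
       filter_counts = c(informative = n_info, sex_excluded = n_sex,
                         covered = sum(covered), post_monoallelic = sum(keep)))
}
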