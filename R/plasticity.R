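# Salinity-response profiling of F1 siblings and the stability of cis
# regulation (allele-specific ratios) across environments.

#' Per-transcript expression profiles relative to the across-sample mean
#'
#' Log2-scale expression (pseudocount 0.5) of each transcript in the subset,
#' centered on that transcript's mean across all samples, so a profile value
#' of +1 means the sample expresses the transcript twice as highly as the
#' average sample.
#'
#' @param expr Genes x samples matrix of normalized expression (FPKM or
#'   size-factor-scaled counts).
#' @param subset_ids Transcript IDs to profile (e.g. salinity-responsive
#'   parallel diverged loci); must be non-empty and present.
#' @return Transcripts x samples matrix of centered log2 profiles.
#' @export
expression_profiles <- function(expr, subset_ids) {
  if (length(subset_ids) == 0L) stop("empty transcript subset")
  missing_ids <- setdiff(subset_ids, rownames(expr))
  if (length(missing_ids)) stop("transcripts not in matrix: ",
                                paste(utils::head(missing_ids), collapse = ", "))
  lg <- log2(expr[subset_ids, , drop = FALSE] + 0.5)
  sweep(lg, 1L, rowMeans(lg), "-")
}

#' Sample similarity of expression profiles
#'
#' Pairwise Spearman correlation between sample profiles, plus a hierarchical
#' clustering order (Euclidean distance between profiles, complete linkage).
#'
#' @param profiles Transcripts x samples profile matrix.
#' @param linkage Hierarchical clustering linkage (default "complete").
#' @return List: `rho` (samples x samples Spearman matrix), `order` (sample
#'   IDs in dendrogram order), `hclust` (the tree).
#' @export
profile_correlation <- function(profiles, linkage = "complete") {
  rho <- stats::cor(profiles, method = "spearman")
  hc <- stats::hclust(stats::dist(t(profiles)), method = linkage)
  list(rho = rho, order = colnames(profiles)[hc$order], hclust = hc)
}

#' Stability of allele-specific ratios across environments
#'
#' Per SNP and sample, the log2 marine/freshwater allele fold-change
#' (pseudocount 0.5); sample similarity is the pairwise Spearman correlation
#' over SNPs of the chosen locus subset, with a hierarchical clustering order
#' (Euclidean, complete linkage) of samples. Since the allelic ratio isolates
#' cis regulation, clustering that does not group samples by environment
#' indicates environment-insensitive cis control.
#'
#' @param allele_counts Long allele-count table (F1 samples only or mixed;
#'   restricted via `sample_ids`).
#' @param snp_truth SNP table with chrom, pos, transcript_id and
#'   `marine_is_ref`.
#' @param subset_ids Transcript IDs to keep.
#' @param sample_ids Samples to include (exclusion lists applied upstream).
#' @param linkage Clustering linkage (default "complete").
#' @return List: `ratios` (SNPs x samples log2 allele fold-changes), `rho`,
#'   `order`, `hclust`.
#' @export
ase_stability <- function(allele_counts, snp_truth, subset_ids, sample_ids,
                          linkage = "complete") {
  snp <- snp_truth[snp_truth$transcript_id %in% subset_ids, , drop = FALSE]
  if (!nrow(snp)) stop("no SNPs in locus subset")
  key <- paste(snp$chrom, snp$pos)
  ac <- allele_counts[allele_counts$sample %in% sample_ids, , drop = FALSE]
  mats <- allele_count_matrices(ac, key)
  M <- ifelse(matrix(snp$marine_is_ref, nrow(mats$ref), ncol(mats$ref)),
              mats$ref, mats$alt)
  Fc <- mats$ref + mats$alt - M
  ratios <- log2_ratio(M, Fc)
  dimnames(ratios) <- dimnames(mats$ref)
  if (nrow(ratios) < 2L) stop("need >= 2 SNPs to correlate samples")
  rho <- stats::cor(ratios, method = "spearman")
  hc <- stats::hclust(stats::dist(t(ratios)), method = linkage)
  list(ratios = ratios, rho = rho, order = colnames(ratios)[hc$order],
       hclust = hc)
}
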