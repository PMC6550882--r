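# Composite principal-component statistic for parallel expression divergence:
# median-of-ratios size factors, a log variance-stabilization, covariance PCA
# on a balanced core sample set, identification of ecotype-separating PCs,
# PVE-weighted composite loadings, outlier selection and a label-permutation
# FDR computed gene-by-gene via rank-2 updates of the sample Gram matrix.

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: the median across genes of the ratio of a
#' sample's count to the gene's geometric mean, computed over genes with a
#' positive geometric mean (the median-of-ratios estimator used for RNA-seq
#' library normalization).
#'
#' @param counts Numeric matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene with nonzero counts in all samples")
  apply(counts, 2L, function(x) exp(stats::median(log(x[use]) - log_geo[use])))
}

#' Variance-stabilizing transform (shifted log)
#'
#' `log2(count / size_factor + 1)`: monotone in counts, zero at zero, and
#' approximately variance-stabilizing for overdispersed counts.
#'
#' @param counts Genes x samples matrix.
#' @param size_factors Per-sample positive scalars (default: estimated).
#' @return Real matrix of the same shape.
#' @export
variance_stabilize <- function(counts, size_factors = NULL) {
  sf <- size_factors %||% estimate_size_factors(counts)
  stopifnot(length(sf) == ncol(counts), all(sf > 0))
  log2(sweep(counts, 2L, sf, "/") + 1)
}

#' Covariance PCA of expression profiles
#'
#' Unscaled (covariance) PCA of samples over all transcripts. Loadings carry
#' a deterministic sign convention (largest-magnitude element positive), so
#' results are invariant to sample order.
#'
#' @param mat Variance-stabilized matrix, genes x samples.
#' @param core_samples Character vector of sample IDs forming the balanced
#'   core set (>= 3).
#' @return List: `scores` (samples x PCs), `loadings` (genes x PCs), `pve`
#'   (fractions summing to 1), `center` (per-gene means), `sdev`,
#'   `core_samples`.
#' @export
run_pca <- function(mat, core_samples = colnames(mat)) {
  stopifnot(all(core_samples %in% colnames(mat)))
  if (length(core_samples) < 3L) stop("need >= 3 core samples")
  x <- t(mat[, core_samples, drop = FALSE])
  if (all(apply(x, 2L, stats::sd) == 0)) stop("constant matrix: no variance for PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) {
    s <- sign(v[which.max(abs(v))]); if (s == 0) 1 else s
  })
  list(scores = sweep(pc$x, 2L, flip, "*"),
       loadings = sweep(pc$rotation, 2L, flip, "*"),
       pve = pc$sdev^2 / sum(pc$sdev^2),
       center = pc$center, sdev = pc$sdev,
       core_samples = core_samples)
}

#' Identify ecotype-separating principal components
#'
#' Returns the `k` PCs whose sample scores have the largest absolute
#' point-biserial correlation with the ecotype label, ordered by PC index.
#'
#' @param scores Samples x PCs score matrix.
#' @param ecotype Character/factor vector of two labels, aligned to rows.
#' @param k Number of components to select.
#' @return Integer vector of PC indices (sorted ascending).
#' @export
identify_ecotype_pcs <- function(scores, ecotype, k = 2L) {
  if (k > ncol(scores)) stop("k exceeds the number of available PCs")
  y <- as.numeric(factor(ecotype))
  if (length(unique(y)) != 2L) stop("need exactly two ecotype labels")
  sds <- apply(scores, 2L, stats::sd)
  r <- abs(vapply(seq_len(ncol(scores)), function(i) {
    # degenerate axes (numerically zero variance) carry no signal
    if (sds[i] <= max(sds) * 1e-8) return(0)
    stats::cor(scores[, i], y)
  }, 0))
  sort(order(r, decreasing = TRUE)[seq_len(k)])
}

#' Orientation signs for chosen PCs
#'
#' Fixes each chosen PC's sign so the marine mean score exceeds the
#' freshwater mean score (marine-positive convention).
#'
#' @param scores Samples x PCs score matrix (core samples).
#' @param ecotype Ecotype labels aligned to rows ("marine"/"freshwater").
#' @param pc_indices PCs to orient.
#' @return Named vector of +/-1 per chosen PC.
#' @export
orient_ecotype_pcs <- function(scores, ecotype, pc_indices) {
  m <- colMeans(scores[ecotype == "marine", pc_indices, drop = FALSE])
  f <- colMeans(scores[ecotype == "freshwater", pc_indices, drop = FALSE])
  s <- ifelse(m >= f, 1, -1)
  names(s) <- colnames(scores)[pc_indices]
  s
}

#' Composite PC loadings
#'
#' Per-transcript composite loading `L_g = sum_i w_i * s_i * l_{g,i}` over the
#' chosen ecotype-separating PCs, with PVE fractions `w_i` as weights and
#' orientation signs `s_i` enforcing the marine-positive convention.
#'
#' @param loadings Genes x PCs loading matrix.
#' @param pve PVE fractions per PC.
#' @param pc_indices Chosen PC indices.
#' @param orientation Vector of +/-1, one per chosen PC.
#' @return Named numeric vector of composite loadings.
#' @export
composite_loadings <- function(loadings, pve, pc_indices, orientation = NULL) {
  orientation <- orientation %||% rep(1, length(pc_indices))
  stopifnot(length(orientation) == length(pc_indices))
  drop(loadings[, pc_indices, drop = FALSE] %*%
         (pve[pc_indices] * orientation))
}

#' Project held-out samples onto an existing PCA
#'
#' Centers new profiles with the core set's per-gene means and projects onto
#' the core loadings; projecting a core sample reproduces its own score.
#'
#' @param new_mat Variance-stabilized matrix (genes x new samples), same gene
#'   order as the PCA input.
#' @param pca Result of [run_pca()].
#' @return New-samples x PCs score matrix.
#' @export
project_samples <- function(new_mat, pca) {
  x <- sweep(t(new_mat), 2L, pca$center, "-")
  x %*% pca$loadings
}

#' Select parallel diverged loci (composite-loading tails)
#'
#' Union of the lower and upper `quantile` tails of the composite loading,
#' with ties broken by transcript ID for determinism.
#'
#' @param L Named composite-loading vector.
#' @param quantile Tail fraction per side (default 0.01).
#' @return Character vector of outlier transcript IDs.
#' @export
select_parallel_loci <- function(L, quantile = 0.01) {
  n <- length(L)
  n_tail <- round(quantile * n)
  if (length(unique(L)) == 1L) {
    warning("degenerate composite loadings: all values equal")
    if (quantile < 0.5) return(character(0))
  }
  ord <- order(L, names(L))
  ids <- names(L)[ord]
  unique(c(utils::head(ids, n_tail), utils::tail(ids, n_tail)))
}

#' Number of unordered balanced label splits
#'
#' Distinct ways of splitting `n` samples into two unordered groups of sizes
#' `k` and `n - k` (halved when the groups are equal-sized, since group
#' identity is exchangeable under the null).
#'
#' @param n Total samples.
#' @param k Size of one group.
#' @return Count of distinct splits.
#' @export
n_label_splits <- function(n, k) {
  if (2L * k == n) choose(n, k) / 2 else choose(n, k)
}

# enumerate splits as a logical matrix (n_splits x n), TRUE = pseudo-marine.
# For equal group sizes, sample 1 is anchored to the pseudo-marine group so
# each unordered split appears exactly once (the identity split is included).
enumerate_splits <- function(n, k) {
  if (2L * k == n) {
    sub <- utils::combn(n - 1L, k - 1L)
    m <- matrix(FALSE, ncol(sub), n)
    m[, 1L] <- TRUE
    for (j in seq_len(ncol(sub))) m[j, sub[, j] + 1L] <- TRUE
  } else {
    sub <- utils::combn(n, k)
    m <- matrix(FALSE, ncol(sub), n)
    for (j in seq_len(ncol(sub))) m[j, sub[, j]] <- TRUE
  }
  m
}

#' Label-permutation FDR for composite-PC outliers
#'
#' For each outlier gene, the sample labels are shuffled for that gene alone
#' (all other data kept as observed): for every balanced split of the core
#' samples into two pseudo-ecotype groups, the gene's values observed in
#' marine samples are reassigned to the pseudo-marine positions and the PCA
#' and composite loading are recalculated. The full PCA recomputation uses a
#' rank-2 update of the sample Gram matrix, so each permutation costs one
#' small eigendecomposition. Splits are enumerated exhaustively when their
#' number is at most `max_perms`, otherwise subsampled without replacement
#' independently per gene (identity split always retained), keeping null
#' p-values independent across genes.
#'
#' Two one-sided p-values are reported per gene: `p`, a normal-approximation
#' p in the direction of the observed loading's sign (used for the BH
#' correction), and `p_upper`, the empirical probability over the enumerated
#' splits of a loading at least as high as the observed one (the fixed
#' upper-tail permutation p; for null genes it is uniform by exchangeability,
#' making it the natural calibration quantity).
#'
#' @param mat Variance-stabilized matrix, genes x samples.
#' @param samples Sample table with `sample_id` and `ecotype`.
#' @param outliers Character vector of transcript IDs to test.
#' @param pca Result of [run_pca()] on the core set.
#' @param pc_indices Ecotype-separating PC indices (reused for every
#'   permutation unless `reidentify = TRUE`).
#' @param k Number of PCs re-identified per permutation when
#'   `reidentify = TRUE`.
#' @param reidentify Re-identify ecotype-separating PCs per permutation by
#'   point-biserial correlation with the pseudo-labels (default FALSE:
#'   observed indices are reused).
#' @param max_perms Enumeration cap (default 6435 = unordered splits of 16
#'   into 8 + 8).
#' @param seed Seed for split subsampling.
#' @return Data frame: transcript_id, observed L, null mean/sd, Z, p,
#'   p_upper, q (BH across outliers), n_perms, degenerate flag.
#' @export
permutation_fdr <- function(mat, samples, outliers, pca,
                            pc_indices, k = length(pc_indices),
                            reidentify = FALSE,
                            max_perms = 6435, seed = NULL) {
  core <- pca$core_samples
  eco <- samples$ecotype[match(core, samples$sample_id)]
  stopifnot(all(eco %in% c("marine", "freshwater")))
  n <- length(core)
  n_marine <- sum(eco == "marine")
  is_marine <- eco == "marine"

  X <- t(mat[, core, drop = FALSE])      # samples x genes
  X <- sweep(X, 2L, colMeans(X), "-")
  G <- tcrossprod(X)                     # n x n Gram matrix

  all_splits <- enumerate_splits(n, n_marine)
  total_splits <- nrow(all_splits)
  id_row <- which(apply(all_splits, 1L, function(s) all(s == is_marine)))
  if (!length(id_row)) {                   # unequal groups: identity present
    all_splits <- rbind(is_marine, all_splits)
    id_row <- 1L
    total_splits <- total_splits + 1L
  }
  if (!is.null(seed)) set.seed(seed)

  marine_idx <- which(is_marine)
  fresh_idx <- which(!is_marine)
  y_base <- numeric(n)

  res <- lapply(outliers, function(g) {
    # subsample splits per gene (always keeping the identity relabeling) so
    # null p-values are independent across genes
    if (total_splits > max_perms) {
      rows <- sample.int(total_splits, max_perms)
      if (!id_row %in% rows) rows[1L] <- id_row
      splits <- all_splits[rows, , drop = FALSE]
    } else {
      splits <- all_splits
    }
    n_perm <- nrow(splits)
    x <- X[, g]
    G0 <- G - tcrossprod(x)
    Lnull <- numeric(n_perm)
    obs <- NA_real_
    for (i in seq_len(n_perm)) {
      pm <- which(splits[i, ])
      pf <- which(!splits[i, ])
      y <- y_base
      y[pm] <- x[marine_idx]
      y[pf] <- x[fresh_idx]
      e <- eigen(G0 + tcrossprod(y), symmetric = TRUE)
      lam <- pmax(e$values, 0)
      idx <- pc_indices
      if (reidentify) {
        lbl <- as.numeric(splits[i, ])
        d_all <- sqrt(lam)
        sc <- sweep(e$vectors, 2L, d_all, "*")
        r <- abs(apply(sc, 2L, function(s)
          if (stats::sd(s) == 0) 0 else stats::cor(s, lbl)))
        idx <- sort(order(r, decreasing = TRUE)[seq_len(k)])
      }
      d <- sqrt(lam[idx])
      valid <- d > 0                           # degenerate axes contribute 0
      idx_v <- idx[valid]
      if (any(valid)) {
        u <- e$vectors[, idx_v, drop = FALSE]
        l <- drop(crossprod(u, y)) / d[valid]
        sc_m <- colSums(u[pm, , drop = FALSE]) / length(pm)
        sc_f <- colSums(u[pf, , drop = FALSE]) / length(pf)
        s <- ifelse((sc_m - sc_f) >= 0, 1, -1) # d > 0 cancels in the sign
        w <- lam[idx_v] / sum(lam)
        Lnull[i] <- sum(w * s * l)
      }
      if (all(splits[i, ] == is_marine)) obs <- Lnull[i]
    }
    mu <- mean(Lnull); sdev <- stats::sd(Lnull)
    if (is.na(sdev) || sdev == 0) {
      data.frame(transcript_id = g, L = obs, null_mean = mu, null_sd = sdev,
                 Z = NA_real_, p = 1, p_upper = 1, n_perms = n_perm,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      z <- (obs - mu) / sdev
      p_dir <- if (obs >= 0) stats::pnorm(z, lower.tail = FALSE)
               else stats::pnorm(z)
      # empirical upper tail over the enumerated splits (identity included),
      # exactly uniform for null genes by exchangeability
      p_up <- mean(Lnull >= obs)
      data.frame(transcript_id = g, L = obs, null_mean = mu, null_sd = sdev,
                 Z = z, p = p_dir, p_upper = p_up, n_perms = n_perm,
                 degenerate = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Composite-PC analysis pipeline
#'
#' Runs size-factor estimation, variance stabilization, covariance PCA on the
#' balanced core set, ecotype-PC identification, composite loadings,
#' held-out-sample projection, outlier selection and (optionally) the
#' permutation FDR for the outliers.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Sample table (`sample_id`, `ecotype`, `river`).
#' @param core_samples Sample IDs of the balanced core set; default all
#'   marine/freshwater samples.
#' @param k Number of ecotype-separating PCs (default 2).
#' @param quantile Outlier tail fraction (default 0.01).
#' @param fdr Run the permutation FDR for the outliers (slow for many
#'   outliers).
#' @param max_perms,seed Passed to [permutation_fdr()].
#' @return List with `size_factors`, `vst`, `pca`, `pc_indices`,
#'   `orientation`, `L` (composite loadings), `outliers`, `projected` (scores
#'   of non-core samples), and `fdr` (data frame or NULL).
#' @export
composite_pc <- function(counts, samples, core_samples = NULL, k = 2L,
                         quantile = 0.01, fdr = FALSE, max_perms = 6435,
                         seed = NULL) {
  sf <- estimate_size_factors(counts)
  vst <- variance_stabilize(counts, sf)
  core <- core_samples %||%
    samples$sample_id[samples$ecotype %in% c("marine", "freshwater")]
  pca <- run_pca(vst, core)
  eco <- samples$ecotype[match(core, samples$sample_id)]
  idx <- identify_ecotype_pcs(pca$scores, eco, k)
  ori <- orient_ecotype_pcs(pca$scores, eco, idx)
  L <- composite_loadings(pca$loadings, pca$pve, idx, ori)
  names(L) <- rownames(counts)
  outliers <- select_parallel_loci(L, quantile)
  held_out <- setdiff(colnames(counts), core)
  projected <- if (length(held_out)) {
    project_samples(vst[, held_out, drop = FALSE], pca)
  } else NULL
  fdr_res <- if (isTRUE(fdr)) {
    permutation_fdr(vst, samples, outliers, pca, idx,
                    max_perms = max_perms, seed = seed)
  } else NULL
  list(size_factors = sf, vst = vst, pca = pca, pc_indices = idx,
       orientation = ori, L = L, outliers = outliers, projected = projected,
       fdr = fdr_res)
}
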