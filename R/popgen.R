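# Population-genetic signatures of selection: per-site Weir-Cockerham FST and
# nucleotide diversity with missing-genotype caps, cluster separation score
# (CSS) in non-overlapping windows with top-1% outliers, TSS-centered
# sliding-window profiles, and the transcript-to-outlier-window proximity
# randomization.

#' Per-site Weir-Cockerham FST for two populations
#'
#' Variance-components estimator (theta-hat) for biallelic sites scored on
#' diploid genotypes, using the observed heterozygosity correction. Negative
#' estimates are clamped to zero. Sites that are monomorphic across both
#' populations, or exceed the missing-genotype cap, are `NA`.
#'
#' @param geno Sites x individuals matrix of alternate-allele dosages
#'   (0/1/2, `NA` missing).
#' @param ecotype Population labels per column (exactly two levels).
#' @param max_missing Maximum missing genotypes per site (default 4; beyond
#'   the cap the site is skipped rather than computed on reduced n).
#' @param clamp Clamp negative estimates to 0 (default TRUE).
#' @return Numeric vector of per-site FST.
#' @export
fst_weir_cockerham <- function(geno, ecotype, max_missing = 4, clamp = TRUE) {
  pops <- unique(ecotype)
  stopifnot(length(pops) == 2L, ncol(geno) == length(ecotype))
  g1 <- geno[, ecotype == pops[1L], drop = FALSE]
  g2 <- geno[, ecotype == pops[2L], drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  miss <- (ncol(g1) - n1) + (ncol(g2) - n2)
  p1 <- rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  fst <- a / denom
  fst[denom == 0] <- NA_real_                   # monomorphic: undefined
  fst[miss > max_missing] <- NA_real_
  fst[n1 < 1 | n2 < 1] <- NA_real_
  if (clamp) fst <- pmax(fst, 0)
  fst
}

#' Per-site nucleotide diversity within one population
#'
#' Average pairwise difference per site: `Pi = j(n-j) / C(n,2)` over the `n`
#' non-missing haploid alleles with `j` alternate copies (equivalently
#' `2j(n-j)/(n(n-1))`). Sites exceeding the missing-genotype cap are `NA`.
#'
#' @param geno Sites x individuals dosage matrix for one population.
#' @param max_missing Maximum missing genotypes per site (default 2).
#' @return Numeric vector of per-site Pi in \[0,1\].
#' @export
pi_per_site <- function(geno, max_missing = 2) {
  n_ind <- rowSums(!is.na(geno))
  miss <- ncol(geno) - n_ind
  n <- 2 * n_ind
  j <- rowSums(geno, na.rm = TRUE)
  pi <- 2 * j * (n - j) / (n * (n - 1))
  pi[n < 2] <- NA_real_
  pi[miss > max_missing] <- NA_real_
  pi
}

#' Per-site statistics table (FST and per-ecotype Pi)
#'
#' @param geno Sites x individuals dosage matrix.
#' @param sites Data frame with chrom, pos aligned to rows.
#' @param ecotype Labels per column (two populations).
#' @param max_missing_fst,max_missing_pi Missing caps per statistic.
#' @return Data frame: chrom, pos, fst, pi_<pop1>, pi_<pop2>, n_missing.
#' @export
site_stats <- function(geno, sites, ecotype, max_missing_fst = 4,
                       max_missing_pi = 2) {
  pops <- unique(ecotype)
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    fst = fst_weir_cockerham(geno, ecotype, max_missing_fst),
                    stringsAsFactors = FALSE)
  for (p in pops) {
    out[[paste0("pi_", p)]] <-
      pi_per_site(geno[, ecotype == p, drop = FALSE], max_missing_pi)
  }
  out$n_missing <- rowSums(is.na(geno))
  out
}

#' Cluster separation score (CSS) in non-overlapping windows
#'
#' Per window: the pairwise distance between individuals is the average
#' per-site allele-sharing difference (`|g_i - g_j| / 2` over sites where
#' both are scored); individuals are embedded by 2-D metric multidimensional
#' scaling of this matrix; CSS contrasts the mean between-ecotype Euclidean
#' distance in the embedding with the within-ecotype means. `css_raw`
#' subtracts the unweighted average of the two within-ecotype means;
#' `css_norm` subtracts the group-size-weighted average (the size
#' normalization of the cluster-separation scheme). Outliers are the top
#' `top_frac` windows by the configured score.
#'
#' @param geno Sites x individuals dosage matrix.
#' @param sites Data frame with chrom, pos.
#' @param ecotype Labels per column.
#' @param window Window size in bp (default 10 kb, non-overlapping).
#' @param top_frac Outlier fraction (default 0.01).
#' @param rank_by `"css_raw"` (default) or `"css_norm"`.
#' @param min_sites Minimum scored sites per window (default 3).
#' @return Data frame: chrom, start, end, n_sites, css_raw, css_norm,
#'   outlier flag.
#' @export
css_windows <- function(geno, sites, ecotype, window = 1e4, top_frac = 0.01,
                        rank_by = c("css_raw", "css_norm"), min_sites = 3L) {
  rank_by <- match.arg(rank_by)
  pops <- unique(ecotype)
  stopifnot(length(pops) == 2L)
  out <- list()
  for (chrom in unique(sites$chrom)) {
    on_chr <- sites$chrom == chrom
    pos <- sites$pos[on_chr]
    g <- geno[on_chr, , drop = FALSE]
    win_id <- (pos - 1L) %/% window
    for (wid in sort(unique(win_id))) {
      rows <- win_id == wid
      res <- data.frame(chrom = chrom, start = wid * window + 1,
                        end = (wid + 1) * window, n_sites = sum(rows),
                        css_raw = NA_real_, css_norm = NA_real_,
                        stringsAsFactors = FALSE)
      if (sum(rows) >= min_sites) {
        gw <- g[rows, , drop = FALSE]
        css <- css_from_genotypes(gw, ecotype == pops[1L])
        res$css_raw <- css["raw"]; res$css_norm <- css["norm"]
      }
      out[[length(out) + 1L]] <- res
    }
  }
  res <- do.call(rbind, out)
  score <- res[[rank_by]]
  n_out <- max(1L, floor(top_frac * sum(!is.na(score))))
  cut <- sort(score, decreasing = TRUE)[n_out]
  res$outlier <- !is.na(score) & score >= cut
  rownames(res) <- NULL
  res
}

# CSS for one window: allele-difference distance matrix -> 2-D MDS ->
# between- minus within-ecotype mean distances (raw and size-normalized)
css_from_genotypes <- function(gw, in_pop1) {
  n_ind <- ncol(gw)
  D <- matrix(0, n_ind, n_ind)
  for (i in seq_len(n_ind - 1L)) {
    for (j in seq(i + 1L, n_ind)) {
      d <- abs(gw[, i] - gw[, j]) / 2
      D[i, j] <- D[j, i] <- mean(d, na.rm = TRUE)
    }
  }
  D[is.nan(D)] <- 0
  css_from_distances(D, in_pop1)
}

#' CSS from a precomputed distance matrix
#'
#' @param D Symmetric individual x individual distance matrix.
#' @param in_pop1 Logical vector: TRUE for individuals of the first ecotype.
#' @return Named vector with `raw` and `norm` CSS variants.
#' @export
css_from_distances <- function(D, in_pop1) {
  k <- min(2L, nrow(D) - 1L)
  mds <- suppressWarnings(stats::cmdscale(D, k = k))
  E <- as.matrix(stats::dist(mds))
  m <- sum(in_pop1); n <- sum(!in_pop1)
  between <- E[in_pop1, !in_pop1, drop = FALSE]
  w1 <- E[in_pop1, in_pop1, drop = FALSE]
  w2 <- E[!in_pop1, !in_pop1, drop = FALSE]
  mean_b <- mean(between)
  mean_w1 <- if (m > 1) mean(w1[upper.tri(w1)]) else 0
  mean_w2 <- if (n > 1) mean(w2[upper.tri(w2)]) else 0
  c(raw = mean_b - (mean_w1 + mean_w2) / 2,
    norm = mean_b - (m * mean_w1 + n * mean_w2) / (m + n))
}

#' TSS-centered sliding-window profiles of site statistics
#'
#' For each transcript, per-site statistics are averaged in `window`-bp bins
#' tiling a `span`-bp region centered on the TSS; offsets are strand-oriented
#' (upstream negative). Profiles are then averaged across the transcripts of
#' each group (e.g. parallel diverged vs control loci), with the standard
#' error of the mean.
#'
#' @param stats_df Output of [site_stats()] (or any data frame with chrom,
#'   pos and numeric statistic columns).
#' @param transcripts Transcript models with tss and strand.
#' @param groups Named character vector or list: group label per
#'   transcript_id (transcripts absent from `groups` are skipped).
#' @param stat_cols Statistic columns to profile (default: all numeric except
#'   pos).
#' @param span Total profiled width in bp (default 400 kb).
#' @param window Bin width in bp (default 1 kb).
#' @return Long data frame: group, stat, offset (bin center, bp), mean, sem,
#'   n_loci.
#' @export
tss_profiles <- function(stats_df, transcripts, groups, stat_cols = NULL,
                         span = 4e5, window = 1e3) {
  stat_cols <- stat_cols %||%
    setdiff(names(stats_df)[vapply(stats_df, is.numeric, TRUE)],
            c("pos", "n_missing"))
  groups <- unlist(groups)
  tr <- transcripts[transcripts$transcript_id %in% names(groups), , drop = FALSE]
  half <- span / 2
  n_bins <- ceiling(span / window)
  bin_centers <- -half + (seq_len(n_bins) - 0.5) * window

  # per-transcript per-bin means: loci x bins per statistic
  per_tr <- lapply(stat_cols, function(s) {
    matrix(NA_real_, nrow(tr), n_bins,
           dimnames = list(tr$transcript_id, NULL))
  })
  names(per_tr) <- stat_cols
  for (i in seq_len(nrow(tr))) {
    on_chr <- stats_df$chrom == tr$chrom[i]
    rel <- stats_df$pos[on_chr] - tr$tss[i]
    if (tr$strand[i] == "-") rel <- -rel
    inside <- rel >= -half & rel < half
    if (!any(inside)) next
    bin <- floor((rel[inside] + half) / window) + 1L
    for (s in stat_cols) {
      v <- stats_df[[s]][on_chr][inside]
      mt <- tapply(v, bin, mean, na.rm = TRUE)
      per_tr[[s]][i, as.integer(names(mt))] <- mt
    }
  }
  out <- list()
  for (grp in unique(groups)) {
    ids <- names(groups)[groups == grp]
    for (s in stat_cols) {
      m <- per_tr[[s]][rownames(per_tr[[s]]) %in% ids, , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        group = grp, stat = s, offset = bin_centers,
        mean = apply(m, 2L, mean, na.rm = TRUE),
        sem = apply(m, 2L, sem),
        n_loci = apply(m, 2L, function(x) sum(!is.na(x))),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$mean[is.nan(res$mean)] <- NA_real_
  rownames(res) <- NULL
  res
}

#' Proximity randomization of transcripts to outlier windows
#'
#' Compares the cumulative proportion of focal transcripts lying within
#' increasing distances of the nearest outlier window against `n_random`
#' equally sized random transcript sets drawn from the pool. The distance
#' between a transcript and a window is 0 when they overlap, otherwise the
#' gap between nearest edges (transcript span, not TSS).
#'
#' @param transcripts Transcript models (pool; must include the focal set).
#' @param outlier_windows Data frame with chrom, start, end (e.g. CSS
#'   outliers).
#' @param focal_ids Transcript IDs of the focal (e.g. parallel diverged) set.
#' @param increments Distance step in bp (default 10 kb).
#' @param max_dist Largest distance evaluated (default 20 increments).
#' @param n_random Number of random sets (default 1000).
#' @param seed RNG seed.
#' @return Data frame: distance, observed cumulative proportion, null mean
#'   and 95% band (2.5/97.5 percentiles).
#' @export
proximity_randomization <- function(transcripts, outlier_windows, focal_ids,
                                    increments = 1e4, max_dist = 20 * increments,
                                    n_random = 1000, seed = NULL) {
  if (is.null(outlier_windows) || !nrow(outlier_windows))
    stop("no outlier windows supplied")
  if (!is.null(seed)) set.seed(seed)
  tx <- transcripts_to_granges(transcripts)
  win <- GenomicRanges::GRanges(outlier_windows$chrom,
                                IRanges::IRanges(outlier_windows$start,
                                                 outlier_windows$end))
  hit <- GenomicRanges::distanceToNearest(tx, win, ignore.strand = TRUE)
  dist <- rep(Inf, length(tx))
  dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  names(dist) <- transcripts$transcript_id

  breaks <- seq(0, max_dist, by = increments)
  ecdf_at <- function(d) vapply(breaks, function(b) mean(d <= b), 0)
  obs <- ecdf_at(dist[focal_ids])
  pool <- names(dist)
  n_focal <- length(focal_ids)
  null <- matrix(0, n_random, length(breaks))
  for (r in seq_len(n_random)) {
    null[r, ] <- ecdf_at(dist[sample(pool, n_focal)])
  }
  data.frame(distance = breaks, observed = obs,
             null_mean = colMeans(null),
             null_lo = apply(null, 2L, stats::quantile, 0.025),
             null_hi = apply(null, 2L, stats::quantile, 0.975),
             stringsAsFactors = FALSE)
}
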