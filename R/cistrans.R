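# Quantitative cis/trans architecture: per-locus magnitudes averaged over
# F1s, dominance/additivity of expression inheritance, sibling sharing of
# regulatory classes, cross-river parallelism correlations with sliding
# thresholds, and effect-size bins along the composite-PC axis.

#' Per-locus cis and trans divergence, averaged over F1s
#'
#' Cis divergence of a locus in one F1 is the F1 allele-specific log2 ratio
#' (`R_F1`); trans divergence is the parental log2 ratio minus it
#' (`R_P - R_F1`). Both are averaged across the available F1s of a cross, so
#' `mean_cis + mean_trans` equals the mean parental log2 ratio exactly.
#'
#' @param calls Per-transcript per-F1 calls (from [ase_classify()]).
#' @param river Optional river label to attach.
#' @return Data frame: transcript_id, river, n_f1, mean_cis, mean_trans,
#'   mean_R_P.
#' @export
locus_cis_trans <- function(calls, river = NA_character_) {
  sp <- split(calls, calls$transcript_id)
  out <- lapply(sp, function(d) {
    data.frame(transcript_id = d$transcript_id[1L], river = river,
               n_f1 = nrow(d),
               mean_cis = mean(d$cis_mag),
               mean_trans = mean(d$trans_mag),
               mean_R_P = mean(d$R_P),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Dominance/additivity ratio of F1 expression
#'
#' `d/a` with `a = (P_high - P_low) / 2` (half the parental difference) and
#' `d = F1 - midparent`, signed toward the high parent: 0 means additive,
#' +1/-1 full dominance of the high/low parent, and values beyond 1 in
#' magnitude over- or underdominance. Loci with equal parental values are
#' skipped (ratio undefined) and flagged.
#'
#' @param parent_high,parent_low Normalized parental expression (the higher
#'   and lower parent; any orientation is accepted and sorted internally).
#' @param f1 Normalized F1 expression.
#' @return Data frame with `ratio` and `defined` flag.
#' @export
dominance_additivity <- function(parent_high, parent_low, f1) {
  m <- max(length(parent_high), length(parent_low), length(f1))
  parent_high <- rep_len(parent_high, m)
  parent_low <- rep_len(parent_low, m)
  f1 <- rep_len(f1, m)
  hi <- pmax(parent_high, parent_low)
  lo <- pmin(parent_high, parent_low)
  a <- (hi - lo) / 2
  mid <- (hi + lo) / 2
  defined <- a > 0
  ratio <- ifelse(defined, (f1 - mid) / a, NA_real_)
  data.frame(ratio = ratio, defined = defined)
}

#' Sharing of regulatory classes between F1 siblings
#'
#' For each class and each sibling pair, the percentage of loci called that
#' class in both siblings out of loci called that class in either, restricted
#' to loci testable (called) in both siblings — a proxy for how much each
#' regulatory mode depends on genetic background (epistasis).
#'
#' @param calls Per-transcript per-F1 calls.
#' @param classes Classes to report (default all except ambiguous).
#' @return Data frame: class, f1_a, f1_b, n_both_testable, shared_pct.
#' @export
sibling_sharing <- function(calls, classes = setdiff(regulatory_classes(),
                                                     "ambiguous")) {
  f1s <- sort(unique(calls$f1))
  out <- list()
  for (i in seq_along(f1s)) {
    for (j in seq_along(f1s)) {
      if (j <= i) next
      a <- calls[calls$f1 == f1s[i], c("transcript_id", "class")]
      b <- calls[calls$f1 == f1s[j], c("transcript_id", "class")]
      common <- intersect(a$transcript_id, b$transcript_id)
      a <- a[match(common, a$transcript_id), ]
      b <- b[match(common, b$transcript_id), ]
      for (cl in classes) {
        in_a <- a$transcript_id[a$class == cl]
        in_b <- b$transcript_id[b$class == cl]
        either <- union(in_a, in_b)
        both <- intersect(in_a, in_b)
        out[[length(out) + 1L]] <- data.frame(
          class = cl, f1_a = f1s[i], f1_b = f1s[j],
          n_both_testable = length(common),
          shared_pct = if (length(either)) 100 * length(both) / length(either)
                       else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Cross-river parallelism of cis/trans magnitudes at sliding thresholds
#'
#' For nested subsets of loci defined by increasingly extreme composite-PC
#' loadings (separately for the negative, freshwater-upregulated, and
#' positive tails), computes the Pearson correlation between river pairs of
#' the per-locus mean cis (or trans) divergence. Subsets with fewer than
#' `min_loci` shared loci are reported as `NA`.
#'
#' @param divergence Named list of [locus_cis_trans()] tables, one per river.
#' @param L Named composite-loading vector (shared across rivers).
#' @param thresholds Tail quantiles (fractions) defining the nested subsets.
#' @param value `"mean_cis"` or `"mean_trans"`.
#' @param min_loci Minimum loci per subset (default 5).
#' @return Data frame: river_a, river_b, tail, threshold, n_loci, r.
#' @export
parallelism_correlation <- function(divergence, L,
                                    thresholds = c(0.5, 0.25, 0.1, 0.05,
                                                   0.025, 0.01),
                                    value = c("mean_cis", "mean_trans"),
                                    min_loci = 5L) {
  value <- match.arg(value)
  rivers <- names(divergence)
  stopifnot(length(rivers) >= 2L)
  out <- list()
  for (i in seq_along(rivers)) {
    for (j in seq_along(rivers)) {
      if (j <= i) next
      a <- divergence[[i]]; b <- divergence[[j]]
      common <- intersect(a$transcript_id, b$transcript_id)
      common <- common[common %in% names(L)]
      va <- a[[value]][match(common, a$transcript_id)]
      vb <- b[[value]][match(common, b$transcript_id)]
      Lc <- L[common]
      for (tail in c("negative", "positive")) {
        for (q in thresholds) {
          cut <- stats::quantile(L, if (tail == "negative") q else 1 - q)
          sel <- if (tail == "negative") Lc <= cut else Lc >= cut
          n <- sum(sel)
          r <- if (n >= min_loci && stats::sd(va[sel]) > 0 &&
                   stats::sd(vb[sel]) > 0) {
            stats::cor(va[sel], vb[sel])
          } else NA_real_
          out[[length(out) + 1L]] <- data.frame(
            river_a = rivers[i], river_b = rivers[j], tail = tail,
            threshold = q, n_loci = n, r = r, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Mean absolute cis/trans magnitude in composite-loading bins
#'
#' @param divergence Named list of [locus_cis_trans()] tables, one per river.
#' @param L Named composite-loading vector.
#' @param breaks Bin edges on L (default: 8 equal-count bins).
#' @return Data frame: bin, bin_mid, river (or "all"), n_loci, mean_abs_cis,
#'   mean_abs_trans; empty bins flagged with `NA`.
#' @export
effect_size_bins <- function(divergence, L, breaks = NULL) {
  breaks <- breaks %||% stats::quantile(L, seq(0, 1, length.out = 9))
  out <- list()
  for (river in names(divergence)) {
    d <- divergence[[river]]
    Lc <- L[d$transcript_id]
    bin <- cut(Lc, breaks, include.lowest = TRUE)
    for (b in levels(bin)) {
      sel <- !is.na(bin) & bin == b
      out[[length(out) + 1L]] <- data.frame(
        bin = b, river = river, n_loci = sum(sel),
        mean_abs_cis = if (any(sel)) mean(abs(d$mean_cis[sel])) else NA_real_,
        mean_abs_trans = if (any(sel)) mean(abs(d$mean_trans[sel])) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  all_rows <- lapply(unique(res$bin), function(b) {
    d <- res[res$bin == b, ]
    data.frame(bin = b, river = "all", n_loci = sum(d$n_loci),
               mean_abs_cis = mean(d$mean_abs_cis, na.rm = TRUE),
               mean_abs_trans = mean(d$mean_abs_trans, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  res <- rbind(res, do.call(rbind, all_rows))
  res$mean_abs_cis[is.nan(res$mean_abs_cis)] <- NA_real_
  res$mean_abs_trans[is.nan(res$mean_abs_trans)] <- NA_real_
  rownames(res) <- NULL
  res
}
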