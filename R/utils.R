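#' Log2 ratio with pseudocounts
#'
#' Computes `log2((a + pseudo) / (b + pseudo))`. The pseudocount (default 0.5
#' per cell) keeps ratios finite when one count is zero; it is applied to
#' magnitudes only, never inside the exact tests.
#'
#' @param a,b Non-negative numeric vectors (counts, possibly size-factor scaled).
#' @param pseudo Pseudocount added to both terms.
#' @return Numeric vector of log2 ratios.
#' @export
log2_ratio <- function(a, b, pseudo = 0.5) {
  log2((a + pseudo) / (b + pseudo))
}

#' Area under the ROC curve for a ranking
#'
#' Rank-based (Mann-Whitney) AUC of `score` for separating `positive` cases
#' from the rest. Used to measure how well a statistic recovers planted truth.
#'
#' @param score Numeric vector.
#' @param positive Logical vector, same length, TRUE for true positives.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]; positive <- positive[ok]
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("need both positive and negative cases")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Benjamini-Hochberg significance flags
#'
#' @param p Numeric vector of p-values (NAs allowed, never flagged).
#' @param level FDR level (default 0.10).
#' @return Logical vector: TRUE where BH-adjusted p <= level.
#' @export
bh_flags <- function(p, level = 0.10) {
  q <- stats::p.adjust(p, method = "BH")
  !is.na(q) & q <= level
}

# standard error of the mean, NA-safe
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
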