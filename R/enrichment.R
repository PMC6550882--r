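# Enrichment of regulatory classes among parallel diverged loci:
# class-frequency summaries, a randomization (resampling) test against a
# background set of ecotype-divergent transcripts, and hypergeometric set
# overlap.

#' Regulatory class frequencies per F1
#'
#' Proportion of analyzed (testable) transcripts assigned to each class, per
#' F1.
#'
#' @param calls Per-transcript per-F1 calls.
#' @param classes Classes to tabulate (default all seven).
#' @return Data frame: f1, class, n, n_analyzed, proportion.
#' @export
class_frequencies <- function(calls, classes = regulatory_classes()) {
  if (!nrow(calls)) stop("no analyzed transcripts")
  out <- list()
  for (f1 in sort(unique(calls$f1))) {
    d <- calls[calls$f1 == f1, ]
    n_analyzed <- nrow(d)
    if (n_analyzed == 0L) stop("no analyzed transcripts for F1 ", f1)
    for (cl in classes) {
      n <- sum(d$class == cl)
      out[[length(out) + 1L]] <- data.frame(
        f1 = f1, class = cl, n = n, n_analyzed = n_analyzed,
        proportion = n / n_analyzed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Randomization test for class overrepresentation among parallel loci
#'
#' Compares the observed class proportions among parallel diverged testable
#' loci with `n_draws` random draws (without replacement) of equal size from
#' the background set of ecotype-divergent testable loci. The observed value
#' is flagged significant when it falls outside the central 99.3% of the null
#' draws (box-plot whisker convention), and an add-one empirical one-sided p
#' in the direction of the deviation is reported:
#' `p = (1 + #draws at least as extreme) / (n_draws + 1)`.
#'
#' @param calls Per-transcript per-F1 calls.
#' @param parallel_set Transcript IDs with parallel expression divergence
#'   (must be a subset of the testable loci per F1 after intersection).
#' @param background_set Transcript IDs forming the background (ecotype
#'   expression divergence).
#' @param n_draws Number of random draws (default 1000).
#' @param seed RNG seed.
#' @param classes Classes to test.
#' @return Data frame per F1 per class: observed proportion, null median,
#'   whisker bounds (central 99.3%), box bounds (central 50%), empirical p,
#'   significance flag.
#' @export
overrepresentation_test <- function(calls, parallel_set, background_set,
                                    n_draws = 1000, seed = NULL,
                                    classes = setdiff(regulatory_classes(),
                                                      "ambiguous")) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (f1 in sort(unique(calls$f1))) {
    d <- calls[calls$f1 == f1, ]
    testable <- d$transcript_id
    par_ids <- intersect(parallel_set, testable)
    bg_ids <- intersect(background_set, testable)
    n_par <- length(par_ids)
    if (n_par == 0L || length(bg_ids) < n_par) next
    cls <- d$class[match(bg_ids, d$transcript_id)]
    obs_cls <- d$class[match(par_ids, d$transcript_id)]
    draws <- matrix(0, n_draws, length(classes),
                    dimnames = list(NULL, classes))
    for (r in seq_len(n_draws)) {
      drawn <- cls[sample.int(length(bg_ids), n_par)]
      draws[r, ] <- vapply(classes, function(cl) mean(drawn == cl), 0)
    }
    for (cl in classes) {
      obs <- mean(obs_cls == cl)
      null <- draws[, cl]
      whisk <- stats::quantile(null, c(0.0035, 0.9965))
      box <- stats::quantile(null, c(0.25, 0.75))
      p_hi <- (1 + sum(null >= obs)) / (n_draws + 1)
      p_lo <- (1 + sum(null <= obs)) / (n_draws + 1)
      out[[length(out) + 1L]] <- data.frame(
        f1 = f1, class = cl, n_parallel = n_par,
        observed = obs, null_median = stats::median(null),
        whisker_lo = whisk[[1L]], whisker_hi = whisk[[2L]],
        box_lo = box[[1L]], box_hi = box[[2L]],
        p_empirical = min(p_hi, p_lo),
        direction = if (obs >= stats::median(null)) "over" else "under",
        significant = obs < whisk[[1L]] | obs > whisk[[2L]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no F1 with a usable parallel/background set")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric test for set overlap
#'
#' Upper-tail probability of observing at least the given overlap between two
#' sets drawn from a common universe.
#'
#' @param setA,setB Character vectors (intersected with `universe`).
#' @param universe Character vector of all possible elements.
#' @return List: overlap size, sizes, universe size, p-value.
#' @export
hypergeometric_overlap <- function(setA, setB, universe) {
  A <- intersect(unique(setA), universe)
  B <- intersect(unique(setB), universe)
  ov <- length(intersect(A, B))
  N <- length(unique(universe))
  p <- stats::phyper(ov - 1, length(A), N - length(A), length(B),
                     lower.tail = FALSE)
  list(overlap = ov, nA = length(A), nB = length(B), universe = N, p = p)
}
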