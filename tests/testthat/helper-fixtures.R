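# Small fixtures shared across test files; everything is built in code.

# a tiny cross with balanced divergence classes, deep enough to classify
tiny_cross <- function(n_genes = 120, seed = 101, depth = 300, ...) {
  cfg <- sim_config(
    n_genes = n_genes, seed = seed, depth_snp = depth,
    class_props = c(cis = 1 / 6, trans = 1 / 6, "cis+trans" = 1 / 6,
                    "cis-trans" = 1 / 6, compensatory = 1 / 6,
                    conserved = 1 / 6),
    ...)
  simulate_cross(cfg)
}

# hand-built per-SNP/per-F1 calls table for set-logic tests
make_calls <- function(transcript_id, f1, class,
                       cis_mag = 1, trans_mag = 0) {
  data.frame(transcript_id = transcript_id, f1 = f1, class = class,
             cis_mag = cis_mag, trans_mag = trans_mag,
             R_P = cis_mag + trans_mag, stringsAsFactors = FALSE)
}

# independent Weir & Cockerham variance-components oracle, written from the
# general r-population formulation with explicit per-population sums
wc_fst_oracle <- function(g1, g2) {
  pops <- list(g1[!is.na(g1)], g2[!is.na(g2)])
  r <- length(pops)
  n <- vapply(pops, length, 0)
  if (any(n < 1)) return(NA_real_)
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), 0)
  h <- vapply(pops, function(g) mean(g == 1), 0)
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# pairwise-enumeration oracle for per-site nucleotide diversity
pi_oracle <- function(alleles) {
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) diffs <- diffs + (alleles[i] != alleles[j])
  }
  diffs / choose(n, 2)
}
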