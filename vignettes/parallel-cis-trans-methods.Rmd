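---
title: "Methods: parallel expression divergence and its cis/trans architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel expression divergence and its cis/trans architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`paracis` implements an inference chain for studying how gene expression
diverges between marine and freshwater ecotypes that have adapted in
parallel in independent river systems:

1. detect transcripts with *parallel* expression divergence using a
   composite principal-component statistic with a label-permutation FDR;
2. dissect each transcript's regulatory divergence into *cis* (allele-specific)
   and *trans* (non allele-specific) components from allele-specific
   expression (ASE) in F1 hybrids of wild-derived parents;
3. quantify the magnitudes, mode of inheritance, sibling sharing and
   environmental stability of those components;
4. test for enrichment of regulatory classes among parallel diverged loci;
5. scan for molecular signatures of selection (FST, nucleotide diversity,
   cluster separation score) around transcription start sites.

Every stage runs on synthetic data with planted, recorded ground truth, so
the entire chain is testable without sequencing data.

# The composite-PC statistic

Expression counts are normalized with median-of-ratios size factors and
transformed with a shifted log, `log2(count/sf + 1)`. The shifted log is a
deliberate, documented stand-in for a full variance-stabilizing transform:
it is monotone, exact at zero, and close to variance-stabilizing for
moderately overdispersed counts; its difference from more elaborate
transforms is immaterial for covariance PCA on deeply sequenced libraries.

PCA is computed on the sample covariance (unscaled), on a *balanced core
set* of samples (equal numbers of marine and freshwater fish); remaining
samples are projected onto the core axes using the core per-gene centering.
The `k = 2` components whose scores correlate most with ecotype (point
biserial) are the ecotype-separating axes; each is oriented so the marine
mean score is positive. The per-transcript composite loading is

    L_g = sum_i w_i * s_i * l_{g,i}

with `w_i` the PVE fraction, `s_i` the orientation sign and `l_{g,i}` the
loading. Transcripts in the top or bottom 1% of `L` are the *parallel
diverged loci*.

## Permutation FDR

Single PCA loadings have no standard significance test. For each outlier
gene we shuffle the sample labels *for that gene alone*, keeping all other
data as observed: for every balanced split of the core samples into two
pseudo-ecotype groups (6435 unordered splits for 8 + 8 from 16; enumerated
when feasible, otherwise subsampled without replacement with the identity
split retained), the gene's values observed in marine samples are
reassigned to the pseudo-marine positions and the PCA and composite loading
are recomputed. Because only one gene's column changes, the sample Gram
matrix changes by a rank-2 update, so each permutation costs one 16x16
eigendecomposition rather than a full PCA.

Two p-values are reported. The directional normal-approximation p (Z-score
of the observed loading against the permuted null, one-sided in the
direction of the observed sign) drives the Benjamini-Hochberg q-values
across outliers — this is the published procedure. The empirical upper-tail
probability `p_upper` (share of enumerated splits with a loading at least
as high as observed) is exactly uniform for exchangeable null genes and is
what we use to verify calibration. Two further choices are recorded as
options: the ecotype-PC indices from the observed analysis are reused per
permutation by default (`reidentify = FALSE` re-selects them per split),
and group identity is treated as exchangeable, so each unordered split is
counted once.

A caveat worth stating: when the expression matrix contains gene-by-river
structure, arbitrary 8/8 relabelings are not exchangeable for a null gene
(they break the river nesting), and the permutation p becomes mildly
conservative. This is a property of the label-shuffling scheme itself; the
calibration test therefore uses a generator configuration without river
offsets, while the recovery test keeps the full two-river design.

# ASE classification

Informative SNPs are sites where the two parents are homozygous for
different alleles, each genotype supported by at least 10 DNA-sequencing
reads. SNPs are assigned to overlapping transcript models; sites outside
transcripts are dropped. Expression coverage must exceed 10 reads in at
least one F1 (strictly greater). A SNP is excluded as monoallelic when any
F1 shows zero reads for one allele while carrying at least 20 reads in
total — 20 separates sampling zeros at low coverage from the mappability
artifacts that produce consistent zeros at high coverage — or when a parent
shows more than 1% of its reads on the allele it should not carry.

Three exact tests are computed per SNP:

* **ASE test** — binomial test of the F1's reference-allele count against a
  null fraction `p0` estimated per F1 as the ratio of all reference reads
  over all reads at informative SNPs. This absorbs residual reference-mapping
  bias; on unbiased data `p0 = 0.5`.
* **Parent test** — binomial test of the marine parent's reads against the
  total at the SNP, with null `sM/(sM + sF)` from the parents'
  median-of-ratios size factors. Folding normalization into the null keeps
  the test exact on integer counts.
* **Fisher test** — two-sided Fisher exact test of the F1 allele counts
  against the parental counts (2x2 table).

Two-sided binomial p-values use the minimum-likelihood ("minlike")
definition — the sum of probabilities of outcomes no more likely than the
observed one — because with an asymmetric null `p0 != 0.5` the
doubling-smaller-tail convention is ambiguous; the central (doubled)
variant is available via `alternative = "central"`. Significance flags are
Benjamini-Hochberg at FDR 10% within each (F1, test) family across SNPs.

The flags and the signs of `cis = R_F1` (F1 allelic log2 ratio) and
`trans = R_P - R_F1` (parental log2 ratio minus the allelic ratio) map to
seven classes: cis; trans; cis+trans (both significant in everything, same
sign); cis-trans (opposite signs); compensatory (alleles differ but parents
do not); conserved (nothing significant); ambiguous (any other flag
combination). Log2 ratios use a 0.5 pseudocount per cell; tests always use
raw counts. Each transcript gets one call per F1 from the representative
SNP minimizing the product of the three p-values (ties broken by
coordinate). This selection is biased toward significance when a transcript
carries several SNPs — one reason the conserved false-call rate is checked
explicitly on null simulations.

# Quantitative architecture

Per-locus cis and trans magnitudes are the F1 allelic log2 ratio and its
complement against the parental ratio, averaged over the (up to four) F1s;
by construction `mean_cis + mean_trans` equals the mean parental log2
ratio. Cross-river parallelism is summarized by Pearson correlations over
nested subsets of loci at composite-loading quantiles {50, 25, 10, 5, 2.5,
1}% per tail (at least 5 loci per subset, otherwise reported missing), and
by mean |cis| and |trans| within composite-loading bins.

The dominance/additivity ratio is `d/a` with `a` half the parental
difference of normalized counts and `d` the F1's deviation from the
midparent: 0 is additive, +/-1 full dominance, beyond that over- or
underdominance. The ratio is undefined where the parents do not differ, so
the analysis evaluates loci in divergence classes (the conserved class is
excluded); this also resolves which loci enter the density plot of the
inheritance analysis.

Sibling sharing of a class is the percentage of loci called that class in
both siblings among loci called it in either, restricted to loci testable
in both — the denominator the figure legend leaves implicit.

# Enrichment

Observed class proportions among parallel diverged testable loci are
compared with 1000 random draws (without replacement, equal size) from the
background set of ecotype-divergent testable loci. An observation is
flagged when it falls outside the central 99.3% of the null draws (the
box-plot whisker convention) and carries an add-one empirical p,
`(1 + #draws at least as extreme)/(n_draws + 1)`, which can never be zero.
The background set is an explicit input (by default the 10% composite-PC
tails among testable loci), and the hypergeometric overlap test takes its
universe explicitly — both recorded in the output because enrichment
results are only interpretable relative to them.

# Population-genetic signatures

Per-site FST uses the two-population Weir-Cockerham variance-components
estimator on diploid dosages with the observed-heterozygosity correction;
negative estimates are clamped to zero, monomorphic sites are undefined.
Per-site nucleotide diversity within an ecotype is `j(n-j)/C(n,2)` over the
`n` non-missing alleles with `j` alternate copies. Sites exceeding the
missing-genotype caps (4 genotypes for FST, 2 for Pi) are skipped entirely
rather than computed on reduced samples.

The cluster separation score (CSS) works in 10 kb non-overlapping windows:
pairwise individual distances (mean per-site allele-sharing difference) are
embedded by 2-D metric MDS, and CSS contrasts the mean between-ecotype
distance with the within-ecotype means. Because the exact size
normalization of the published scheme is external to this implementation,
both `css_raw` (unweighted within-mean) and `css_norm` (group-size
weighted) are emitted; with equal group sizes they coincide, and outlier
ranking (top 1%) is invariant to the choice.

TSS profiles average per-site statistics in 1 kb bins tiling 400 kb
centered on each TSS — the "1 kb sliding windows" read as a non-overlapping
tiling, configurable — with offsets strand-oriented (upstream negative),
then average across the loci of each group with the SEM. The proximity
randomization measures the cumulative share of focal transcripts within
10 kb increments of the nearest outlier window (distance 0 on overlap,
else the gap between nearest edges, using the transcript span) against
1000 random transcript sets; the figure-legend value of 100 randomizations
is available via `n_random`.

# Salinity plasticity

Expression profiles are per-transcript log2 values centered on the
across-sample mean; sample similarity is Spearman correlation with
complete-linkage Euclidean clustering. The stability of cis regulation is
measured analogously on per-SNP log2 marine/freshwater allele fold-changes.
Under trans-mediated plasticity the expression profiles of freshwater- and
seawater-acclimated siblings anticorrelate while the allelic ratios stay
put — the signature of a heritable cis state that could genetically
assimilate a plastic response.

# The synthetic-data generator

`simulate_cross()` plants, per gene, a regulatory class and log2 effects
`c` (cis) and `t` (trans) honouring the class sign constraints: the
expected parental ratio is `2^(c+t)` and the expected F1 allelic ratio
`2^c`. Read counts are Poisson by default (`dispersion = 0`); a
negative-binomial option exists, but independent overdispersed totals for
the two parents would make the parental allele fraction conditionally
beta-binomial, contradicting the planted truth that the parental ratio is
exact with read-sampling noise — so Poisson is the coherent default, and
biological across-individual variance lives in the population-expression
generator's `noise_sd` (0.5 log2 units) instead. Mapping bias distorts the
observed reference fraction at heterozygous sites as
`b*r/(b*r + (1-b)(1-r))`; homozygous parents sit at the fixed points of
this map and are undistorted. The simulator records which of
reference/alternate is the marine allele per SNP, mirroring the conversion
between reference/alternate and marine/freshwater orientations.

Default study conditions, chosen once: class proportions 12% cis, 6% trans,
4% cis+trans, 3% cis-trans, 5% compensatory, 70% conserved (the ballpark of
the most divergent ecotype pair); |c| = |t| = 1 log2 unit, with
`t = -c` for compensatory and `t = -sign(c)(|c|+|t|)` for the opposing
class so its parental ratio stays nonzero; 3 informative SNPs per
transcript (within the observed 2-6 per locus); 200 reads per SNP; 4 F1s;
parental DNA depth 30; library-size factors spread by 0.15 log2 units.
`effect_jitter_sd` optionally spreads the per-gene magnitudes log-normally:
rank-based stability statistics degenerate when every locus shares one
exact magnitude (within-tie ranks are pure noise, capping Spearman near
0.75 for two atoms), so the salinity-stability analyses use a continuous
spread of 0.5 log2 units, which is also the more realistic reading of an
effect-size distribution.

Sweeps are planted by pushing within-ecotype allele frequencies toward
opposite fixation near a quarter of the TSSs, with a linear decay of the
distortion over a 20 kb half-width — the simplest shape consistent with
empirical profiles. Salinity acts purely in trans: plastic genes shift
`+shift` at 0.2 ppt and `-shift` at 35 ppt (random direction per gene)
while the allelic fraction stays at `2^c` in every salinity.

What the generator does *not* emulate: read alignment and its artifacts
beyond the scalar bias `b`, isoform structure, linkage disequilibrium
beyond the sweep block, batch effects, and biological dispersion of SNP
counts within an individual. Passing tests therefore demonstrate that the
inference chain is correct and calibrated under its stated assumptions, not
that those assumptions exhaust real RNA-seq data.

# Problem sizes and numerical choices

The shipped analyses and checks use: 2 000-2 500 genes x 3 SNPs x 6
individuals for classifier runs (depths 20-1000 reads/SNP for the
recovery-vs-depth curve); 5 000 genes x 16 core samples with 1% planted
parallel effects of 2 noise-SD for the composite PC; 2 000 enumerated (or
all 6435) label splits per gene for the permutation null; 8 000 sites on a
4 Mb chromosome with 6 + 6 diploids and 10 planted sweeps for the popgen
scan; 1000 draws for the enrichment and proximity randomizations. Exact
tests are evaluated by direct pmf/hypergeometric summation with the
`(1 + 1e-7)` relative tolerance conventional for minlike definitions;
degenerate permutation nulls (zero spread) are flagged with p = 1; all
randomized operations take explicit seeds and are reproducible
bit-for-bit.

# Known limitations

* The shifted-log transform is not a full variance-stabilizing transform;
  at very low counts its variance rises, which slightly favors
  highly-expressed transcripts in the PCA loadings.
* The permutation FDR is conservative in the presence of strong
  river-by-gene structure (see above).
* The representative-SNP rule (lowest p-product) biases per-transcript
  calls toward significance when many SNPs tag one transcript; the
  conserved-calibration check bounds the practical effect.
* Isoform-level ASE is out of scope; classification is at the transcribed
  locus level.
* The CSS size normalization follows the cited scheme only up to its
  unpublished constant; both variants are emitted and ranking is unaffected
  for balanced designs.
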