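---
title: "Methods: burden, F-statistics and haplotype analysis in carnburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burden, F-statistics and haplotype analysis in carnburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carnburden)
```

`carnburden` asks whether a small founder cohort carries an excess of
rare, deleterious missense alleles in the carnitine acyltransferase
genes relative to a reference population, and quantifies the allele- and
haplotype-level differentiation between the two. This vignette is the
package's own account of the statistical machinery: the models, their
assumptions, the tunable parameters and the numerical choices, and what
the synthetic-data tests do and do not demonstrate.

## The cohort model

A cohort is an individuals-by-variants matrix of diploid dosages
(0/1/2, `NA` for a missing call) with per-variant annotation. Two
conventions matter throughout:

* **Derived-allele orientation.** Frequencies and burdens count
  *derived* alleles relative to the reference genome, not ALT alleles.
  Every variant carries an explicit `derived_is_alt` flag set when the
  data are generated or read; nothing downstream assumes ALT = derived.
* **Coordinates.** Gene regions are 1-based inclusive and extended by a
  flank (default 2000 bp) before variants are assigned; the assignment
  flips exactly at `start - flank` and `end + flank`, which is covered
  by a dedicated boundary test.

Missing genotypes stay missing through QC; allele frequencies divide by
*called* chromosomes, so a frequency is always an estimate over the
individuals actually genotyped.

## Genotype-level QC

Three thresholds, all explicit parameters of `qc_thresholds()` with the
pipeline defaults: sequencing depth ≥ 20 reads, genotype quality ≥ 10
(phred), and alternate-read fraction ≥ 0.25. The 25% rule is
interpreted *per genotype* (the standard exome-QC reading of a "variant
frequency" filter): a heterozygous or hom-alt call supported by under a
quarter of its reads is masked, while hom-ref calls are untouched. The
alternative reading — a cohort-level MAF filter — would contradict the
analysis itself, which deliberately retains cohort-common,
panel-absent variants; the choice is flagged here because the phrase is
ambiguous in the field. Filtering is idempotent and the masked-call
count is logged.

The Hardy–Weinberg test is the exact conditional test: given `n`
diploids and the observed allele counts, the heterozygote count `h` has
probability

$$P(h) = \frac{n!}{n_{AA}!\,h!\,n_{aa}!}\,2^h \Big/ \binom{2n}{n_A},$$

and the two-sided p sums `P(h')` over all feasible `h'` with
`P(h') ≤ P(h_obs)` (probability ordering). The implementation evaluates
the distribution in log space; a brute-force enumeration oracle checks
it exhaustively for all configurations up to `N = 50`.

## Ancestry screening

`ibs_mds()` performs classical metric scaling of the allele-sharing
distance `d(i,j) = 1 − IBS(i,j)/2`, with IBS the mean number of shared
alleles over variants called in both individuals — the distance most
association-era toolchains use. The choice of distance is a design
decision (the field's common practice), not a published specification.
Outliers are then flagged by a reproducible rule replacing visual
inspection of the MDS plot: an individual is an outlier when its
position on the first two axes lies more than `k` (default 6) robust
scale units (MAD of within-cluster distances) from its claimed
cluster's medoid. The default `k` is deliberately loose; it flags
individuals *between* clusters (admixture) rather than cluster-edge
noise. On simulated data, 9 planted half-admixed genomes among 104 pure
ones are recovered exactly.

## Rarity and the mutation burden

A variant is **rare** when its minor allele frequency is ≤ 0.01
(inclusive) in *every* reference panel population. Rarity is strictly
reference-based: a variant at frequency 0.955 in the study cohort but
absent from all panels is rare, which is precisely what makes the
burden statistic informative in a founder population. Variants absent
from the panel file are treated as frequency 0 with a warning.

The per-gene burden is

$$B = \frac{1}{N}\sum_{v \in \text{rare missense}} \sum_{i=1}^{N} g_{iv},$$

the mean count of rare missense derived alleles per person. Missing
genotypes contribute 0 while the denominator stays `N`, making `B`
conservative under missingness. On exact-count cohorts
`B = 2\sum_v p_v` to machine precision, which the tests assert.

Three significance devices accompany `B`:

* an exact one-sided binomial tail `P(X ≥ k | n, p₀)` where `p₀` is the
  comparison cohort's pooled rare-missense allele frequency for the
  gene. One-sided because the hypothesis is an *increased* burden;
  per-gene (rather than per-variant) pooling of `p₀` reproduces the
  magnitudes of the published table. `p₀ = 0` with `k > 0` is a
  degenerate null and returns 0 with a warning;
* a label permutation test: individuals are pooled, relabelled into
  groups of the original sizes, and the burden difference recomputed;
  `p = (1 + \#\{perm ≥ obs\})/(1 + n_\text{perm})`. The add-one rule
  guarantees `p ≥ 1/(n_\text{perm}+1)` and super-uniformity under the
  null (verified by a 1000-replicate KS calibration test). The
  published analysis names an "adaptive" permutation scheme without
  specifying it; we implement plain fixed-count permutation and offer
  `early_stop` (abort once significance at `alpha` is impossible) as an
  optional flag;
* Bonferroni adjustment `min(1, m·p)` over the `m` variant-containing
  genes.

## F-statistics

No single F_ST estimator is canonical at these sample sizes, and
published per-variant values rarely say which was used; `carnburden`
therefore ships four and reports them side by side:

* **Wright**: `(H_T − H_S)/H_T` with the unweighted pooled frequency;
* **Nei G_ST**: the same contrast with sample-size-weighted pooling;
* **Weir–Cockerham**: the two-population variance-component estimator
  `θ = a/(a+b+c)`, using observed heterozygosity when genotypes are
  available and the HWE expectation otherwise. Components are kept so
  multi-locus summaries can pool `Σa / Σ(a+b+c)` (ratio of sums), the
  recommended weighting;
* **Hudson**: the ratio-of-moments estimator with its small-sample
  bias correction.

For the signature variant (0.955 vs 0 at 100 vs 83 individuals) the
four estimators span 0.906–0.955 — they genuinely differ at strong
differentiation, which is why results bracket rather than pin a single
value. At a site monomorphic for the same allele in both samples the
statistic is undefined and flagged `NA`, never coerced to 0; undefined
loci are excluded from multi-locus summaries. Note two numerical
subtleties the tests encode: the bias-corrected estimators
(Weir–Cockerham, Hudson) sit slightly *below* zero when the two sample
frequencies coincide, and estimator agreement to `O(1/n)` holds under
panmictic sampling (both samples drawn from one frequency), not for
arbitrary frequency pairs.

`F_IS = 1 − H_obs/H_exp` uses the unbiased expected heterozygosity
`2p(1−p)·2N/(2N−1)` by default (switchable). Randomization significance
permutes population labels for F_ST and shuffles alleles among
individuals within the population for F_IS (breaking genotypic
correlation while preserving allele counts), with the same add-one
empirical p.

## Haplotype frequencies and LD

`em_haplotype_frequencies()` maximises the multinomial haplotype-pair
likelihood under HWE by EM. Haplotypes are enumerated as bit codes
(capped at 12 loci); each phase-ambiguous multilocus genotype is
distributed over its `2^{h-1}` compatible resolutions proportionally to
current frequency products. Initialisation is uniform over compatible
haplotypes and ties are broken only by frequency products, so the fit
is deterministic; the log-likelihood is asserted non-decreasing at
every iteration and convergence is declared when the largest frequency
change drops below `tol` (default 1e-8). Individuals missing a
genotype at any requested locus are dropped with a warning — the
estimator targets population frequencies, not imputation. A simplex
grid-search oracle confirms the EM optimum on two-locus fixtures to
1e-3.

Pairwise LD uses the closed forms `D = f_{AB} − f_A f_B`,
`D' = D/D_\max` with the sign-appropriate bound, and
`r² = D²/(p_Aq_Ap_Bq_B)`; the LOD score is the log10 likelihood ratio
of the EM haplotype frequencies against linkage equilibrium given the
genotype data. The D′ confidence interval is a profile likelihood:
allele frequencies are held at their sample estimates, the genotype
likelihood is evaluated on a |D′| grid (step 0.01), normalised, and the
5th/95th percentiles reported — the convention used by
confidence-interval block finders. A seeded 200-resample bootstrap is
available as an alternative.

Blocks follow the confidence-interval recipe with the thresholds used
in the source analysis: a pair is strong LD when CI ∈ [≥ 0.6, ≥ 0.98],
shows strong recombination when the upper bound < 0.9, and is otherwise
uninformative; markers with MAF < 0.05 are excluded from pair counting
(the dashed-line convention). A span is a block when its outermost pair
is strong and ≥ 95% of its informative pairs are strong; maximal
non-overlapping spans are reported left to right.

Haplotype-frequency comparisons are offered in both modes the field
uses — an exact one-sample binomial tail against the comparison
population's frequency and a two-proportion z test on the 2×2 table —
because published binomial p-values for haplotype contrasts often do
not state which was applied (the bracketing behaviour of the two modes
is documented in the tests).

## Deleteriousness scores

`mann_whitney_exact()` computes U from midranks and, for combined
samples up to 20, an exact p by enumerating all `C(n₁+n₂, n₁)` group
assignments of the observed multiset — valid under ties, which matters
because PolyPhen-2 scores saturate at 1.0 and tie frequently. Larger
samples use the tie-corrected normal approximation. Two-sided p is the
default report, with both one-sided options exposed. The 2×2
`chi2_two_proportions()` is Pearson's statistic (optional Yates), which
is undefined (and flagged) on zero-margin tables.

## The synthetic-data generator

The generator defines the study conditions under which everything is
tested:

* `exact_count` mode places exactly `round(2Np)` derived alleles per
  variant, assigning genotypes as the HWE-closest configuration — the
  heterozygote count nearest `2Npq` with the parity the allele count
  forces. This makes burden statistics deterministic and, at the
  signature variant (191 alleles in 100 individuals → 91 hom + 9 het),
  yields F_IS ≈ −0.042, matching the near-HWE inbreeding estimates the
  analysis reports. Because the true genotype configurations behind
  published F_IS values are not recoverable from summary tables, the
  heterozygote counts are exposed as an override (`het_counts`) rather
  than guessed.
* `hwe_sampling` mode draws genotypes i.i.d. from `(q², 2pq, p²)`;
  generated cohorts pass the exact HWE test with super-uniform
  p-values (KS-checked).
* `simulate_haplotype_cohort()` draws two haplotypes per individual
  i.i.d. from a specified haplotype distribution (random union of
  gametes) and retains the phased truth, so EM accuracy is scored
  against both the realized haplotype counts (phase-ambiguity error
  only, < 0.03 at N = 100 on the bundled four-haplotype structure) and
  the population truth (3·SE bound).
* `simulate_admixed()` draws HWE genotypes at mixed frequencies
  `(1−λ)p_A + λp_B` to plant ancestry outliers.

Seeds are mandatory arguments and all outputs are reproducible
bit-for-bit from (spec, seed). The bundled frequency tables place the
studied cohorts at their published sizes (100 and 286 individuals) and
frequencies; the three synonymous variants whose cohort frequencies
were never published are carried with `NA` frequency and excluded from
simulation. Variant base-pair positions are synthetic placements inside
the true gene regions, spaced to preserve the reported LD-block spans.

What the generator does *not* emulate: linkage between genes, realistic
site-frequency spectra beyond the specified variants, sequencing error,
genotype-calling artefacts, or demographic history (no coalescent).
Passing tests therefore demonstrate the correctness of the statistics
under their own sampling assumptions, not robustness to real-data
artefacts.

## Problem sizes and budgets

The default test run simulates cohorts of 30–500 individuals, uses
2·10⁴ permutations for the permutation-oracle comparison, 10⁵ for the
published-scale scenario, 1000 replicates for permutation-null
calibration and 300 for randomization-null calibration, and exhausts
the HWE oracle to N = 50 — sizes chosen so the full suite completes in
about a minute on one core while keeping every Monte-Carlo tolerance at
3–4 standard errors.

## Known limitations

* Biallelic SNVs only; multi-allelic records are rejected, not split.
* The EM estimator is frequency-only (no individual phasing) and
  enumeration-bound at 12 loci.
* Two populations only for F-statistics; no hierarchical levels, no
  block-jackknife intervals.
* The burden statistic is unweighted allele counting; no SKAT-style
  kernels.
* `F_ST`/`F_IS` randomization recomputes the full estimator per
  replicate and is the slowest stage at large variant counts.
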