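# carnburden

Rare-variant mutation burden, F-statistics and haplotype analysis of
carnitine acyltransferase gene variation in small founder cohorts.

## The problem

The six carnitine acyltransferase genes (*CPT1A*, *CPT1B*, *CPT1C*,
*CPT2*, *CRAT*, *CROT*) encode the enzymes that shuttle fatty acyl groups
into mitochondria for beta-oxidation. In populations with a very
high-fat traditional diet — the Nunavik Inuit being the canonical case —
these genes are candidates for diet-driven selection: the question is
whether such a cohort carries *more rare, functionally deleterious
missense alleles per person* in these genes than a comparison
population, and how strongly differentiated the two populations are at
these sites.

`carnburden` implements the complete statistical pipeline for that
question as a tested, reusable R package, for population geneticists
analysing small exome-sequenced cohorts against public reference panels:

- genotype-level QC (depth ≥ 20×, genotype quality ≥ 10, per-call
  alternate-read fraction ≥ 25%), derived-allele frequencies and an
  exact Hardy–Weinberg test;
- identity-by-state MDS with a reproducible ancestry-outlier rule;
- reference-panel rarity classification (MAF ≤ 0.01 in *every* panel);
- the per-gene **mutation burden** B = (rare missense derived alleles) / N,
  with an exact one-sided binomial test against the comparison cohort's
  pooled rare-allele frequency p₀, a label permutation test
  (add-one rule, p = (1 + #{perm ≥ obs}) / (1 + n_perm)) and Bonferroni
  correction over variant-containing genes;
- per-variant F_ST (Wright, Nei G_ST, Weir–Cockerham θ = a/(a+b+c),
  Hudson) and F_IS = 1 − H_obs/H_exp with randomization significance;
- EM estimation of haplotype frequencies from unphased genotypes under
  HWE, pairwise D′ / r² / LOD, profile-likelihood D′ confidence
  intervals and Gabriel-style LD blocks;
- exact Mann–Whitney comparison of deleteriousness scores (valid under
  ties) and two-proportion χ² tests.

A synthetic-cohort simulator (`simulate_cohort()`,
`simulate_haplotype_cohort()`, `simulate_admixed()`) generates diploid
cohorts with exact allele counts or HWE sampling at any frequency
profile — the published allele and haplotype frequencies are bundled
(`carn_variants()`, `carn_refpanel()`, `cpt2_haplotypes()`) — so the
whole pipeline is exercisable without access to individual-level data.

## Worked example

```r
library(carnburden)

paths <- make_fixtures("fixtures", seed = 1)   # 100-individual study
a     <- read_vcf(paths[["vcf"]])              # cohort and 286-individual
b     <- read_vcf(paths[["vcf_b"]])            # comparison cohort
panel <- load_reference_frequencies(paths[["refpanel"]])

burden_table(a, b, panel, n_perm = 10000, seed = 1)
#> # A tibble: 5 x 11
#>   gene  burden_a burden_b  ratio p_binomial  p_perm p_binomial_adj
#>   <chr>    <dbl>    <dbl>  <dbl>      <dbl>   <dbl>          <dbl>
#> 1 CPT1A     1.91  0.00699 273.     0        0.0001         0
#> 2 CPT1B     0     0.00699   0      1        1              1
#> 3 CPT1C     0.01  0.0140    0.714  0.754    0.778          1
#> 4 CPT2      0.06  0.0105    6      0.000722 0.0115         0.00361
#> 5 CRAT      0.05  0.00699   7.14   0.000754 0.0146         0.00377
```

`burden_a` is the mean number of rare missense derived alleles per
person: a study-cohort individual carries on average 1.91 *CPT1A*
alleles (the near-fixed p.P479L at frequency 0.955) against 0.007 in
the comparison cohort — a ~270-fold excess with a vanishing binomial p.
*CPT2* and *CRAT* show smaller but significant excesses (Bonferroni-
adjusted p < 0.01); *CPT1B* and *CPT1C* show none. The two common
*CPT2* variants (p.F352C, p.V368I) are correctly excluded by the
reference-MAF rule even though they are frequent in the study cohort.

Haplotype structure at the three *CPT2* missense sites, re-estimated
from unphased genotypes:

```r
loci <- dplyr::filter(carn_variants(),
                      variant %in% c("CPT2:p.F352C", "CPT2:p.V368I",
                                     "CPT2:p.R477W"))
ch <- simulate_haplotype_cohort(
  haplotype_spec(loci, cpt2_haplotypes(), 100, seed = 1))
em_haplotype_frequencies(ch)
#> <haplo_em> 3 loci, 100 individuals, 34 iterations (converged)
#>   TGC   GAC   TAC   TGT   TAT
#> 0.415 0.320 0.240 0.025 0.000
```

The EM recovers the four simulated haplotypes (truth 0.45/0.28/0.24/0.03)
within binomial sampling error of a 200-chromosome draw.

Population differentiation at the signature variant (0.955 vs 0,
100 vs 83 individuals):

```r
fst_per_variant(0.955, 100, 0, 83)
#> # A tibble: 4 x 6
#>   estimator        fst      a         b       c defined
#> 1 wright         0.914 NA     NA        NA      TRUE
#> 2 nei_gst        0.906 NA     NA        NA      TRUE
#> 3 weir_cockerham 0.951  0.456  0.000130  0.0235 TRUE
#> 4 hudson         0.955 NA     NA        NA      TRUE
```

All four estimators agree that essentially all variance at this site
lies between the populations.

## File formats

- **VCF 4.2** (`read_vcf()` / `write_vcf()`): biallelic SNVs, `GT`
  plus optional `DP:GQ:AD`; INFO keys `GENE`, `CSQ`, `DER`, `RS` carry
  gene assignment, consequence class, derived-allele orientation and
  rsID through a round trip.
- **Gene regions** (`load_gene_models()`): TSV `gene, chrom, start,
  end`, 1-based inclusive; variants are assigned within a 2 kb flank.
- **Reference panel** (`load_reference_frequencies()`): long TSV
  `variant, population, frequency, chromosomes`.
- **Scores**: TSV `variant, polyphen2, mutationtaster`, values in [0, 1].
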