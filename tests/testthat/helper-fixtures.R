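# Shared builders for in-code fixtures. Everything is generated at test
# time; no data files.

# A generic variant table: `n` biallelic missense SNVs on one chromosome.
test_variants <- function(n, gene = "GENE1", chrom = "chr1",
                          start = 1000L, step = 1000L,
                          consequence = "missense") {
  tibble::tibble(
    variant = sprintf("%s:v%02d", gene, seq_len(n)),
    chrom = chrom,
    pos = start + step * (seq_len(n) - 1L),
    ref = "A", alt = "G",
    gene = gene,
    consequence = consequence
  )
}

# A cohort built directly from a genotype matrix (ALT dosage).
test_cohort <- function(geno, variants = NULL, ...) {
  geno <- as.matrix(geno)
  if (is.null(variants)) variants <- test_variants(ncol(geno))
  colnames(geno) <- variants$variant
  new_cohort(geno, variants, ...)
}

# The three CPT2 missense sites and the published four-haplotype spec.
cpt2_loci <- function() {
  v <- carn_variants()
  v[v$variant %in% c("CPT2:p.F352C", "CPT2:p.V368I", "CPT2:p.R477W"), ]
}

# Independent brute-force HWE exact test: explicit multinomial
# probabilities conditional on allele counts, via log-factorials.
hwe_oracle <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  n_a <- 2 * hom_alt + het
  if (n_a == 0 || n_a == 2 * n) return(1)
  rare <- min(n_a, 2 * n - n_a)
  hs <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hs, function(h) {
    hom_rare <- (rare - h) / 2
    hom_common <- n - h - hom_rare
    lfactorial(n) - lfactorial(hom_rare) - lfactorial(h) -
      lfactorial(hom_common) + h * log(2) +
      lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  }, numeric(1))
  pr <- exp(lp)
  stopifnot(abs(sum(pr) - 1) < 1e-8)
  obs <- pr[match(het, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Pair-counting Mann-Whitney U (independent of the rank-sum route).
u_by_pairs <- function(xs, ys) {
  sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
}
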