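test_that("exact_count mode places exactly round(2N*p) derived alleles", {
  for (n in c(1L, 7L, 100L, 286L)) {
    v <- test_variants(7)
    v$freq <- c(0, 0.003, 0.03, 0.28, 0.5, 0.955, 1)
    ch <- simulate_cohort(cohort_spec(v, n, "exact_count", seed = 3))
    realized <- colSums(ch$geno)
    expect_equal(unname(realized), round(2 * n * v$freq))
    expect_false(anyNA(ch$geno))
  }
  # per-person mean at the high-frequency CPT1A-like variant
  v1 <- test_variants(1); v1$freq <- 0.955
  ch <- simulate_cohort(cohort_spec(v1, 100, "exact_count", seed = 1))
  expect_equal(mean(ch$geno[, 1]), 1.91)
})

test_that("frequency 0 gives an all-reference cohort", {
  v <- test_variants(2); v$freq <- 0
  ch <- simulate_cohort(cohort_spec(v, 40, "exact_count", seed = 5))
  expect_true(all(ch$geno == 0L))
  ch2 <- simulate_cohort(cohort_spec(v, 40, "hwe_sampling", seed = 5))
  expect_true(all(ch2$geno == 0L))
})

test_that("exact_count genotype configuration is HWE-closest", {
  v <- test_variants(1); v$freq <- 0.955
  ch <- simulate_cohort(cohort_spec(v, 100, "exact_count", seed = 2))
  g <- ch$geno[, 1]
  # 191 alleles: HWE expects 2*100*.955*.045 = 8.6 hets, parity forces 9
  expect_equal(sum(g == 1L), 9)
  expect_equal(sum(g == 2L), 91)
  # override for a target genotype configuration
  ch2 <- simulate_cohort(cohort_spec(v, 100, "exact_count", seed = 2),
                         het_counts = c("GENE1:v01" = 7L))
  expect_equal(sum(ch2$geno[, 1] == 1L), 7)
  expect_equal(sum(ch2$geno[, 1]), 191)
})

test_that("hwe_sampling realized frequencies are unbiased", {
  # 1000 replicate variants at p = 0.3 in a 500-individual cohort:
  # the grand mean frequency estimates p with SE ~ 0.0005
  v <- test_variants(1000)
  v$freq <- 0.3
  ch <- simulate_cohort(cohort_spec(v, 500, "hwe_sampling", seed = 11))
  expect_lt(abs(mean(ch$geno) / 2 - 0.3), 0.005)
})

test_that("simulation is reproducible bit-for-bit and seeds are mandatory", {
  v <- test_variants(3); v$freq <- c(0.1, 0.5, 0.9)
  a <- simulate_cohort(cohort_spec(v, 50, "hwe_sampling", seed = 9))
  b <- simulate_cohort(cohort_spec(v, 50, "hwe_sampling", seed = 9))
  expect_identical(a$geno, b$geno)
  expect_error(cohort_spec(v, 50, "hwe_sampling"), "seed")
})

test_that("cohort_spec rejects invalid frequencies and sizes", {
  v <- test_variants(1); v$freq <- 1.2
  expect_error(cohort_spec(v, 10, seed = 1), "\\[0, 1\\]")
  v$freq <- -0.1
  expect_error(cohort_spec(v, 10, seed = 1), "\\[0, 1\\]")
  v$freq <- 0.5
  expect_error(cohort_spec(v, 0, seed = 1), "positive")
})

test_that("haplotype cohorts carry phased truth consistent with genotypes", {
  loci <- cpt2_loci()
  spec <- haplotype_spec(loci, cpt2_haplotypes(), 100, seed = 21)
  ch <- simulate_haplotype_cohort(spec)
  expect_equal(dim(ch$haplotypes), c(100, 2))
  expect_true(all(nchar(ch$haplotypes) == 3))
  # unphased dosage must equal the allele content of the truth pair
  alt <- loci$alt
  for (i in c(1, 37, 100)) {
    expected <- (strsplit(ch$haplotypes[i, 1], "")[[1]] == alt) +
      (strsplit(ch$haplotypes[i, 2], "")[[1]] == alt)
    expect_identical(unname(ch$geno[i, ]), as.integer(expected))
  }
  # truth haplotype counts look multinomial(200, f): within 4 SD
  counts <- table(factor(ch$haplotypes,
                         levels = names(cpt2_haplotypes())))
  f <- cpt2_haplotypes()
  expect_true(all(abs(counts - 200 * f) <= 4 * sqrt(200 * f * (1 - f))))
})

test_that("a single haplotype at frequency 1 yields full homozygosity", {
  loci <- cpt2_loci()
  spec <- haplotype_spec(loci, c("TGC" = 1), 30, seed = 2)
  ch <- simulate_haplotype_cohort(spec)
  expect_true(all(ch$geno %in% c(0L, 2L)))
  expect_true(all(ch$haplotypes == "TGC"))
})

test_that("truth phase of a two-haplotype cohort gives D-prime 1", {
  loci <- test_variants(2)
  spec <- haplotype_spec(loci, c("GG" = 0.5, "AA" = 0.5), 80, seed = 4)
  ch <- simulate_haplotype_cohort(spec)
  haps <- c(ch$haplotypes)
  f_ab <- mean(haps == "GG")            # coupling haplotype (alt-alt)
  f_a <- mean(substr(haps, 1, 1) == "G")
  f_b <- mean(substr(haps, 2, 2) == "G")
  ld <- ld_from_freqs(f_ab, f_a, f_b)
  expect_equal(ld$dprime, 1)
})

test_that("haplotype frequencies must sum to one", {
  loci <- test_variants(2)
  expect_error(haplotype_spec(loci, c("GG" = 0.6, "AA" = 0.5), 10,
                              seed = 1), "sum to 1")
  expect_error(haplotype_spec(loci, c("G" = 1), 10, seed = 1),
               "one allele per locus")
})

test_that("admixture at lambda 0 reproduces the pure cohort", {
  v <- test_variants(5); v$freq <- c(0.05, 0.2, 0.5, 0.8, 0.95)
  w <- v; w$freq <- rev(v$freq)
  sa <- cohort_spec(v, 40, "hwe_sampling", seed = 8)
  sb <- cohort_spec(w, 40, "hwe_sampling", seed = 8)
  pure <- simulate_cohort(sa)
  adm <- simulate_admixed(sa, sb, lambda = 0, n = 40, seed = 8)
  expect_identical(pure$geno, adm$geno)
  expect_error(simulate_admixed(sa, sb, lambda = 1.5, n = 10, seed = 1),
               "lambda")
})

test_that("half-admixed individuals fall between the pure MDS clusters", {
  v <- test_variants(40); v$freq <- 0.05
  w <- v; w$freq <- 0.95
  sa <- cohort_spec(v, 30, "hwe_sampling", seed = 31)
  sb <- cohort_spec(w, 30, "hwe_sampling", seed = 32)
  a <- simulate_cohort(sa)
  b <- simulate_cohort(sb)
  adm <- simulate_admixed(sa, sb, lambda = 0.5, n = 6, seed = 33)
  rownames(adm$geno) <- paste0("ADM", seq_len(6))
  pool1 <- pool_cohorts(a, b)
  pool <- pool_cohorts(pool1$cohort, adm)
  m <- ibs_mds(pool$cohort)
  grp <- rep(c("A", "B", "adm"), c(30, 30, 6))
  centers <- tapply(m$MDS1, grp, mean)
  expect_true(centers[["adm"]] > min(centers[c("A", "B")]) &&
                centers[["adm"]] < max(centers[c("A", "B")]))
})

test_that("HWE exact p-values on sampled cohorts are super-uniform", {
  v <- test_variants(1000)
  v$freq <- 0.5
  ch <- simulate_cohort(cohort_spec(v, 100, "hwe_sampling", seed = 77))
  pvals <- apply(ch$geno, 2L, function(g) {
    hwe_exact_test(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
})
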