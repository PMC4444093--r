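make_metric_cohort <- function() {
  geno <- matrix(1L, nrow = 4, ncol = 3)
  ch <- test_cohort(geno)
  ch$dp <- matrix(100, 4, 3, dimnames = dimnames(ch$geno))
  ch$gq <- matrix(99, 4, 3, dimnames = dimnames(ch$geno))
  ch$altfrac <- matrix(0.5, 4, 3, dimnames = dimnames(ch$geno))
  ch
}

test_that("genotypes at the depth boundary are masked, others untouched", {
  ch <- make_metric_cohort()
  ch$dp[1, 1] <- 19
  ch$dp[2, 2] <- 20   # exactly at threshold: kept
  out <- filter_genotypes(ch)
  expect_true(is.na(out$geno[1, 1]))
  expect_equal(sum(is.na(out$geno)), 1L)
  expect_equal(out$qc_log$n_masked, 1L)
})

test_that("a fully clean cohort passes unchanged and filtering is idempotent", {
  ch <- make_metric_cohort()
  out <- filter_genotypes(ch)
  expect_identical(out$geno, ch$geno)
  ch$dp[1, ] <- 5
  ch$gq[2, 1] <- 3
  once <- filter_genotypes(ch)
  twice <- filter_genotypes(once)
  expect_identical(once$geno, twice$geno)
  expect_equal(twice$qc_log$n_masked, 0L)
})

test_that("exactly the planted failing genotypes are masked", {
  geno <- matrix(1L, nrow = 5, ncol = 4)
  geno[5, 4] <- 0L
  ch <- test_cohort(geno, test_variants(4))
  ch$dp <- matrix(50, 5, 4, dimnames = dimnames(ch$geno))
  ch$gq <- matrix(50, 5, 4, dimnames = dimnames(ch$geno))
  ch$altfrac <- matrix(0.5, 5, 4, dimnames = dimnames(ch$geno))
  ch$dp[1, 1:3] <- 10          # 3 depth failures
  ch$gq[2, 1:2] <- 9           # 2 quality failures
  ch$altfrac[3, 1] <- 0.1      # 1 alt-fraction failure on a het call
  ch$altfrac[4, 2] <- 0.24     # 1 more, just under the threshold
  ch$altfrac[5, 4] <- 0.0      # hom-ref: alt-fraction rule must NOT apply
  out <- filter_genotypes(ch)
  expect_equal(out$qc_log$n_masked, 7L)
  expect_false(is.na(out$geno[5, 4]))
})

test_that("allele frequency counts derived alleles over called chromosomes", {
  g <- c(rep(2L, 91), rep(1L, 9))
  ch <- test_cohort(matrix(g, ncol = 1), test_variants(1))
  af <- allele_frequency(ch)
  expect_equal(af$frequency, 0.955)
  expect_equal(af$derived_alleles, 191)
  expect_equal(af$n_het, 9)
  # invariant under individual reordering
  set.seed(6)
  ch2 <- cohort_subset(ch, individuals = sample(100))
  expect_equal(allele_frequency(ch2)$frequency, 0.955)
  # missing genotypes shrink the denominator
  ch$geno[1:10, 1] <- NA_integer_
  af3 <- allele_frequency(ch)
  expect_equal(af3$called_chromosomes, 180)
  # all hom-ref
  ch0 <- test_cohort(matrix(0L, 10, 1), test_variants(1))
  expect_equal(allele_frequency(ch0)$frequency, 0)
  # all-missing errors
  chm <- test_cohort(matrix(NA_integer_, 5, 1), test_variants(1))
  expect_error(allele_frequency(chm), "no called genotypes")
})

test_that("derived-allele orientation flips dosages where derived is REF", {
  v <- test_variants(1)
  v$derived_is_alt <- FALSE
  ch <- test_cohort(matrix(c(0L, 0L, 2L, 1L), ncol = 1), v)
  # ALT dosage mean = 3/8; derived = REF so derived frequency = 5/8
  expect_equal(allele_frequency(ch)$frequency, 5 / 8)
})

test_that("HWE exact test matches enumeration and known configurations", {
  expect_equal(hwe_exact_test(0, 0, 40), 1)    # monomorphic
  expect_equal(hwe_exact_test(25, 50, 25), 1)  # modal configuration
  expect_lt(hwe_exact_test(50, 0, 50), 1e-20)
  expect_error(hwe_exact_test(-1, 0, 3), "nonnegative")
  # exhaustive agreement with the brute-force oracle for N <= 50
  for (n in c(5L, 17L, 33L, 50L)) {
    for (n_alt in seq(0L, n)) {          # rare-allele count sweep
      hs <- seq(n_alt %% 2L, n_alt, by = 2L)
      for (h in hs) {
        hom_alt <- (n_alt - h) / 2
        hom_ref <- n - h - hom_alt
        expect_equal(hwe_exact_test(hom_ref, h, hom_alt),
                     hwe_oracle(hom_ref, h, hom_alt),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("concordance is 1 for identical cohorts and counts mismatches", {
  v <- test_variants(10)
  set.seed(19)
  ch <- test_cohort(matrix(rbinom(100, 2, 0.4), 10, 10), v)
  expect_equal(concordance(ch, ch)$concordance, 1)
  # plant exactly 23 mismatches among 100 intronic comparisons
  other <- ch
  flip <- cbind(rep(1:10, length.out = 23),
                rep(1:10, each = 3)[1:23])
  for (r in seq_len(23)) {
    ij <- flip[r, ]
    other$geno[ij[1], ij[2]] <- (ch$geno[ij[1], ij[2]] + 1L) %% 3L
  }
  cls <- stats::setNames(rep("intronic", 10), v$variant)
  res <- concordance(ch, other, cls)
  expect_equal(res$concordance[res$class == "intronic"], 0.77)
  # disjoint variant sets error
  shifted <- test_cohort(ch$geno, test_variants(10, gene = "GENE2"))
  expect_error(concordance(ch, shifted), "no overlapping variants")
})

test_that("IBS-MDS separates fixed clusters and respects duplicates", {
  # 2 + 2 individuals with disjoint fixed alleles: distance 1 across,
  # 0 within; classical scaling puts the clusters 1 apart on axis 1
  g <- rbind(matrix(0L, 2, 6), matrix(2L, 2, 6))
  ch <- test_cohort(g, test_variants(6))
  m <- ibs_mds(ch)
  expect_equal(m$MDS1[1], m$MDS1[2], tolerance = 1e-10)
  expect_equal(m$MDS1[3], m$MDS1[4], tolerance = 1e-10)
  expect_equal(abs(m$MDS1[1] - m$MDS1[3]), 1, tolerance = 1e-8)
  expect_error(ibs_mds(cohort_subset(ch, individuals = 1:2)),
               "at least 3")
})

test_that("ancestry outlier flagging finds planted admixed individuals", {
  v <- test_variants(50); v$freq <- 0.02
  w <- v; w$freq <- 0.98
  sa <- cohort_spec(v, 104, "hwe_sampling", seed = 41)
  sb <- cohort_spec(w, 104, "hwe_sampling", seed = 42)
  pure <- simulate_cohort(sa)
  adm <- simulate_admixed(sa, sb, lambda = 0.5, n = 9, seed = 43)
  rownames(adm$geno) <- paste0("ADM", 1:9)
  pool <- pool_cohorts(pure, adm)
  m <- ibs_mds(pool$cohort)
  labels <- stats::setNames(rep("inuit", 113), m$individual)
  flags <- flag_ancestry_outliers(m, labels)
  expect_equal(sort(flags$individual[flags$flagged]),
               sort(paste0("ADM", 1:9)))
  # k = Inf flags nothing
  none <- flag_ancestry_outliers(m, labels, k = Inf)
  expect_false(any(none$flagged))
})

test_that("individuals exactly at the medoid are never flagged", {
  coords <- tibble::tibble(individual = paste0("S", 1:4),
                           MDS1 = 0, MDS2 = 0)
  class(coords) <- c("mds_coords", class(coords))
  labels <- stats::setNames(rep("c1", 4), coords$individual)
  expect_false(any(flag_ancestry_outliers(coords, labels)$flagged))
  expect_error(flag_ancestry_outliers(coords, labels[1:2]),
               "fewer than 3")
})
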