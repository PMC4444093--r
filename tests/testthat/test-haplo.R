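test_that("phase-unambiguous genotypes are solved in one EM pass", {
  # all homozygous: haplotype frequencies are the observed proportions
  g <- rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(0L, 2L))
  em <- em_haplotype_frequencies(g)
  expect_equal(em$iterations, 1L)
  expect_true(em$converged)
  expect_equal(unname(em$frequencies_full[c("aa", "AA", "aA")]),
               c(0.5, 0.25, 0.25))
})

test_that("EM matches a simplex grid search on the two-locus fixture", {
  g <- rbind(matrix(rep(c(2L, 2L), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(0L, 0L), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(1L, 1L), 10), ncol = 2, byrow = TRUE))
  em <- em_haplotype_frequencies(g, tol = 1e-12)
  # independent oracle: coarse grid over the 4-haplotype simplex,
  # refined locally; likelihood written out from the three genotype
  # classes (double het splits into two phase resolutions)
  loglik <- function(f) {
    # f = c(f_ab, f_aB, f_Ab, f_AB)
    20 * log(max(f[4]^2, 1e-300)) + 20 * log(max(f[1]^2, 1e-300)) +
      10 * log(max(2 * f[1] * f[4] + 2 * f[2] * f[3], 1e-300))
  }
  best <- c(-Inf, 0, 0, 0, 0)
  step <- 0.02
  for (a in seq(0, 1, step)) for (b in seq(0, 1 - a, step)) {
    for (c_ in seq(0, 1 - a - b, step)) {
      f <- c(a, b, c_, 1 - a - b - c_)
      ll <- loglik(f)
      if (ll > best[1]) best <- c(ll, f)
    }
  }
  centre <- best[2:5]
  for (a in seq(max(0, centre[1] - 0.03), min(1, centre[1] + 0.03),
                0.001)) {
    for (b in seq(max(0, centre[2] - 0.03), min(1 - a, centre[2] + 0.03),
                  0.001)) {
      for (c_ in seq(max(0, centre[3] - 0.03),
                     min(1 - a - b, centre[3] + 0.03), 0.001)) {
        f <- c(a, b, c_, 1 - a - b - c_)
        ll <- loglik(f)
        if (ll > best[1]) best <- c(ll, f)
      }
    }
  }
  grid_f <- stats::setNames(best[2:5], c("aa", "aA", "Aa", "AA"))
  em_f <- em$frequencies_full[names(grid_f)]
  em_f[is.na(em_f)] <- 0
  expect_lt(max(abs(unname(em_f) - unname(grid_f))), 1e-3)
  # log-likelihood trace is monotone non-decreasing
  expect_true(all(diff(em$loglik) >= -1e-9))
})

test_that("EM recovers the published four-haplotype structure", {
  loci <- cpt2_loci()
  truth <- cpt2_haplotypes()
  ch <- simulate_haplotype_cohort(haplotype_spec(loci, truth, 100,
                                                 seed = 5))
  em <- em_haplotype_frequencies(ch)
  gac <- em$frequencies_full["GAC"]
  expect_lt(abs(gac - 0.28), 3 * sqrt(0.28 * 0.72 / 200))
  # tidy/glance accessors
  td <- tidy(em)
  expect_true(all(c("haplotype", "frequency") %in% names(td)))
  expect_equal(sum(td$frequency), 1, tolerance = 1e-6)
  expect_true(glance(em)$converged)
})

test_that("EM error against realized truth haplotypes is small, many seeds", {
  loci <- cpt2_loci()
  truth <- cpt2_haplotypes()
  for (s in 1:25) {
    ch <- simulate_haplotype_cohort(haplotype_spec(loci, truth, 100,
                                                   seed = s))
    em <- em_haplotype_frequencies(ch)
    realized <- table(factor(ch$haplotypes, levels = names(truth))) / 200
    est <- em$frequencies_full[names(truth)]
    est[is.na(est)] <- 0
    # phase-ambiguity error only; 3 SE bound against the population truth
    expect_lt(max(abs(est - as.numeric(realized))), 0.03)
    se <- sqrt(truth * (1 - truth) / 200)
    expect_true(all(abs(est - truth) <= 3 * se))
  }
})

test_that("EM input validation catches degenerate loci", {
  g <- cbind(c(1L, 0L, 2L), c(NA_integer_, NA_integer_, NA_integer_))
  expect_error(em_haplotype_frequencies(g), "no called genotypes")
  expect_error(em_haplotype_frequencies(matrix(0L, 5, 1)), "at least 2")
  expect_error(em_haplotype_frequencies(matrix(0L, 5, 13)), "12 loci")
  g2 <- cbind(c(1L, 0L, NA), c(1L, 0L, 1L))
  expect_warning(em_haplotype_frequencies(g2), "dropped")
})

test_that("closed-form LD statistics match hand arithmetic", {
  ld <- ld_from_freqs(0.4, 0.5, 0.5)
  expect_equal(ld$D, 0.15)
  expect_equal(ld$dprime, 0.6)
  expect_equal(ld$r2, 0.36)
  indep <- ld_from_freqs(0.5 * 0.3, 0.5, 0.3)
  expect_equal(indep$D, 0)
  expect_equal(indep$dprime, 0)
  coup <- ld_from_freqs(0.3, 0.3, 0.3)  # only coupling haplotypes
  expect_equal(coup$dprime, 1)
  expect_error(ld_from_freqs(0, 0, 0.5), "monomorphic")
})

test_that("D-prime and r-squared stay within their bounds", {
  set.seed(23)
  for (i in 1:200) {
    fa <- runif(1, 0.05, 0.95); fb <- runif(1, 0.05, 0.95)
    lo <- max(-fa * fb, -(1 - fa) * (1 - fb))
    hi <- min(fa * (1 - fb), (1 - fa) * fb)
    d <- runif(1, lo, hi)
    ld <- ld_from_freqs(fa * fb + d, fa, fb)
    expect_true(ld$dprime >= -1 - 1e-9 && ld$dprime <= 1 + 1e-9)
    expect_true(ld$r2 >= -1e-12 && ld$r2 <= 1 + 1e-9)
    expect_lte(ld$r2, abs(ld$dprime) + 1e-9)
  }
})

test_that("ld_pair reports strong LD with high LOD on coupled loci", {
  loci <- test_variants(2)
  ch <- simulate_haplotype_cohort(
    haplotype_spec(loci, c("GG" = 0.6, "AA" = 0.4), 60, seed = 3))
  res <- ld_pair(ch, loci$variant[1], loci$variant[2])
  expect_equal(res$dprime, 1, tolerance = 1e-6)
  expect_gt(res$lod, 2)
  expect_gte(res$ci_low, 0.6)
  expect_gte(res$ci_high, 0.98)
  # bootstrap CI agrees qualitatively
  bs <- ld_pair(ch, loci$variant[1], loci$variant[2],
                ci_method = "bootstrap", seed = 4)
  expect_gt(bs$ci_low, 0.6)
})

test_that("independent loci show no LD and wide recombination evidence", {
  loci <- test_variants(2)
  haps <- c("AA" = 0.25, "AG" = 0.25, "GA" = 0.25, "GG" = 0.25)
  ch <- simulate_haplotype_cohort(haplotype_spec(loci, haps, 200,
                                                 seed = 9))
  res <- ld_pair(ch, loci$variant[1], loci$variant[2])
  expect_lt(abs(res$D), 0.05)
  expect_lt(res$ci_high, 0.9)
})

test_that("Gabriel blocks find the tight trio and skip equilibrium markers", {
  loci <- test_variants(4)
  loci$pos <- c(1000L, 3000L, 8000L, 500000L)
  # loci 1-3 perfectly coupled, locus 4 independent
  haps <- c("GGGA" = 0.3, "GGGG" = 0.3, "AAAA" = 0.2, "AAAG" = 0.2)
  ch <- simulate_haplotype_cohort(haplotype_spec(loci, haps, 120,
                                                 seed = 17))
  blocks <- gabriel_blocks(ch)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$first_marker, "GENE1:v01")
  expect_equal(blocks$last_marker, "GENE1:v03")
  expect_equal(blocks$n_markers, 3L)
  # equilibrium-only markers yield no blocks
  eq <- c("AA" = 0.25, "AG" = 0.25, "GA" = 0.25, "GG" = 0.25)
  ch2 <- simulate_haplotype_cohort(haplotype_spec(test_variants(2), eq,
                                                  200, seed = 18))
  expect_equal(nrow(gabriel_blocks(ch2)), 0L)
  # two markers in complete LD form one block
  ch3 <- simulate_haplotype_cohort(
    haplotype_spec(test_variants(2), c("GG" = 0.6, "AA" = 0.4), 80,
                   seed = 19))
  b3 <- gabriel_blocks(ch3)
  expect_equal(nrow(b3), 1L)
  expect_equal(b3$n_markers, 2L)
  expect_error(gabriel_blocks(ch, variants = rev(loci$variant)),
               "sorted")
})

test_that("low-MAF markers are excluded from informative pair counting", {
  loci <- test_variants(3)
  # middle marker at MAF 0.03 (dashed-line exclusion); flanking pair
  # in complete LD
  haps <- c("GAG" = 0.57, "GGG" = 0.03, "AAA" = 0.40)
  ch <- simulate_haplotype_cohort(haplotype_spec(loci, haps, 150,
                                                 seed = 27))
  blocks <- gabriel_blocks(ch)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$n_markers, 3L)   # span includes the excluded marker
  expect_equal(blocks$n_informative, 1L)
})

test_that("haplotype frequency comparisons match their oracles", {
  # one-sample binomial tail against the comparison frequency
  res <- haplotype_freq_compare(132, 200, freq_b = 0.458)
  oracle <- sum(stats::dbinom(132:200, 200, 0.458))
  expect_equal(res$p, oracle, tolerance = 1e-12)
  # two-proportion z, one-sided: same order as a small printed p
  res2 <- haplotype_freq_compare(132, 200, count_b = 76, chrom_b = 166,
                                 mode = "two_proportion")
  expect_gt(res2$p, 3e-5)
  expect_lt(res2$p, 2e-4)
  # equal frequencies: p around one half or larger
  eq <- haplotype_freq_compare(100, 200, freq_b = 0.5)
  expect_gte(eq$p, 0.5)
  # degenerate null
  zero <- haplotype_freq_compare(0, 200, freq_b = 0)
  expect_equal(zero$p, 1)
  expect_error(haplotype_freq_compare(5, 0, freq_b = 0.2), "zero")
})
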