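#' Per-variant FST between two populations
#'
#' Four standard estimators of the fixation index from two population
#' samples; all are reported because published per-variant values rarely
#' state which was used and the estimators differ at small sample sizes:
#'
#' * `wright`: `(HT - HS) / HT` with the *unweighted* pooled frequency.
#' * `nei_gst`: same contrast with the sample-size-weighted pooled
#'   frequency and weighted mean HS.
#' * `weir_cockerham`: the theta = a / (a + b + c) variance-component
#'   estimator (two-population form); observed heterozygosity from
#'   genotypes when supplied, HWE-expected otherwise. Components are
#'   returned for multi-locus pooling.
#' * `hudson`: ratio-of-moments numerator/denominator estimator.
#'
#' A site monomorphic for the same allele in both populations has no
#' defined differentiation and returns `NA` estimates with
#' `defined = FALSE`.
#'
#' @param p1,p2 Derived-allele frequencies in the two populations.
#' @param n1,n2 Sample sizes in *individuals* (>= 2 each).
#' @param het_obs Optional numeric(2): observed heterozygote proportions;
#'   defaults to the HWE expectation `2p(1-p)`.
#' @param estimator One of the four names or `"all"`.
#' @return A tibble with `estimator`, `fst`, the `weir_cockerham`
#'   components `a`, `b`, `c` (NA for the analytical estimators) and
#'   `defined`.
#' @export
fst_per_variant <- function(p1, n1, p2, n2, het_obs = NULL,
                            estimator = c("all", "wright", "nei_gst",
                                          "weir_cockerham", "hudson")) {
  estimator <- match.arg(estimator)
  if (n1 < 2 || n2 < 2) stop("sample sizes must be >= 2 individuals")
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  mono <- (p1 == p2) && (p1 %in% c(0, 1))
  p <- c(p1, p2); n <- c(n1, n2)
  h <- if (is.null(het_obs)) 2 * p * (1 - p) else het_obs
  ests <- list()

  pbar_u <- mean(p)
  ht_u <- 2 * pbar_u * (1 - pbar_u)
  hs_u <- mean(2 * p * (1 - p))
  ests$wright <- if (ht_u > 0) (ht_u - hs_u) / ht_u else NA_real_

  w <- n / sum(n)
  pbar_w <- sum(w * p)
  ht_w <- 2 * pbar_w * (1 - pbar_w)
  hs_w <- sum(w * 2 * p * (1 - p))
  ests$nei_gst <- if (ht_w > 0) (ht_w - hs_w) / ht_w else NA_real_

  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  ests$weir_cockerham <- if ((a + b + cc) > 0) a / (a + b + cc) else NA_real_

  m1 <- 2 * n1; m2 <- 2 * n2  # chromosomes
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (m1 - 1) - p2 * (1 - p2) / (m2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ests$hudson <- if (den > 0) num / den else NA_real_

  keep <- if (estimator == "all") names(ests) else estimator
  out <- tibble::tibble(
    estimator = keep,
    fst = if (mono) NA_real_ else unlist(ests[keep], use.names = FALSE),
    a = ifelse(keep == "weir_cockerham" & !mono, a, NA_real_),
    b = ifelse(keep == "weir_cockerham" & !mono, b, NA_real_),
    c = ifelse(keep == "weir_cockerham" & !mono, cc, NA_real_),
    defined = !mono & !is.na(unlist(ests[keep], use.names = FALSE))
  )
  out
}

#' Per-variant inbreeding coefficient FIS
#'
#' `FIS = 1 - H_obs / H_exp`. By default the expected heterozygosity
#' carries the small-sample (unbiased) correction
#' `H_exp = 2 p (1 - p) * 2N / (2N - 1)`. Monomorphic sites have no
#' defined FIS and return `NA`.
#'
#' @param hom_ref,het,hom_alt Genotype counts.
#' @param unbiased Apply the `2N/(2N-1)` correction (default TRUE).
#' @return A one-row tibble: `fis`, `h_obs`, `h_exp`, `defined`.
#' @export
fis_per_variant <- function(hom_ref, het, hom_alt, unbiased = TRUE) {
  if (any(c(hom_ref, het, hom_alt) < 0)) stop("counts must be nonnegative")
  n <- hom_ref + het + hom_alt
  if (n < 2) stop("at least 2 individuals are required")
  p <- (2 * hom_alt + het) / (2 * n)
  if (p %in% c(0, 1)) {
    return(tibble::tibble(fis = NA_real_, h_obs = het / n, h_exp = 0,
                          defined = FALSE))
  }
  h_obs <- het / n
  h_exp <- 2 * p * (1 - p) * (if (unbiased) 2 * n / (2 * n - 1) else 1)
  tibble::tibble(fis = 1 - h_obs / h_exp, h_obs = h_obs, h_exp = h_exp,
                 defined = TRUE)
}

#' Multi-locus FST summaries
#'
#' Two poolings of per-locus estimates are reported: `ratio_of_sums`
#' pools the Weir-Cockerham variance components as
#' `sum(a) / sum(a + b + c)` (the recommended weighting), and
#' `arithmetic_mean` averages the defined per-locus estimates.
#' Undefined (monomorphic) loci are excluded, not treated as 0.
#'
#' @param per_locus Tibble with one row per locus: column `fst` and,
#'   for the ratio-of-sums method, components `a`, `b`, `c`.
#' @return A tibble: `method`, `fst`, `n_loci`, `defined`.
#' @export
multilocus_fst <- function(per_locus) {
  if (nrow(per_locus) == 0L) stop("no loci supplied")
  ok <- !is.na(per_locus$fst)
  am <- if (any(ok)) mean(per_locus$fst[ok]) else NA_real_
  have_abc <- all(c("a", "b", "c") %in% names(per_locus))
  if (have_abc) {
    okc <- ok & !is.na(per_locus$a)
    den <- sum(per_locus$a[okc] + per_locus$b[okc] + per_locus$c[okc])
    ros <- if (sum(okc) && den > 0) sum(per_locus$a[okc]) / den else NA_real_
    n_ros <- sum(okc)
  } else {
    ros <- NA_real_; n_ros <- 0L
  }
  tibble::tibble(
    method = c("ratio_of_sums", "arithmetic_mean"),
    fst = c(ros, am),
    n_loci = c(n_ros, sum(ok)),
    defined = !is.na(c(ros, am))
  )
}

#' FST and FIS over all variants of two cohorts
#'
#' Convenience wrapper computing per-variant estimates from two cohorts'
#' genotype matrices (derived orientation), with observed heterozygosity
#' feeding the Weir-Cockerham and FIS estimates.
#'
#' @param cohort_a,cohort_b Cohorts sharing a variant set.
#' @param estimator Estimator passed to [fst_per_variant()].
#' @return A tibble of class `fst_result`: one row per variant and
#'   estimator, with `fst`, components, and `fis` (computed in cohort A).
#' @export
fst_table <- function(cohort_a, cohort_b, estimator = "all") {
  fa <- allele_frequency(cohort_a)
  b2 <- cohort_subset(cohort_b, variants = colnames(cohort_a$geno))
  fb <- allele_frequency(b2)
  rows <- purrr::map_dfr(seq_len(nrow(fa)), function(i) {
    est <- fst_per_variant(
      fa$frequency[i], fa$called_chromosomes[i] / 2,
      fb$frequency[i], fb$called_chromosomes[i] / 2,
      het_obs = c(fa$n_het[i] / (fa$called_chromosomes[i] / 2),
                  fb$n_het[i] / (fb$called_chromosomes[i] / 2)),
      estimator = estimator)
    fis <- fis_per_variant(fa$n_hom_ref[i], fa$n_het[i], fa$n_hom_alt[i])
    dplyr::bind_cols(tibble::tibble(variant = fa$variant[i],
                                    gene = fa$gene[i]),
                     est, tibble::tibble(fis = fis$fis))
  })
  class(rows) <- c("fst_result", class(rows))
  rows
}

#' Randomization significance for F-statistics
#'
#' For FST, individuals are permuted between the two population labels
#' and the multi-locus statistic recomputed; for FIS, alleles are
#' shuffled among individuals within the population (breaking genotypic
#' correlation while preserving allele counts), testing deviation from 0.
#' Empirical two-sided p with the add-one rule, guaranteeing
#' `p >= 1/(n_rand + 1)`.
#'
#' @param cohort_a,cohort_b Cohorts sharing a variant set (`cohort_b`
#'   ignored for `statistic = "fis"`).
#' @param statistic `"fst"` (multi-locus Weir-Cockerham ratio of sums) or
#'   `"fis"` (mean per-variant FIS in cohort A).
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed.
#' @return A one-row tibble: `statistic`, `observed`, `p_rand`, `n_rand`.
#' @export
fst_randomization_test <- function(cohort_a, cohort_b = NULL,
                                   statistic = c("fst", "fis"),
                                   n_rand = 1000, seed) {
  statistic <- match.arg(statistic)
  if (n_rand < 1) stop("n_rand must be >= 1")
  if (missing(seed)) stop("an integer seed is mandatory")
  set.seed(as.integer(seed))
  if (statistic == "fst") {
    if (is.null(cohort_b)) stop("cohort_b required for FST")
    b2 <- cohort_subset(cohort_b, variants = colnames(cohort_a$geno))
    ga <- derived_dosage(cohort_a); gb <- derived_dosage(b2)
    pooled <- rbind(ga, gb)
    na <- nrow(ga)
    stat_fun <- function(idx_a) {
      g1 <- pooled[idx_a, , drop = FALSE]
      g2 <- pooled[-idx_a, , drop = FALSE]
      comps <- purrr::map_dfr(seq_len(ncol(pooled)), function(j) {
        c1 <- g1[, j]; c2 <- g2[, j]
        n1 <- sum(!is.na(c1)); n2 <- sum(!is.na(c2))
        p1 <- mean(c1, na.rm = TRUE) / 2; p2 <- mean(c2, na.rm = TRUE) / 2
        if ((p1 == p2 && p1 %in% c(0, 1)) || n1 < 2 || n2 < 2) {
          return(tibble::tibble(fst = NA_real_, a = NA_real_,
                                b = NA_real_, c = NA_real_))
        }
        fst_per_variant(p1, n1, p2, n2,
                        het_obs = c(mean(c1 == 1L, na.rm = TRUE),
                                    mean(c2 == 1L, na.rm = TRUE)),
                        estimator = "weir_cockerham")[, c("fst", "a",
                                                          "b", "c")]
      })
      multilocus_fst(comps)$fst[1]
    }
    obs <- stat_fun(seq_len(na))
    perms <- vapply(seq_len(n_rand), function(b) {
      stat_fun(sample.int(nrow(pooled), na))
    }, numeric(1))
  } else {
    g <- derived_dosage(cohort_a)
    fis_mean <- function(gm) {
      vals <- apply(gm, 2L, function(col) {
        col <- col[!is.na(col)]
        f <- fis_per_variant(sum(col == 0L), sum(col == 1L),
                             sum(col == 2L))
        f$fis
      })
      mean(vals, na.rm = TRUE)
    }
    obs <- fis_mean(g)
    perms <- vapply(seq_len(n_rand), function(b) {
      shuffled <- apply(g, 2L, function(col) {
        ok <- !is.na(col)
        alleles <- sample(rep(c(rep(1L, sum(col[ok])),
                                rep(0L, 2L * sum(ok) - sum(col[ok])))))
        col[ok] <- alleles[seq_len(sum(ok))] +
          alleles[sum(ok) + seq_len(sum(ok))]
        col
      })
      fis_mean(shuffled)
    }, numeric(1))
  }
  p <- (1 + sum(abs(perms) >= abs(obs) - 1e-12, na.rm = TRUE)) /
    (1 + n_rand)
  tibble::tibble(statistic = statistic, observed = obs, p_rand = p,
                 n_rand = n_rand)
}
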