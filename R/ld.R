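#' Pairwise LD statistics from haplotype frequencies
#'
#' Closed-form two-locus linkage disequilibrium given the frequency of the
#' A-B coupling haplotype and the two allele frequencies:
#' `D = f(AB) - f(A) f(B)`, `D' = D / Dmax` with the sign-appropriate
#' bound, and `r^2 = D^2 / (pA qA pB qB)`.
#'
#' @param f_ab Frequency of the haplotype carrying allele A and allele B.
#' @param f_a,f_b Allele frequencies of A and B.
#' @return A one-row tibble: `D`, `dprime`, `r2`.
#' @export
ld_from_freqs <- function(f_ab, f_a, f_b) {
  if (f_a %in% c(0, 1) || f_b %in% c(0, 1)) {
    stop("LD is undefined at a monomorphic locus")
  }
  D <- f_ab - f_a * f_b
  dmax <- if (D >= 0) {
    min(f_a * (1 - f_b), (1 - f_a) * f_b)
  } else {
    min(f_a * f_b, (1 - f_a) * (1 - f_b))
  }
  dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (f_a * (1 - f_a) * f_b * (1 - f_b))
  tibble::tibble(D = D, dprime = dprime, r2 = r2)
}

# Two-locus haplotype frequencies (h00, h01, h10, h11) from allele
# frequencies and D, clamped away from zero and renormalised.
hap4 <- function(p_a, p_b, D) {
  h <- c(`00` = (1 - p_a) * (1 - p_b) + D, `01` = (1 - p_a) * p_b - D,
         `10` = p_a * (1 - p_b) - D, `11` = p_a * p_b + D)
  h <- pmax(h, 1e-12)
  h / sum(h)
}

# Genotype-data log-likelihood for a 2-locus pair under given haplotype
# frequencies (HWE).
loglik2 <- function(geno2, h) {
  ex <- hap_expand(geno2)
  freq_by_code <- stats::setNames(as.numeric(h), c(0, 2, 1, 3))
  # codes: bit1 = locus1 allele, bit2 = locus2 allele
  # h names "00","01","10","11" (locus1, locus2) -> codes 0, 2, 1, 3
  hap_loglik(ex, freq_by_code)
}

#' LD statistics for a pair of variants in a cohort
#'
#' Estimates the two-locus haplotype frequencies by EM
#' ([em_haplotype_frequencies()]), then reports D, D', r-squared, the LOD
#' score (log10 likelihood ratio of the estimated haplotype frequencies
#' against linkage equilibrium, given the genotype data) and a D'
#' confidence interval.
#'
#' The D' confidence interval comes from the profile likelihood over
#' |D'| on a grid, with allele frequencies held at their sample
#' estimates: the normalized likelihood is treated as a density and the
#' 5th/95th percentiles reported (the convention used for
#' confidence-interval-based block finding). A seeded bootstrap
#' (`ci_method = "bootstrap"`) is available as an alternative.
#'
#' @param cohort A `cohort`.
#' @param var1,var2 Variant keys.
#' @param ci_method `"profile"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples (when `ci_method = "bootstrap"`).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble: `var1`, `var2`, `D`, `dprime`, `r2`, `lod`,
#'   `ci_low`, `ci_high`.
#' @export
ld_pair <- function(cohort, var1, var2, ci_method = c("profile",
                                                      "bootstrap"),
                    n_boot = 200, seed = 1L) {
  ci_method <- match.arg(ci_method)
  geno2 <- cohort$geno[, c(var1, var2), drop = FALSE]
  geno2 <- geno2[stats::complete.cases(geno2), , drop = FALSE]
  p_a <- mean(geno2[, 1]) / 2
  p_b <- mean(geno2[, 2]) / 2
  if (p_a %in% c(0, 1) || p_b %in% c(0, 1)) {
    return(tibble::tibble(var1 = var1, var2 = var2, D = NA_real_,
                          dprime = NA_real_, r2 = NA_real_,
                          lod = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_))
  }
  em <- em_haplotype_frequencies(geno2, tol = 1e-10)
  f <- em$frequencies_full
  codes <- em$codes
  f11 <- sum(f[codes == 3L])
  ld <- ld_from_freqs(f11, p_a, p_b)
  ll1 <- em$loglik[length(em$loglik)]
  ll0 <- loglik2(geno2, hap4(p_a, p_b, 0))
  lod <- (ll1 - ll0) / log(10)
  ci <- dprime_ci(geno2, p_a, p_b, sign(ld$D), ci_method, n_boot, seed)
  tibble::tibble(var1 = var1, var2 = var2, D = ld$D, dprime = ld$dprime,
                 r2 = ld$r2, lod = lod, ci_low = ci[1], ci_high = ci[2])
}

dprime_ci <- function(geno2, p_a, p_b, d_sign, method, n_boot, seed) {
  if (d_sign == 0) d_sign <- 1
  if (method == "profile") {
    grid <- seq(0, 1, by = 0.01)
    dmax <- if (d_sign > 0) {
      min(p_a * (1 - p_b), (1 - p_a) * p_b)
    } else {
      min(p_a * p_b, (1 - p_a) * (1 - p_b))
    }
    ll <- vapply(grid, function(d) {
      loglik2(geno2, hap4(p_a, p_b, d_sign * d * dmax))
    }, numeric(1))
    lik <- exp(ll - max(ll))
    cdf <- cumsum(lik) / sum(lik)
    c(grid[which(cdf >= 0.05)[1]], grid[which(cdf >= 0.95)[1]])
  } else {
    set.seed(as.integer(seed))
    n <- nrow(geno2)
    dp <- vapply(seq_len(n_boot), function(b) {
      g <- geno2[sample.int(n, n, replace = TRUE), , drop = FALSE]
      pa <- mean(g[, 1]) / 2; pb <- mean(g[, 2]) / 2
      if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
      em <- em_haplotype_frequencies(g, tol = 1e-8)
      f11 <- sum(em$frequencies_full[em$codes == 3L])
      abs(ld_from_freqs(f11, pa, pb)$dprime)
    }, numeric(1))
    stats::quantile(dp, c(0.05, 0.95), na.rm = TRUE, names = FALSE)
  }
}

#' Gabriel-style LD blocks from D' confidence intervals
#'
#' Pairs of markers are "strong LD" when the D' confidence interval has
#' lower bound >= `strong_low` and upper bound >= `strong_high`, and show
#' "strong evidence of recombination" when the upper bound <
#' `recomb_high`; other pairs are uninformative. Markers with minor
#' allele frequency below `maf_exclude` are excluded from pair counting
#' (the dashed-line convention). A candidate span of markers is accepted
#' as a block when its outermost informative pair is strong and at least
#' `frac_strong` of its informative pairs are strong; maximal
#' non-overlapping blocks are reported left to right.
#'
#' @param cohort A `cohort`; marker order follows genomic position.
#' @param variants Variant keys to consider (default: all), must be
#'   position-sorted on one chromosome.
#' @param maf_exclude MAF below which markers are uninformative
#'   (default 0.05).
#' @param strong_low,strong_high CI bounds defining strong LD
#'   (defaults 0.6 and 0.98).
#' @param recomb_high CI upper bound below which a pair shows strong
#'   recombination (default 0.9).
#' @param frac_strong Minimum fraction of informative pairs in strong LD
#'   (default 0.95).
#' @return A tibble of blocks: `first_marker`, `last_marker`,
#'   `n_markers`, `span_bp`, `n_informative`, `frac_strong`.
#' @export
gabriel_blocks <- function(cohort, variants = NULL, maf_exclude = 0.05,
                           strong_low = 0.6, strong_high = 0.98,
                           recomb_high = 0.9, frac_strong = 0.95) {
  v <- cohort$variants
  if (is.null(variants)) variants <- v$variant
  vt <- v[match(variants, v$variant), ]
  if (length(unique(vt$chrom)) > 1L) {
    stop("blocks are delineated within one chromosome")
  }
  if (is.unsorted(vt$pos)) stop("markers must be sorted by position")
  m <- length(variants)
  if (m < 2L) stop("at least 2 markers are required")
  freqs <- allele_frequency(cohort, variants)
  maf <- pmin(freqs$frequency, 1 - freqs$frequency)
  informative_marker <- maf >= maf_exclude
  strong <- matrix(FALSE, m, m)
  informative <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (!informative_marker[i] || !informative_marker[j]) next
      ci <- ld_pair(cohort, variants[i], variants[j])
      if (is.na(ci$ci_high)) next
      is_strong <- ci$ci_low >= strong_low && ci$ci_high >= strong_high
      is_recomb <- ci$ci_high < recomb_high
      strong[i, j] <- is_strong
      informative[i, j] <- is_strong || is_recomb
    }
  }
  cand <- expand.grid(i = seq_len(m), j = seq_len(m))
  cand <- cand[cand$j > cand$i, ]
  cand <- cand[order(-(cand$j - cand$i), cand$i), ]
  taken <- rep(FALSE, m)
  blocks <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (any(taken[i:j])) next
    sub_inf <- informative[i:j, i:j]
    sub_str <- strong[i:j, i:j]
    n_inf <- sum(sub_inf)
    if (n_inf == 0L) next
    if (!strong[i, j]) next
    frac <- sum(sub_str) / n_inf
    if (frac < frac_strong) next
    taken[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      first_marker = variants[i], last_marker = variants[j],
      n_markers = j - i + 1L,
      span_bp = vt$pos[j] - vt$pos[i] + 1L,
      n_informative = n_inf, frac_strong = frac)
  }
  if (length(blocks) == 0L) {
    return(tibble::tibble(first_marker = character(),
                          last_marker = character(),
                          n_markers = integer(), span_bp = integer(),
                          n_informative = integer(),
                          frac_strong = numeric()))
  }
  out <- dplyr::bind_rows(blocks)
  out[order(match(out$first_marker, variants)), ]
}

#' Compare a haplotype frequency between cohorts
#'
#' Either an exact one-sample binomial test of the study cohort's
#' haplotype count against the comparison population's frequency, or a
#' two-proportion z test on the 2x2 haplotype table. One-sided
#' (`"greater"`: excess in the study cohort) by default.
#'
#' @param count_a Haplotype count in the study cohort.
#' @param chrom_a Chromosomes in the study cohort.
#' @param freq_b Comparison frequency (one-sample mode).
#' @param count_b,chrom_b Comparison counts (two-proportion mode).
#' @param mode `"one_sample_binomial"` or `"two_proportion"`.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return A one-row tibble: `mode`, `freq_a`, `freq_b`, `statistic`,
#'   `p`.
#' @export
haplotype_freq_compare <- function(count_a, chrom_a, freq_b = NULL,
                                   count_b = NULL, chrom_b = NULL,
                                   mode = c("one_sample_binomial",
                                            "two_proportion"),
                                   alternative = c("greater", "less",
                                                   "two.sided")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (chrom_a < 1) stop("zero chromosomes in cohort A")
  if (count_a > chrom_a) stop("count exceeds chromosomes")
  p_a <- count_a / chrom_a
  if (mode == "one_sample_binomial") {
    if (is.null(freq_b)) stop("freq_b required in one-sample mode")
    if (freq_b == 0) {
      p <- if (count_a == 0 || alternative == "less") 1 else 0
      return(tibble::tibble(mode = mode, freq_a = p_a, freq_b = freq_b,
                            statistic = count_a, p = p))
    }
    p <- stats::binom.test(count_a, chrom_a, freq_b,
                           alternative = alternative)$p.value
    tibble::tibble(mode = mode, freq_a = p_a, freq_b = freq_b,
                   statistic = count_a, p = p)
  } else {
    if (is.null(count_b) || is.null(chrom_b)) {
      stop("count_b and chrom_b required in two-proportion mode")
    }
    if (chrom_b < 1) stop("zero chromosomes in cohort B")
    p_b <- count_b / chrom_b
    pp <- (count_a + count_b) / (chrom_a + chrom_b)
    se <- sqrt(pp * (1 - pp) * (1 / chrom_a + 1 / chrom_b))
    z <- if (se > 0) (p_a - p_b) / se else 0
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(-abs(z)))
    tibble::tibble(mode = mode, freq_a = p_a, freq_b = p_b,
                   statistic = z, p = p)
  }
}
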