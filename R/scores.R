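#' Exact Mann-Whitney U test
#'
#' U is computed from midranks (ties averaged). For combined sample sizes
#' up to `exact_limit` the p-value is exact: the permutation distribution
#' of U is enumerated over all `C(n1 + n2, n1)` group assignments of the
#' observed value multiset, which remains valid under ties. Larger
#' samples use the normal approximation with the tie-corrected variance.
#'
#' @param xs,ys Numeric score vectors (both non-empty).
#' @param exact_limit Maximum `n1 + n2` for exhaustive enumeration
#'   (default 20).
#' @return A one-row tibble of class `score_comparison`: `u`, `n1`, `n2`,
#'   `p_greater` (xs stochastically larger), `p_two_sided`, `method`
#'   (`"exact"` or `"normal"`), `ties`.
#' @export
mann_whitney_exact <- function(xs, ys, exact_limit = 20) {
  if (length(xs) == 0L || length(ys) == 0L) {
    stop("both groups must be non-empty")
  }
  n1 <- length(xs); n2 <- length(ys); n <- n1 + n2
  pooled <- c(xs, ys)
  rk <- rank(pooled)  # midranks
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- any(duplicated(pooled))
  eps <- 1e-9
  if (n <= exact_limit) {
    sets <- utils::combn(n, n1)
    r1 <- colSums(matrix(rk[sets], nrow = n1))
    u_all <- r1 - n1 * (n1 + 1) / 2
    p_g <- mean(u_all >= u_obs - eps)
    p_t <- mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    z <- (u_obs - mu) / sqrt(sigma2)
    p_g <- stats::pnorm(z, lower.tail = FALSE)
    p_t <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  out <- tibble::tibble(u = u_obs, n1 = n1, n2 = n2, p_greater = p_g,
                        p_two_sided = min(1, p_t), method = method,
                        ties = ties)
  class(out) <- c("score_comparison", class(out))
  out
}

#' Pearson chi-squared test of two proportions
#'
#' Pearson chi-squared (1 df) on the 2x2 allele-count table
#' `(k1, n1 - k1 | k2, n2 - k2)`, optionally Yates-corrected. Symmetric
#' in group order. A table with a zero margin has no defined statistic
#' and returns `NA` with a warning.
#'
#' @param k1,n1,k2,n2 Successes and totals in the two groups.
#' @param yates Apply the continuity correction (default FALSE).
#' @return A one-row tibble: `chi2`, `df`, `p`, `defined`.
#' @export
chi2_two_proportions <- function(k1, n1, k2, n2, yates = FALSE) {
  if (k1 > n1 || k2 > n2) stop("counts cannot exceed totals")
  if (n1 <= 0 || n2 <= 0) stop("totals must be positive")
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
    warning("zero margin: chi-squared statistic undefined")
    return(tibble::tibble(chi2 = NA_real_, df = 1L, p = NA_real_,
                          defined = FALSE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  tibble::tibble(chi2 = unname(ht$statistic), df = 1L,
                 p = unname(ht$p.value), defined = TRUE)
}

#' Long-format frequency-versus-score table
#'
#' Builds the tidy table behind a frequency-versus-deleteriousness
#' scatterplot: one row per variant and population with the
#' derived-allele frequency and the requested score. No statistics are
#' computed.
#'
#' @param cohorts Named list of `cohort`s (names are population labels).
#' @param score Score column in the variant tables (default
#'   `"polyphen2"`).
#' @param consequence Restrict to these consequence classes (default
#'   missense).
#' @return A tibble: `variant`, `gene`, `population`, `frequency`,
#'   `score`.
#' @export
score_frequency_table <- function(cohorts, score = "polyphen2",
                                  consequence = "missense") {
  purrr::imap_dfr(cohorts, function(ch, pop) {
    v <- ch$variants
    keep <- v$consequence %in% consequence
    if (!any(keep)) return(tibble::tibble())
    af <- allele_frequency(ch, v$variant[keep])
    tibble::tibble(variant = af$variant, gene = af$gene,
                   population = pop, frequency = af$frequency,
                   score = if (score %in% names(v)) {
                     v[[score]][match(af$variant, v$variant)]
                   } else NA_real_)
  })
}
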