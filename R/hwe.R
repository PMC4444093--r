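#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (the standard "probability-ordering" exact HWE test). Monomorphic
#' sites return p = 1.
#'
#' The conditional distribution of the heterozygote count h given n
#' diploids and n_A copies of allele A is
#' `P(h) = n! / (n_AA! h! n_aa!) * 2^h / C(2n, n_A)`,
#' evaluated in log space over all feasible h of the correct parity.
#'
#' @param hom_ref,het,hom_alt Nonnegative genotype counts.
#' @return The exact p-value.
#' @export
hwe_exact_test <- function(hom_ref, het, hom_alt) {
  counts <- c(hom_ref, het, hom_alt)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("genotype counts must be nonnegative")
  }
  n <- hom_ref + het + hom_alt
  if (n < 1L) stop("at least one genotyped individual is required")
  n_a <- 2L * hom_alt + het          # copies of the alt allele
  if (n_a == 0L || n_a == 2L * n) return(1)
  rare <- min(n_a, 2L * n - n_a)
  h_all <- seq.int(rare %% 2L, rare, by = 2L)
  # log P(h) up to the shared normalising constant
  logp <- lchoose(n, (rare - h_all) / 2) +
    lchoose(n - (rare - h_all) / 2, h_all) + h_all * log(2) -
    lchoose(2L * n, rare)
  # the two lchoose terms give n! / (hom_rare! h! hom_common!)
  logp <- logp - max(logp)
  p_h <- exp(logp) / sum(exp(logp))
  obs <- p_h[match(het, h_all)]
  if (is.na(obs)) stop("observed heterozygote count is infeasible")
  min(1, sum(p_h[p_h <= obs * (1 + 1e-12)]))
}
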