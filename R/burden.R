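#' Classify variants as rare against a reference panel
#'
#' A variant is rare when its minor allele frequency is at or below
#' `threshold` (default 0.01, inclusive) in *every* reference population.
#' Rarity is reference-based, never cohort-based: a variant common in the
#' study cohort but absent from all panels (MAF 0 everywhere) is rare.
#'
#' @param variants Character vector of variant keys.
#' @param refpanel Long-format panel tibble (`variant`, `population`,
#'   `frequency`, `chromosomes`), e.g. [carn_refpanel()] or
#'   [load_reference_frequencies()]. Variants absent from the panel are
#'   treated as frequency 0 (unobserved) in all populations.
#' @param threshold MAF cutoff (inclusive).
#' @return A tibble: `variant`, `max_panel_maf`, `is_rare`.
#' @export
classify_rare <- function(variants, refpanel, threshold = 0.01) {
  maf <- refpanel |>
    dplyr::mutate(maf = pmin(.data$frequency, 1 - .data$frequency)) |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(max_panel_maf = max(.data$maf), .groups = "drop")
  tibble::tibble(variant = variants) |>
    dplyr::left_join(maf, by = "variant") |>
    dplyr::mutate(max_panel_maf = dplyr::coalesce(.data$max_panel_maf, 0),
                  is_rare = .data$max_panel_maf <= threshold)
}

#' Per-gene mutation burden
#'
#' The mutation burden of a gene is the average number of rare missense
#' derived alleles carried per individual:
#' `B = sum(derived-allele dosages over the rare missense set) / N`.
#' Missing genotypes contribute 0 alleles while the denominator stays the
#' full individual count, so burden is conservative under missingness.
#'
#' @param cohort A `cohort`.
#' @param gene Gene symbol.
#' @param rare_variants Character vector of variant keys already
#'   classified rare (see [classify_rare()]); only missense variants of
#'   `gene` among them contribute.
#' @return A one-row tibble: `gene`, `burden`, `rare_alleles`,
#'   `n_individuals`, `called_chromosomes`, `n_variants`.
#' @export
gene_burden <- function(cohort, gene, rare_variants) {
  n <- nrow(cohort$geno)
  if (n == 0L) stop("empty cohort")
  v <- cohort$variants
  keep <- v$variant %in% rare_variants & v$gene == gene &
    v$consequence == "missense"
  g <- derived_dosage(cohort)[, keep, drop = FALSE]
  tibble::tibble(
    gene = gene,
    burden = sum(g, na.rm = TRUE) / n,
    rare_alleles = sum(g, na.rm = TRUE),
    n_individuals = n,
    called_chromosomes = if (ncol(g)) min(2L * colSums(!is.na(g)))
                         else 2L * n,
    n_variants = sum(keep)
  )
}

#' Exact binomial burden test
#'
#' Upper-tail exact binomial probability `P(X >= k | n, p0)` of observing
#' at least the study cohort's rare-allele count if alleles arose at the
#' comparison cohort's pooled rare-allele frequency `p0`. One-sided by
#' design: the hypothesis is an *increased* burden in the study cohort.
#'
#' @param k Observed rare-allele count in the study cohort.
#' @param n Number of chromosomes in the study cohort.
#' @param p0 Null allele frequency (comparison cohort's pooled rare
#'   missense allele frequency for the gene).
#' @return One-sided p-value.
#' @export
burden_binomial_test <- function(k, n, p0) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 < 0 || p0 > 1) stop("p0 must lie in [0, 1]")
  if (p0 == 0 && k > 0) {
    warning("degenerate null (p0 = 0) with observed alleles; p = 0")
    return(0)
  }
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Permutation test for a burden difference
#'
#' Pools the individuals of both cohorts, randomly relabels them into
#' groups of the original sizes `n_perm` times, and recomputes the burden
#' difference `B_A - B_B` each time. The empirical one-sided p-value uses
#' the add-one rule `p = (1 + #\{perm >= obs\}) / (1 + n_perm)`, which
#' guarantees `p >= 1/(n_perm + 1)` and super-uniformity under the null.
#'
#' With `early_stop = TRUE` the permutation loop aborts once the number
#' of exceedances already makes `p < alpha` impossible.
#'
#' @param cohort_a,cohort_b Cohorts sharing the variant set.
#' @param gene Gene symbol.
#' @param rare_variants Rare variant keys (see [gene_burden()]).
#' @param n_perm Number of permutations (default 1e5).
#' @param seed Integer seed.
#' @param early_stop Abort early when significance at `alpha` is already
#'   excluded.
#' @param alpha Significance level used by `early_stop`.
#' @return A one-row tibble: `gene`, `observed_diff`, `p_perm`,
#'   `n_perm_used`.
#' @export
burden_permutation_test <- function(cohort_a, cohort_b, gene, rare_variants,
                                    n_perm = 1e5, seed,
                                    early_stop = FALSE, alpha = 0.01) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (missing(seed)) stop("an integer seed is mandatory")
  burden_counts <- function(cohort) {
    v <- cohort$variants
    keep <- v$variant %in% rare_variants & v$gene == gene &
      v$consequence == "missense"
    rowSums(derived_dosage(cohort)[, keep, drop = FALSE], na.rm = TRUE)
  }
  ca <- burden_counts(cohort_a)
  if (!setequal(colnames(cohort_a$geno), colnames(cohort_b$geno))) {
    stop("cohorts do not share a variant set")
  }
  cb <- burden_counts(cohort_b)
  na <- length(ca); nb <- length(cb)
  pooled <- c(ca, cb)
  obs <- mean(ca) - mean(cb)
  total <- sum(pooled)
  set.seed(as.integer(seed))
  exceed <- 0L
  used <- 0L
  needed_max <- ceiling(alpha * (n_perm + 1)) # exceedances that kill alpha
  for (b in seq_len(n_perm)) {
    sa <- sum(pooled[sample.int(na + nb, na)])
    stat <- sa / na - (total - sa) / nb
    if (stat >= obs - 1e-12) exceed <- exceed + 1L
    used <- b
    if (early_stop && exceed >= needed_max) break
  }
  tibble::tibble(gene = gene, observed_diff = obs,
                 p_perm = (1 + exceed) / (1 + used),
                 n_perm_used = used)
}

#' Bonferroni adjustment over variant-containing genes
#'
#' `p_adj = min(1, m * p)` with `m` the number of genes tested (the
#' variant-containing genes).
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons; defaults to `length(p)`.
#' @return Adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < 1) stop("m must be >= 1")
  if (m < length(p)) stop("m must be at least the number of p-values")
  pmin(1, m * p)
}

#' Per-gene mutation-burden table for two cohorts
#'
#' The full burden analysis: classifies each cohort's missense variants
#' against the reference panel, computes per-gene burdens in both cohorts,
#' their ratio (from burdens rounded to 3 decimals, matching the reporting
#' convention), the one-sided exact binomial p against the comparison
#' cohort's pooled rare-allele frequency, its Bonferroni adjustment over
#' the variant-containing genes, and optionally the permutation p.
#'
#' @param cohort_a Study cohort (e.g. Inuit-like).
#' @param cohort_b Comparison cohort (e.g. Asian-like).
#' @param refpanel Reference panel tibble.
#' @param maf Rarity threshold (default 0.01).
#' @param n_perm Permutations for the empirical p (0 skips the
#'   permutation test).
#' @param seed Integer seed (needed when `n_perm > 0`).
#' @param genes Genes to test; defaults to all genes with at least one
#'   rare missense variant in either cohort.
#' @return A tibble of class `burden_result`, one row per gene.
#' @export
burden_table <- function(cohort_a, cohort_b, refpanel, maf = 0.01,
                         n_perm = 0, seed = NULL, genes = NULL) {
  rare <- classify_rare(cohort_a$variants$variant, refpanel, maf)
  rare_set <- rare$variant[rare$is_rare]
  va <- cohort_a$variants
  if (is.null(genes)) {
    genes <- sort(unique(va$gene[va$variant %in% rare_set &
                                   va$consequence == "missense"]))
  }
  rows <- purrr::map_dfr(genes, function(g) {
    ba <- gene_burden(cohort_a, g, rare_set)
    bb <- gene_burden(cohort_b, g, rare_set)
    p0 <- bb$rare_alleles / bb$called_chromosomes
    pb <- burden_binomial_test(ba$rare_alleles, ba$called_chromosomes,
                               p0)
    ratio <- if (round(bb$burden, 3) > 0) {
      round(ba$burden, 3) / round(bb$burden, 3)
    } else NA_real_
    out <- tibble::tibble(
      gene = g,
      burden_a = ba$burden, burden_b = bb$burden,
      rare_alleles_a = ba$rare_alleles, rare_alleles_b = bb$rare_alleles,
      chromosomes_a = ba$called_chromosomes,
      chromosomes_b = bb$called_chromosomes,
      ratio = ratio, p_binomial = pb)
    if (n_perm > 0) {
      out$p_perm <- burden_permutation_test(cohort_a, cohort_b, g,
                                            rare_set, n_perm = n_perm,
                                            seed = seed)$p_perm
    }
    out
  })
  rows$p_binomial_adj <- bonferroni(rows$p_binomial, m = length(genes))
  class(rows) <- c("burden_result", class(rows))
  rows
}
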