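#' Specify a synthetic diploid cohort
#'
#' A cohort specification couples a variant table carrying target
#' derived-allele frequencies with a cohort size, a generation mode and a
#' mandatory random seed, so that every simulated cohort is reproducible
#' bit-for-bit from its spec.
#'
#' Two generation modes are supported. `exact_count` places exactly
#' `round(2N * p)` derived alleles at each variant, distributed over
#' individuals as the genotype configuration closest to Hardy-Weinberg
#' proportions (heterozygote count nearest `2*N*p*q` with the parity the
#' allele count forces); this makes burden statistics deterministic.
#' `hwe_sampling` draws genotypes i.i.d. from the Hardy-Weinberg genotype
#' distribution (q^2, 2pq, p^2).
#'
#' @param variants Variant table (see [as_variant_table()]) with an extra
#'   `freq` column of derived-allele frequencies in \[0, 1\].
#' @param n_individuals Positive integer cohort size.
#' @param mode `"exact_count"` or `"hwe_sampling"`.
#' @param seed Integer seed (mandatory).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(variants, n_individuals,
                        mode = c("exact_count", "hwe_sampling"), seed) {
  mode <- match.arg(mode)
  variants <- as_variant_table(variants)
  if (is.null(variants[["freq"]])) stop("variants need a `freq` column")
  if (any(is.na(variants$freq)) ||
      any(variants$freq < 0) || any(variants$freq > 1)) {
    stop("frequencies must lie in [0, 1]")
  }
  if (length(n_individuals) != 1L || is.na(n_individuals) ||
      n_individuals < 1) {
    stop("n_individuals must be a positive integer")
  }
  if (missing(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an integer seed is mandatory")
  }
  structure(list(variants = variants,
                 n_individuals = as.integer(n_individuals),
                 mode = mode, seed = as.integer(seed)),
            class = "cohort_spec")
}

# HWE-closest heterozygote count for A derived alleles among N diploids:
# same parity as A, feasible (het <= A and het <= 2N - A), nearest to the
# Hardy-Weinberg expectation 2*N*p*q at p = A/2N.
hwe_het_count <- function(alleles, n) {
  if (alleles == 0L || alleles == 2L * n) return(0L)
  p <- alleles / (2 * n)
  target <- 2 * n * p * (1 - p)
  cand <- seq.int(alleles %% 2L, min(alleles, 2L * n - alleles), by = 2L)
  cand[which.min(abs(cand - target))]
}

#' Simulate a diploid cohort at fixed allele frequencies
#'
#' @param spec A [cohort_spec()].
#' @param het_counts Optional named integer vector (variant -> heterozygote
#'   count) overriding the Hardy-Weinberg-closest configuration in
#'   `exact_count` mode; used to generate cohorts with a target inbreeding
#'   coefficient when the true genotype configuration is known.
#' @return A [new_cohort()] with no missing genotypes. The variant table
#'   keeps the target `freq` column as `truth_freq`.
#' @export
simulate_cohort <- function(spec, het_counts = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  v <- spec$variants
  n <- spec$n_individuals
  set.seed(spec$seed)
  geno <- matrix(0L, nrow = n, ncol = nrow(v),
                 dimnames = list(sprintf("S%04d", seq_len(n)), v$variant))
  for (j in seq_len(nrow(v))) {
    p <- v$freq[j]
    if (spec$mode == "exact_count") {
      alleles <- as.integer(round(2 * n * p))
      het <- if (!is.null(het_counts) && v$variant[j] %in% names(het_counts)) {
        as.integer(het_counts[[v$variant[j]]])
      } else {
        hwe_het_count(alleles, n)
      }
      if (het > alleles || (alleles - het) %% 2L != 0L ||
          (alleles + het) / 2 > n) {
        stop("infeasible heterozygote count for ", v$variant[j])
      }
      hom <- (alleles - het) %/% 2L
      g <- c(rep(2L, hom), rep(1L, het), rep(0L, n - hom - het))
      geno[, j] <- g[sample.int(n)]
    } else {
      geno[, j] <- stats::rbinom(n, 2L, p)
    }
  }
  # dosage is stored ALT-oriented; flip where the derived allele is REF
  flip <- !v$derived_is_alt
  if (any(flip)) geno[, flip] <- 2L - geno[, flip]
  vt <- v
  names(vt)[names(vt) == "freq"] <- "truth_freq"
  new_cohort(geno, vt)
}

#' Specify a haplotype-structured cohort
#'
#' @param loci Variant table of the ordered loci (biallelic; `ref`/`alt`
#'   give the two alleles at each site).
#' @param haplotypes Named numeric vector: allele strings (one character
#'   per locus, each matching that locus's `ref` or `alt`) mapped to
#'   frequencies summing to 1.
#' @param n_individuals Positive integer.
#' @param seed Integer seed (mandatory).
#' @return An object of class `haplotype_spec`.
#' @export
haplotype_spec <- function(loci, haplotypes, n_individuals, seed) {
  loci <- as_variant_table(loci)
  if (abs(sum(haplotypes) - 1) > 1e-9) {
    stop("haplotype frequencies must sum to 1")
  }
  if (any(haplotypes < 0)) stop("haplotype frequencies must be nonnegative")
  if (any(nchar(names(haplotypes)) != nrow(loci))) {
    stop("haplotype strings must have one allele per locus")
  }
  for (h in names(haplotypes)) {
    al <- strsplit(h, "")[[1]]
    ok <- al == loci$ref | al == loci$alt
    if (!all(ok)) stop("haplotype ", h, " uses alleles absent at its loci")
  }
  if (missing(seed)) stop("an integer seed is mandatory")
  structure(list(loci = loci, haplotypes = haplotypes,
                 n_individuals = as.integer(n_individuals),
                 seed = as.integer(seed)),
            class = "haplotype_spec")
}

#' Simulate a cohort from population haplotype frequencies
#'
#' Each individual receives two haplotypes drawn i.i.d. from the haplotype
#' distribution (random union of gametes). The phased truth is retained in
#' the returned cohort (`$haplotypes`) alongside the unphased genotype
#' matrix, so phasing and EM-estimation accuracy can be scored against it.
#'
#' @param spec A [haplotype_spec()].
#' @return A [new_cohort()] with truth haplotypes.
#' @export
simulate_haplotype_cohort <- function(spec) {
  stopifnot(inherits(spec, "haplotype_spec"))
  n <- spec$n_individuals
  set.seed(spec$seed)
  hap_names <- names(spec$haplotypes)
  draws <- sample(hap_names, 2L * n, replace = TRUE,
                  prob = spec$haplotypes)
  h1 <- draws[seq_len(n)]
  h2 <- draws[n + seq_len(n)]
  alt <- spec$loci$alt
  allele_mat <- function(h) {
    m <- do.call(rbind, strsplit(h, ""))
    sweep_alt <- matrix(rep(alt, each = n), nrow = n)
    (m == sweep_alt) * 1L
  }
  geno <- allele_mat(h1) + allele_mat(h2)
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(sprintf("S%04d", seq_len(n)), spec$loci$variant)
  new_cohort(geno, spec$loci, haplotypes = cbind(h1, h2))
}

#' Simulate an admixed cohort between two frequency profiles
#'
#' Each admixed individual's per-variant derived-allele frequency is the
#' mixture `(1 - lambda) * p_A + lambda * p_B`; genotypes are drawn under
#' Hardy-Weinberg at the mixed frequency. Used to plant ancestry outliers
#' for the MDS screening stage.
#'
#' @param spec_a,spec_b [cohort_spec()]s sharing the same variant list.
#' @param lambda Mixing fraction in \[0, 1\] (0 = pure A).
#' @param n Number of admixed individuals.
#' @param seed Integer seed.
#' @return A [new_cohort()].
#' @export
simulate_admixed <- function(spec_a, spec_b, lambda, n, seed) {
  stopifnot(inherits(spec_a, "cohort_spec"), inherits(spec_b, "cohort_spec"))
  if (!identical(spec_a$variants$variant, spec_b$variants$variant)) {
    stop("specs must share the same variant list")
  }
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  p_mix <- (1 - lambda) * spec_a$variants$freq + lambda * spec_b$variants$freq
  v <- spec_a$variants
  v$freq <- p_mix
  mixed <- cohort_spec(v, n, mode = "hwe_sampling", seed = seed)
  simulate_cohort(mixed)
}

#' Attach simulated sequencing metrics to a cohort
#'
#' Generates per-genotype depth (Poisson around `mean_depth`), genotype
#' quality and alternate-read fraction matrices consistent with the
#' genotype calls, for exercising the QC filters.
#'
#' @param cohort A `cohort`.
#' @param mean_depth Mean sequencing depth (reads).
#' @param gq Genotype quality assigned to every call (phred).
#' @param seed Integer seed.
#' @return The cohort with `dp`, `gq` and `altfrac` matrices filled in.
#' @export
simulate_metrics <- function(cohort, mean_depth = 100, gq = 99, seed) {
  set.seed(as.integer(seed))
  d <- dim(cohort$geno)
  dp <- matrix(stats::rpois(prod(d), mean_depth), nrow = d[1])
  af <- cohort$geno / 2 +
    matrix(stats::rnorm(prod(d), 0, 0.02), nrow = d[1])
  af <- pmin(pmax(af, 0), 1)
  af[cohort$geno == 0L] <- 0
  dimnames(dp) <- dimnames(af) <- dimnames(cohort$geno)
  cohort$dp <- dp
  cohort$gq <- matrix(gq, nrow = d[1], ncol = d[2],
                      dimnames = dimnames(cohort$geno))
  cohort$altfrac <- af
  cohort
}
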