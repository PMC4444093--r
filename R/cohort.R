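#' Assemble a cohort object
#'
#' A `cohort` bundles an individuals-by-variants genotype dosage matrix with
#' its variant annotation table and optional per-genotype quality metrics.
#' Dosages count ALT alleles (0, 1, 2); `NA` marks a missing call. Derived
#' alleles are oriented per variant by the `derived_is_alt` flag, so derived
#' frequencies never silently assume ALT = derived.
#'
#' @param geno Integer matrix, individuals in rows, variants in columns.
#'   Column names must match `variants$variant`.
#' @param variants Tibble of variant annotation; see [as_variant_table()].
#' @param dp,gq,altfrac Optional numeric matrices of per-genotype sequencing
#'   depth, genotype quality (phred) and alternate-read fraction, same
#'   dimensions as `geno`.
#' @param haplotypes Optional N x 2 character matrix of true phased
#'   haplotype strings (retained by the simulator for phasing oracles).
#'
#' @return An object of class `cohort`.
#' @export
new_cohort <- function(geno, variants, dp = NULL, gq = NULL, altfrac = NULL,
                       haplotypes = NULL) {
  variants <- as_variant_table(variants)
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (ncol(geno) > 0L) {
    if (is.null(colnames(geno))) colnames(geno) <- variants$variant
    if (!identical(colnames(geno), variants$variant)) {
      stop("genotype columns must match the variant table, in order")
    }
  } else if (nrow(variants) > 0L) {
    stop("genotype columns must match the variant table, in order")
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- sprintf("S%04d", seq_len(nrow(geno)))
  }
  bad <- geno[!is.na(geno)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  for (m in list(dp, gq, altfrac)) {
    if (!is.null(m) && !identical(dim(m), dim(geno))) {
      stop("metric matrices must match the genotype matrix dimensions")
    }
  }
  structure(
    list(geno = geno, variants = variants, dp = dp, gq = gq,
         altfrac = altfrac, haplotypes = haplotypes),
    class = "cohort"
  )
}

#' Build a variant annotation table
#'
#' Canonicalises a data frame of variant records: one row per biallelic SNV
#' with chromosome, 1-based position, REF/ALT alleles, gene symbol, a
#' consequence class from the fixed vocabulary, and the derived-allele
#' orientation flag. Deleteriousness scores (PolyPhen-2, MutationTaster),
#' when present, must lie in [0, 1].
#'
#' @param x Data frame with at least columns `variant`, `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `consequence`; optional `rsid`, `derived_is_alt`,
#'   `polyphen2`, `mutationtaster`.
#' @return A tibble with validated columns.
#' @export
as_variant_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("variant", "chrom", "pos", "ref", "alt", "gene", "consequence")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("variant table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(x$variant)) stop("duplicate variant keys")
  if (any(x$pos < 1)) stop("positions are 1-based; pos must be >= 1")
  vocab <- c("missense", "synonymous", "splicing", "other")
  if (!all(x$consequence %in% vocab)) {
    stop("consequence must be one of: ", paste(vocab, collapse = ", "))
  }
  if (is.null(x[["rsid"]])) x$rsid <- NA_character_
  if (is.null(x[["derived_is_alt"]])) x$derived_is_alt <- TRUE
  for (s in c("polyphen2", "mutationtaster")) {
    if (!is.null(x[[s]])) {
      v <- x[[s]][!is.na(x[[s]])]
      if (length(v) && (any(v < 0) || any(v > 1))) {
        stop(s, " scores must lie in [0, 1]")
      }
    }
  }
  x$pos <- as.integer(x$pos)
  x
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$geno), " individuals x ", ncol(x$geno),
      " variants\n", sep = "")
  cat("  genes: ", paste(unique(x$variants$gene), collapse = ", "), "\n",
      sep = "")
  n_miss <- sum(is.na(x$geno))
  cat("  missing genotypes: ", n_miss, "\n", sep = "")
  if (!is.null(x$haplotypes)) cat("  phased truth haplotypes retained\n")
  invisible(x)
}

#' Number of individuals and variants in a cohort
#' @param x A `cohort`.
#' @return Integer.
#' @export
n_individuals <- function(x) nrow(x$geno)

#' @rdname n_individuals
#' @export
n_variants <- function(x) ncol(x$geno)

# Derived-allele dosage matrix: flips dosage at variants where the derived
# allele is the REF allele.
derived_dosage <- function(cohort) {
  g <- cohort$geno
  flip <- !cohort$variants$derived_is_alt
  if (any(flip)) g[, flip] <- 2L - g[, flip]
  g
}

#' Subset a cohort
#'
#' @param x A `cohort`.
#' @param individuals,variants Row/column selectors (indices, names or
#'   logical vectors); `NULL` keeps everything.
#' @return A `cohort`.
#' @export
cohort_subset <- function(x, individuals = NULL, variants = NULL) {
  ii <- if (is.null(individuals)) seq_len(nrow(x$geno)) else individuals
  if (is.character(ii)) ii <- match(ii, rownames(x$geno))
  jj <- if (is.null(variants)) seq_len(ncol(x$geno)) else variants
  if (is.character(jj)) jj <- match(jj, colnames(x$geno))
  sub <- function(m) if (is.null(m)) NULL else m[ii, jj, drop = FALSE]
  new_cohort(x$geno[ii, jj, drop = FALSE], x$variants[jj, , drop = FALSE],
             dp = sub(x$dp), gq = sub(x$gq), altfrac = sub(x$altfrac),
             haplotypes = if (is.null(x$haplotypes)) NULL else
               x$haplotypes[ii, , drop = FALSE])
}

#' Combine two cohorts over a shared variant set
#'
#' Stacks the individuals of two cohorts genotyped at the same variants,
#' tagging each row with its population of origin.
#'
#' @param a,b Cohorts sharing the same variant keys (order may differ).
#' @param labels Character(2) population labels.
#' @return A list with the pooled `cohort` and a `population` factor.
#' @export
pool_cohorts <- function(a, b, labels = c("A", "B")) {
  if (!setequal(colnames(a$geno), colnames(b$geno))) {
    stop("cohorts do not share a variant set")
  }
  b <- cohort_subset(b, variants = colnames(a$geno))
  geno <- rbind(a$geno, b$geno)
  rownames(geno) <- make.unique(c(rownames(a$geno), rownames(b$geno)))
  pooled <- new_cohort(geno, a$variants)
  list(cohort = pooled,
       population = factor(rep(labels, c(nrow(a$geno), nrow(b$geno))),
                           levels = labels))
}
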