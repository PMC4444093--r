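# Internal machinery shared by the EM estimator and the LD likelihoods:
# multilocus genotypes are grouped into unique patterns, and each pattern
# is expanded into its compatible ordered-unordered haplotype pairs.
# Haplotypes are encoded as integers (bit j = allele at locus j), which
# bounds L at the enumeration limit of 12 loci.

hap_expand <- function(geno) {
  L <- ncol(geno)
  pat_key <- apply(geno, 1L, paste, collapse = "")
  tab <- table(pat_key)
  patterns <- do.call(rbind, strsplit(names(tab), ""))
  storage.mode(patterns) <- "integer"
  pows <- 2L^(seq_len(L) - 1L)
  pairs <- vector("list", nrow(patterns))
  for (k in seq_len(nrow(patterns))) {
    g <- patterns[k, ]
    het <- which(g == 1L)
    base <- sum(pows[g == 2L])
    if (length(het) == 0L) {
      pairs[[k]] <- cbind(h1 = base, h2 = base)
    } else {
      rest <- het[-1L]
      n_res <- 2L^length(rest)
      h1 <- h2 <- integer(n_res)
      for (r in seq_len(n_res)) {
        bits <- as.integer(intToBits(r - 1L))[seq_along(rest)]
        a1 <- base + pows[het[1L]] + sum(pows[rest] * bits)
        a2 <- base + sum(pows[rest] * (1L - bits))
        h1[r] <- a1; h2[r] <- a2
      }
      pairs[[k]] <- cbind(h1 = h1, h2 = h2)
    }
  }
  list(counts = as.integer(tab), pairs = pairs, L = L, pows = pows)
}

hap_string <- function(code, L, allele0, allele1) {
  bits <- vapply(code, function(x) {
    b <- as.integer(intToBits(x))[seq_len(L)]
    paste(ifelse(b == 1L, allele1, allele0), collapse = "")
  }, character(1))
  bits
}

# Log-likelihood of the genotype data given haplotype frequencies freq
# (named by integer code) under HWE.
hap_loglik <- function(ex, freq_by_code) {
  ll <- 0
  for (k in seq_along(ex$pairs)) {
    pr <- ex$pairs[[k]]
    f1 <- freq_by_code[as.character(pr[, 1])]
    f2 <- freq_by_code[as.character(pr[, 2])]
    f1[is.na(f1)] <- 0; f2[is.na(f2)] <- 0
    mult <- ifelse(pr[, 1] == pr[, 2], 1, 2)
    ll <- ll + ex$counts[k] * log(max(sum(mult * f1 * f2), 1e-300))
  }
  ll
}

#' EM estimation of population haplotype frequencies
#'
#' Maximum-likelihood haplotype frequencies from unphased multilocus
#' genotypes under the Hardy-Weinberg assumption, by the standard EM
#' algorithm over the multinomial haplotype-pair likelihood. The E-step
#' distributes each phase-ambiguous genotype over its compatible phase
#' resolutions in proportion to current haplotype frequency products;
#' initialization is uniform over the compatible haplotypes, so the
#' result is deterministic. The log-likelihood is checked to be
#' non-decreasing at every iteration.
#'
#' Individuals with a missing genotype at any of the loci are dropped
#' with a warning (population frequencies only; no imputation).
#'
#' @param x A `cohort`, or an integer matrix of 0/1/2 dosages
#'   (individuals x loci).
#' @param loci Character vector of variant keys (required when `x` is a
#'   cohort with more variants than wanted); 2 to 12 loci.
#' @param tol Convergence tolerance on the maximum frequency change.
#' @param max_iter Iteration cap.
#' @return An object of class `haplo_em` with elements `frequencies`
#'   (named numeric, names are allele strings), `loglik` (trace),
#'   `iterations`, `converged`, `loci`, `n_individuals`, `n_dropped`.
#' @export
em_haplotype_frequencies <- function(x, loci = NULL, tol = 1e-8,
                                     max_iter = 1000) {
  if (inherits(x, "cohort")) {
    if (is.null(loci)) loci <- colnames(x$geno)
    geno <- x$geno[, loci, drop = FALSE]
    vt <- x$variants[match(loci, x$variants$variant), ]
    allele0 <- vt$ref; allele1 <- vt$alt
  } else {
    geno <- as.matrix(x)
    if (!is.null(loci)) geno <- geno[, loci, drop = FALSE]
    loci <- colnames(geno)
    if (is.null(loci)) loci <- paste0("L", seq_len(ncol(geno)))
    allele0 <- rep("a", ncol(geno)); allele1 <- rep("A", ncol(geno))
  }
  L <- ncol(geno)
  if (L < 2L) stop("at least 2 loci are required")
  if (L > 12L) stop("haplotype enumeration is limited to 12 loci")
  all_missing <- colSums(!is.na(geno)) == 0L
  if (any(all_missing)) {
    stop("locus with no called genotypes: ",
         paste(loci[all_missing], collapse = ", "))
  }
  complete <- stats::complete.cases(geno)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    warning(n_dropped, " individual(s) with missing genotypes dropped")
  }
  geno <- geno[complete, , drop = FALSE]
  if (nrow(geno) == 0L) stop("no complete multilocus genotypes")
  ex <- hap_expand(geno)
  codes <- sort(unique(unlist(lapply(ex$pairs, as.vector))))
  idx <- stats::setNames(seq_along(codes), codes)
  # flatten pairs for vectorised E-steps
  pat_id <- rep(seq_along(ex$pairs),
                vapply(ex$pairs, nrow, integer(1)))
  i1 <- idx[as.character(unlist(lapply(ex$pairs, function(p) p[, 1])))]
  i2 <- idx[as.character(unlist(lapply(ex$pairs, function(p) p[, 2])))]
  mult <- ifelse(i1 == i2, 1, 2)
  cnt <- ex$counts
  n <- nrow(geno)
  ambiguous <- any(tabulate(pat_id) > 1L)
  f <- rep(1 / length(codes), length(codes))
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- mult * f[i1] * f[i2]
    s <- as.vector(rowsum(w, pat_id))
    ll <- sum(cnt * log(pmax(s, 1e-300)))
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-9) {
      stop("EM log-likelihood decreased; this should be impossible")
    }
    ll_trace <- c(ll_trace, ll)
    post <- w / s[pat_id] * cnt[pat_id]
    counts_h <- tapply(c(post, post), factor(c(i1, i2),
                                             levels = seq_along(codes)),
                       sum, default = 0)
    f_new <- as.numeric(counts_h) / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (!ambiguous) { converged <- TRUE; break }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  names(f) <- hap_string(codes, L, allele0, allele1)
  structure(list(frequencies = sort(f[f > 1e-12], decreasing = TRUE),
                 frequencies_full = stats::setNames(f, names(f)),
                 codes = codes, loglik = ll_trace, iterations = iter,
                 converged = converged, loci = loci,
                 n_individuals = n, n_dropped = n_dropped),
            class = "haplo_em")
}

#' @exportS3Method base::print
print.haplo_em <- function(x, ...) {
  cat("<haplo_em> ", length(x$loci), " loci, ", x$n_individuals,
      " individuals, ", x$iterations, " iterations",
      if (x$converged) " (converged)\n" else " (NOT converged)\n",
      sep = "")
  print(round(x$frequencies, 4))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a haplotype EM fit
#'
#' @param x A `haplo_em` object.
#' @param ... Unused.
#' @return A tibble: `haplotype`, `frequency`.
#' @export
tidy.haplo_em <- function(x, ...) {
  tibble::tibble(haplotype = names(x$frequencies),
                 frequency = unname(x$frequencies))
}

#' One-row EM fit summary
#'
#' @param x A `haplo_em` object.
#' @param ... Unused.
#' @return A tibble: `loglik`, `iterations`, `converged`,
#'   `n_haplotypes`, `n_individuals`, `n_dropped`.
#' @export
glance.haplo_em <- function(x, ...) {
  tibble::tibble(loglik = x$loglik[length(x$loglik)],
                 iterations = x$iterations, converged = x$converged,
                 n_haplotypes = length(x$frequencies),
                 n_individuals = x$n_individuals,
                 n_dropped = x$n_dropped)
}
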