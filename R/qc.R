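#' Genotype-level quality thresholds
#'
#' Defaults follow standard exome practice for this pipeline: calls need
#' sequencing depth >= 20 reads, genotype quality >= 10 (phred) and, for
#' calls carrying the alternate allele, an alternate-read fraction >= 0.25.
#' The alternate-read-fraction rule is applied per genotype (not as a
#' cohort-level MAF filter): a heterozygous or hom-alt call supported by
#' fewer than 25% alternate reads is treated as unreliable and masked.
#'
#' @param min_depth Minimum read depth.
#' @param min_alt_fraction Minimum alternate-read fraction for calls with
#'   at least one ALT allele, in \[0, 1\].
#' @param min_gq Minimum genotype quality (phred).
#' @return A list of thresholds.
#' @export
qc_thresholds <- function(min_depth = 20, min_alt_fraction = 0.25,
                          min_gq = 10) {
  if (min_depth < 0 || min_alt_fraction < 0 || min_gq < 0) {
    stop("thresholds must be nonnegative")
  }
  structure(list(min_depth = min_depth,
                 min_alt_fraction = min_alt_fraction,
                 min_gq = min_gq),
            class = "qc_thresholds")
}

#' Mask genotype calls failing quality thresholds
#'
#' Sets to missing every genotype failing any available metric threshold.
#' Filters are applied only for metrics whose matrices are present in the
#' cohort; the alternate-fraction test applies to heterozygous and hom-alt
#' calls only. The operation is idempotent. The number of masked genotypes
#' is recorded in the returned cohort's `qc_log`.
#'
#' @param cohort A `cohort` with metric matrices.
#' @param thresholds A [qc_thresholds()].
#' @return The filtered `cohort`, with `$qc_log$n_masked`.
#' @export
filter_genotypes <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  fail <- matrix(FALSE, nrow(cohort$geno), ncol(cohort$geno))
  if (!is.null(cohort$dp)) {
    fail <- fail | (!is.na(cohort$dp) & cohort$dp < thresholds$min_depth)
  }
  if (!is.null(cohort$gq)) {
    fail <- fail | (!is.na(cohort$gq) & cohort$gq < thresholds$min_gq)
  }
  if (!is.null(cohort$altfrac)) {
    carries_alt <- !is.na(cohort$geno) & cohort$geno > 0L
    fail <- fail | (carries_alt & !is.na(cohort$altfrac) &
                      cohort$altfrac < thresholds$min_alt_fraction)
  }
  newly <- fail & !is.na(cohort$geno)
  cohort$geno[fail] <- NA_integer_
  cohort$qc_log <- list(n_masked = sum(newly),
                        thresholds = unclass(thresholds))
  cohort
}

#' Derived-allele frequencies and genotype counts
#'
#' Frequency = derived alleles / called chromosomes, oriented per variant
#' by `derived_is_alt`. Missing genotypes are excluded from the
#' denominator (frequencies are over genotyped chromosomes). Invariant to
#' the ordering of individuals.
#'
#' @param cohort A `cohort`.
#' @param variants Optional character vector restricting to some variants.
#' @return A tibble with one row per variant: `variant`, `gene`,
#'   `derived_alleles`, `called_chromosomes`, `frequency`, `n_hom_ref`,
#'   `n_het`, `n_hom_alt` (genotype classes in derived orientation).
#' @export
allele_frequency <- function(cohort, variants = NULL) {
  g <- derived_dosage(cohort)
  if (!is.null(variants)) {
    miss <- setdiff(variants, colnames(g))
    if (length(miss)) stop("unknown variants: ", paste(miss, collapse = ", "))
    g <- g[, variants, drop = FALSE]
  }
  called <- colSums(!is.na(g))
  if (any(called == 0L)) {
    stop("variant(s) with no called genotypes: ",
         paste(colnames(g)[called == 0L], collapse = ", "))
  }
  tibble::tibble(
    variant = colnames(g),
    gene = cohort$variants$gene[match(colnames(g),
                                      cohort$variants$variant)],
    derived_alleles = unname(colSums(g, na.rm = TRUE)),
    called_chromosomes = unname(2L * called),
    frequency = .data$derived_alleles / .data$called_chromosomes,
    n_hom_ref = unname(colSums(g == 0L, na.rm = TRUE)),
    n_het = unname(colSums(g == 1L, na.rm = TRUE)),
    n_hom_alt = unname(colSums(g == 2L, na.rm = TRUE))
  )
}

#' Cross-platform genotype concordance
#'
#' Compares genotype calls between two cohorts (e.g. exome sequencing vs
#' SNP array) over their shared individuals and variants, reporting the
#' fraction of matching non-missing genotype pairs per variant class.
#'
#' @param cohort_a,cohort_b Cohorts sharing sample and variant keys.
#' @param classes Optional named character vector mapping variant keys to
#'   classes (e.g. exonic/intronic); unlisted variants fall in class
#'   `"all"`.
#' @return A tibble: `class`, `n_compared`, `n_match`, `concordance`.
#' @export
concordance <- function(cohort_a, cohort_b, classes = NULL) {
  vshared <- intersect(colnames(cohort_a$geno), colnames(cohort_b$geno))
  if (length(vshared) == 0L) stop("no overlapping variants to compare")
  ishared <- intersect(rownames(cohort_a$geno), rownames(cohort_b$geno))
  if (length(ishared) == 0L) stop("no overlapping individuals to compare")
  ga <- cohort_a$geno[ishared, vshared, drop = FALSE]
  gb <- cohort_b$geno[ishared, vshared, drop = FALSE]
  cls <- rep("all", length(vshared))
  if (!is.null(classes)) {
    hit <- vshared %in% names(classes)
    cls[hit] <- classes[vshared[hit]]
  }
  both <- !is.na(ga) & !is.na(gb)
  match_ <- both & (ga == gb)
  tibble::tibble(variant = vshared, class = cls,
                 n_compared = colSums(both), n_match = colSums(match_)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_compared = sum(.data$n_compared),
                     n_match = sum(.data$n_match),
                     concordance = .data$n_match / .data$n_compared,
                     .groups = "drop")
}

#' Identity-by-state multidimensional scaling
#'
#' Classical (metric) MDS of the allele-sharing distance
#' `d(i, j) = 1 - IBS(i, j) / 2`, where IBS averages the number of shared
#' alleles (0, 1 or 2) over variants called in both individuals. The
#' eigen-decomposition makes coordinates deterministic up to axis sign.
#'
#' @param cohort A `cohort` with at least 3 individuals.
#' @param dims Number of coordinate axes (default 2).
#' @return A tibble of class `mds_coords`: `individual`, `MDS1`, `MDS2`,
#'   ...; eigenvalues in `attr(, "eig")`.
#' @export
ibs_mds <- function(cohort, dims = 2) {
  n <- nrow(cohort$geno)
  if (n < 3L) stop("MDS needs at least 3 individuals")
  if (dims >= n) stop("fewer individuals than requested dimensions")
  g <- cohort$geno
  d <- matrix(0, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n - 1L)) {
    diffs <- abs(sweep(g[(i + 1L):n, , drop = FALSE], 2L, g[i, ]))
    d[i, (i + 1L):n] <- rowMeans(diffs, na.rm = TRUE) / 2
  }
  d <- d + t(d)
  coords <- stats::cmdscale(stats::as.dist(d), k = dims, eig = TRUE)
  out <- tibble::as_tibble(coords$points, .name_repair = ~ paste0("MDS",
                                                                  seq_len(dims)))
  out <- dplyr::bind_cols(tibble::tibble(individual = rownames(g)), out)
  attr(out, "eig") <- coords$eig
  class(out) <- c("mds_coords", class(out))
  out
}

#' Flag ancestry outliers on an MDS projection
#'
#' An individual is flagged when its position on the first two MDS axes
#' lies more than `k` robust scale units (MAD of within-cluster distances
#' to the cluster medoid) away from its claimed cluster's medoid
#' (componentwise median). This automates the visual outlier screen of an
#' MDS ancestry plot with a reproducible rule.
#'
#' @param coords An [ibs_mds()] result (or tibble with `individual`,
#'   `MDS1`, `MDS2`).
#' @param cluster_labels Named character vector: individual -> claimed
#'   cluster, for the individuals to screen. Each cluster needs >= 3
#'   members.
#' @param k Flagging multiplier (default 6).
#' @return A tibble: `individual`, `cluster`, `distance`, `flagged`.
#' @export
flag_ancestry_outliers <- function(coords, cluster_labels, k = 6) {
  stopifnot(all(names(cluster_labels) %in% coords$individual))
  xy <- as.matrix(coords[match(names(cluster_labels), coords$individual),
                         c("MDS1", "MDS2")])
  out <- tibble::tibble(individual = names(cluster_labels),
                        cluster = unname(cluster_labels),
                        distance = NA_real_, flagged = FALSE)
  for (cl in unique(out$cluster)) {
    idx <- which(out$cluster == cl)
    if (length(idx) < 3L) stop("cluster '", cl, "' has fewer than 3 members")
    medoid <- apply(xy[idx, , drop = FALSE], 2L, stats::median)
    dist_i <- sqrt(rowSums(sweep(xy[idx, , drop = FALSE], 2L, medoid)^2))
    scale_ <- stats::mad(dist_i, center = stats::median(dist_i))
    thr <- k * scale_
    out$distance[idx] <- dist_i
    out$flagged[idx] <- !is.na(thr) & dist_i > thr
  }
  out
}
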