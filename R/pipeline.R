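#' Pipeline configuration
#'
#' Collects the input paths, thresholds and seeds for [run_pipeline()].
#' Every threshold actually applied is logged by the pipeline; the
#' defaults (depth >= 20, GQ >= 10, alt fraction >= 0.25, reference MAF
#' <= 0.01) are explicit here, never silent constants.
#'
#' @param vcf,vcf_b Study and comparison cohort VCF paths.
#' @param genes Gene-region TSV path.
#' @param refpanel Reference-panel TSV path.
#' @param scores Optional deleteriousness-score TSV path (columns
#'   `variant`, `polyphen2`, `mutationtaster`).
#' @param thresholds A [qc_thresholds()].
#' @param maf Rarity threshold.
#' @param n_perm Burden permutations.
#' @param n_rand F-statistic randomizations.
#' @param seed Integer master seed.
#' @param outdir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(vcf, vcf_b, genes, refpanel, scores = NULL,
                            thresholds = qc_thresholds(), maf = 0.01,
                            n_perm = 10000, n_rand = 1000, seed = 1L,
                            outdir = "carnburden-out") {
  cfg <- list(vcf = vcf, vcf_b = vcf_b, genes = genes,
              refpanel = refpanel, scores = scores,
              thresholds = thresholds, maf = maf,
              n_perm = n_perm, n_rand = n_rand, seed = as.integer(seed),
              outdir = outdir)
  class(cfg) <- "pipeline_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes QC, burden, F-statistics, haplotype/LD and score stages on a
#' study/comparison cohort pair, writing one TSV per stage plus a
#' machine-readable JSON summary and a log (package version, seeds,
#' thresholds, genotype-masking counts) into `config$outdir`. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("vcf", "vcf_b", "genes", "refpanel")) {
    if (!file.exists(config[[f]])) stop("input file missing: ",
                                        config[[f]])
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  gm <- stage("input", load_gene_models(config$genes))
  if (nrow(gm) == 0L) stop("pipeline stage [input] failed: empty gene list",
                           call. = FALSE)
  panel <- stage("input", load_reference_frequencies(config$refpanel))
  a <- stage("input", read_vcf(config$vcf, gm))
  b <- stage("input", read_vcf(config$vcf_b, gm))
  if (!is.null(config$scores)) {
    sc <- stage("input", readr::read_tsv(config$scores,
                                         show_col_types = FALSE))
    for (ch_name in c("a", "b")) {
      ch <- get(ch_name)
      ch$variants <- dplyr::left_join(
        ch$variants, sc[, intersect(names(sc),
                                    c("variant", "polyphen2",
                                      "mutationtaster"))],
        by = "variant")
      assign(ch_name, ch)
    }
  }

  a <- stage("qc", filter_genotypes(a, config$thresholds))
  b <- stage("qc", filter_genotypes(b, config$thresholds))
  qc_tab <- stage("qc", {
    af <- allele_frequency(a)
    af$p_hwe <- purrr::pmap_dbl(
      list(af$n_hom_ref, af$n_het, af$n_hom_alt), hwe_exact_test)
    af
  })
  readr::write_tsv(qc_tab, file.path(config$outdir, "qc.tsv"))

  burden <- stage("burden", burden_table(a, b, panel, maf = config$maf,
                                         n_perm = config$n_perm,
                                         seed = config$seed))
  readr::write_tsv(burden, file.path(config$outdir, "burden.tsv"))

  fst <- stage("fstats", fst_table(a, b))
  wc <- fst[fst$estimator == "weir_cockerham", ]
  fst_summary <- stage("fstats", multilocus_fst(wc))
  fst_rand <- stage("fstats", dplyr::bind_rows(
    fst_randomization_test(a, b, "fst", n_rand = config$n_rand,
                           seed = config$seed + 1L),
    fst_randomization_test(a, statistic = "fis",
                           n_rand = config$n_rand,
                           seed = config$seed + 2L)))
  readr::write_tsv(fst, file.path(config$outdir, "fstat.tsv"))
  readr::write_tsv(fst_summary, file.path(config$outdir,
                                          "fstat_summary.tsv"))

  haplo <- stage("haplo", {
    af <- allele_frequency(a)
    maf <- pmin(af$frequency, 1 - af$frequency)
    rows <- list()
    for (g in unique(a$variants$gene)) {
      keys <- af$variant[af$gene %in% g & maf > 0]
      keys <- keys[order(a$variants$pos[match(keys,
                                              a$variants$variant)])]
      if (length(keys) < 2L || length(keys) > 8L) next
      em <- em_haplotype_frequencies(a, keys)
      rows[[g]] <- tibble::tibble(gene = g, tidy(em),
                                  loglik = glance(em)$loglik)
    }
    dplyr::bind_rows(rows)
  })
  readr::write_tsv(haplo, file.path(config$outdir, "haplotypes.tsv"))

  scores_tab <- stage("scores", {
    rare <- classify_rare(a$variants$variant, panel, config$maf)
    rare_missense <- a$variants$variant %in%
      rare$variant[rare$is_rare] & a$variants$consequence == "missense"
    af_a <- allele_frequency(a)
    af_b <- allele_frequency(cohort_subset(b,
                                           variants = colnames(a$geno)))
    seen_a <- rare_missense & af_a$frequency > 0
    seen_b <- rare_missense & af_b$frequency > 0
    xs <- a$variants$polyphen2[seen_a]
    ys <- a$variants$polyphen2[seen_b]
    cmp <- if (length(xs) && length(ys)) {
      mann_whitney_exact(xs[!is.na(xs)], ys[!is.na(ys)])
    } else NULL
    list(comparison = cmp,
         table = score_frequency_table(list(study = a, comparison = b)))
  })
  readr::write_tsv(scores_tab$table,
                   file.path(config$outdir, "score_frequency.tsv"))

  summary <- list(
    n_individuals = c(study = nrow(a$geno), comparison = nrow(b$geno)),
    n_masked = c(study = a$qc_log$n_masked,
                 comparison = b$qc_log$n_masked),
    burden = burden,
    fst_summary = fst_summary,
    fst_randomization = fst_rand,
    mann_whitney = scores_tab$comparison,
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  log_lines <- c(
    paste0("carnburden version: ",
           as.character(utils::packageVersion("carnburden"))),
    paste0("seed: ", config$seed),
    paste0("maf threshold: ", config$maf),
    paste0("min depth: ", config$thresholds$min_depth),
    paste0("min gq: ", config$thresholds$min_gq),
    paste0("min alt fraction: ", config$thresholds$min_alt_fraction),
    paste0("permutations: ", config$n_perm),
    paste0("randomizations: ", config$n_rand),
    paste0("masked genotypes (study): ", a$qc_log$n_masked),
    paste0("masked genotypes (comparison): ", b$qc_log$n_masked))
  writeLines(log_lines, file.path(config$outdir, "pipeline.log"))
  invisible(list(qc = qc_tab, burden = burden, fst = fst,
                 fst_summary = fst_summary, fst_rand = fst_rand,
                 haplotypes = haplo, scores = scores_tab))
}

#' Write the bundled study fixtures
#'
#' Generates the deterministic fixture bundle used throughout the
#' package: a study-cohort VCF (100 individuals, exact-count mode at the
#' published Nunavik Inuit derived-allele frequencies), a comparison
#' cohort VCF (286 individuals at the published 1KGP Asian frequencies),
#' the gene-region TSV, the reference-panel TSV, a deleteriousness-score
#' TSV and a truth TSV of the target frequencies. Regeneration with the
#' same seed is byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  v <- carn_variants()
  fx <- v[!is.na(v$freq_inuit) & !is.na(v$freq_asian), ]
  inuit_v <- fx; inuit_v$freq <- fx$freq_inuit
  asian_v <- fx; asian_v$freq <- fx$freq_asian
  inuit <- simulate_cohort(cohort_spec(inuit_v, 100, "exact_count",
                                       seed = seed))
  inuit <- simulate_metrics(inuit, seed = seed + 1L)
  asian <- simulate_cohort(cohort_spec(asian_v, 286, "exact_count",
                                       seed = seed + 2L))
  asian <- simulate_metrics(asian, seed = seed + 3L)
  paths <- c(
    vcf = file.path(outdir, "study_cohort.vcf"),
    vcf_b = file.path(outdir, "comparison_cohort.vcf"),
    genes = file.path(outdir, "genes.tsv"),
    refpanel = file.path(outdir, "refpanel.tsv"),
    scores = file.path(outdir, "scores.tsv"),
    truth = file.path(outdir, "truth.tsv"))
  write_vcf(inuit, paths[["vcf"]])
  write_vcf(asian, paths[["vcf_b"]])
  readr::write_tsv(carn_genes(), paths[["genes"]])
  readr::write_tsv(carn_refpanel(), paths[["refpanel"]])
  readr::write_tsv(
    fx[, c("variant", "gene", "polyphen2", "mutationtaster")],
    paths[["scores"]])
  readr::write_tsv(
    tibble::tibble(variant = fx$variant,
                   truth_freq_study = fx$freq_inuit,
                   truth_freq_comparison = fx$freq_asian),
    paths[["truth"]])
  invisible(paths)
}
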