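#' Read a multi-sample VCF into a cohort
#'
#' Parses a VCF 4.x file (via the vcfR package), builds the genotype dosage
#' matrix and, when the `DP`, `GQ` and `AD` FORMAT fields are present, the
#' per-genotype metric matrices (`altfrac` is alternate AD over total AD).
#' Variants are assigned to the gene whose flanked region contains them;
#' gene regions are 1-based inclusive and extended by `flank` bp each side.
#' Multi-allelic records are rejected with an explicit message; split them
#' upstream (e.g. `bcftools norm -m-`).
#'
#' The INFO keys `GENE`, `CSQ` and `DER` (written by [write_vcf()]) carry
#' the gene symbol, consequence class and derived-allele orientation; when
#' absent, the gene comes from `gene_models`, the consequence defaults to
#' `"other"` and ALT is taken as derived.
#'
#' @param path VCF file path.
#' @param gene_models Tibble of gene regions (`gene`, `chrom`, `start`,
#'   `end`), e.g. [carn_genes()].
#' @param flank Flanking margin in bp added to each gene region
#'   (default 2000).
#' @return A [new_cohort()].
#' @export
read_vcf <- function(path, gene_models = carn_genes(), flank = 2000) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no variant records")
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE))) {
    stop("multi-allelic records are not supported; ",
         "split them upstream (e.g. bcftools norm -m-)")
  }
  info <- vcf@fix[, "INFO"]
  info_get <- function(key) {
    m <- regexec(paste0("(?:^|;)", key, "=([^;]*)"), info)
    vapply(regmatches(info, m), function(z)
      if (length(z) == 2L) z[2] else NA_character_, character(1))
  }
  gene <- info_get("GENE")
  gene[!is.na(gene) & gene == "."] <- NA_character_
  csq <- info_get("CSQ")
  der <- info_get("DER")
  rs <- info_get("RS")
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  gene[is.na(gene)] <- vapply(which(is.na(gene)), function(i) {
    assign_gene(chrom[i], pos[i], gene_models, flank)
  }, character(1))
  csq[is.na(csq)] <- "other"
  variants <- tibble::tibble(
    variant = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                     paste0(chrom, ":", pos), fix[, "ID"]),
    chrom = chrom, pos = pos,
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = gene, consequence = csq,
    rsid = ifelse(!is.na(rs), rs,
                  ifelse(grepl("^rs", fix[, "ID"]), fix[, "ID"],
                         NA_character_)),
    derived_is_alt = is.na(der) | der != "REF"
  )
  gt <- vcfR::extract.gt(vcf)
  geno <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), variants$variant))
  alleles <- gsub("\\|", "/", t(gt))
  geno[alleles == "0/0"] <- 0L
  geno[alleles %in% c("0/1", "1/0")] <- 1L
  geno[alleles == "1/1"] <- 2L
  num_fmt <- function(key) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = key, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    out <- t(m)
    dimnames(out) <- dimnames(geno)
    out
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  dp <- if ("DP" %in% fmt_keys) num_fmt("DP") else NULL
  gq <- if ("GQ" %in% fmt_keys) num_fmt("GQ") else NULL
  altfrac <- NULL
  if ("AD" %in% fmt_keys) {
    ad <- t(vcfR::extract.gt(vcf, element = "AD"))
    refr <- altr <- matrix(NA_real_, nrow(ad), ncol(ad))
    parsed <- strsplit(ad, ",")
    refr[] <- vapply(parsed, function(z)
      if (length(z) >= 1) as.numeric(z[1]) else NA_real_, numeric(1))
    altr[] <- vapply(parsed, function(z)
      if (length(z) >= 2) as.numeric(z[2]) else NA_real_, numeric(1))
    tot <- refr + altr
    altfrac <- ifelse(tot > 0, altr / tot, NA_real_)
    dimnames(altfrac) <- dimnames(geno)
  }
  new_cohort(geno, variants, dp = dp, gq = gq, altfrac = altfrac)
}

# Gene containing (chrom, pos) after flanking; NA_character_ when none.
assign_gene <- function(chrom, pos, gene_models, flank = 2000) {
  hit <- gene_models$chrom == chrom &
    pos >= gene_models$start - flank &
    pos <= gene_models$end + flank
  if (!any(hit)) NA_character_ else gene_models$gene[which(hit)[1]]
}

#' Write a cohort as VCF 4.2
#'
#' Emits a minimal, bit-stable VCF with `GT` (plus `DP:GQ:AD` when metric
#' matrices are present) and INFO keys `GENE`, `CSQ`, `DER` so a round
#' trip through [read_vcf()] reproduces the cohort's genotype matrix and
#' annotation exactly.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(cohort, path) {
  v <- cohort$variants
  has_metrics <- !is.null(cohort$dp)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=carnburden",
    paste0("##INFO=<ID=GENE,Number=1,Type=String,",
           "Description=\"Assigned gene symbol\">"),
    paste0("##INFO=<ID=CSQ,Number=1,Type=String,",
           "Description=\"Consequence class\">"),
    paste0("##INFO=<ID=DER,Number=1,Type=String,",
           "Description=\"Derived allele orientation (ALT or REF)\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  if (has_metrics) {
    hdr <- c(hdr,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
      paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
             "Description=\"Allelic depths\">"))
  }
  samples <- rownames(cohort$geno)
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
  ord <- order(v$chrom, v$pos)
  lines <- vapply(ord, function(j) {
    g <- cohort$geno[, j]
    gt <- c("0/0", "0/1", "1/1")[g + 1L]
    gt[is.na(g)] <- "./."
    cells <- gt
    if (has_metrics) {
      dp <- cohort$dp[, j]
      gq <- cohort$gq[, j]
      altr <- round(dp * cohort$altfrac[, j])
      ad <- paste0(dp - altr, ",", altr)
      ad[is.na(dp)] <- ".,."
      cells <- paste(gt, ifelse(is.na(dp), ".", dp),
                     ifelse(is.na(gq), ".", gq), ad, sep = ":")
    }
    info <- paste0("GENE=", ifelse(is.na(v$gene[j]), ".", v$gene[j]),
                   ";CSQ=", v$consequence[j],
                   ";DER=", ifelse(v$derived_is_alt[j], "ALT", "REF"),
                   ifelse(is.na(v$rsid[j]), "",
                          paste0(";RS=", v$rsid[j])))
    paste(c(v$chrom[j], v$pos[j], v$variant[j],
            v$ref[j], v$alt[j], ".", "PASS", info,
            if (has_metrics) "GT:DP:GQ:AD" else "GT", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Load a reference-panel allele-frequency table
#'
#' Reads a TSV with columns `variant`, `population`, `frequency`,
#' `chromosomes` (derived-allele frequency and diploid chromosome count
#' per population). Variant-population cells absent from the file are
#' completed as frequency 0 with a warning, mirroring the treatment of
#' variants unobserved in a public panel.
#'
#' @param path TSV file path.
#' @return A tibble reference panel (long format).
#' @export
load_reference_frequencies <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             variant = readr::col_character(),
                             population = readr::col_character(),
                             frequency = readr::col_double(),
                             chromosomes = readr::col_integer()))
  if (nrow(panel) == 0L) stop("reference panel file is empty")
  if (anyDuplicated(panel[, c("variant", "population")])) {
    stop("duplicate variant-population keys in reference panel")
  }
  if (any(is.na(panel$frequency)) ||
      any(panel$frequency < 0) || any(panel$frequency > 1)) {
    stop("panel frequencies must lie in [0, 1]")
  }
  if (any(panel$chromosomes <= 0) || any(panel$chromosomes %% 2L != 0L)) {
    stop("panel chromosome counts must be positive even integers")
  }
  full <- tidyr::expand_grid(variant = unique(panel$variant),
                             population = unique(panel$population))
  filled <- dplyr::left_join(full, panel, by = c("variant", "population"))
  if (any(is.na(filled$frequency))) {
    warning("missing variant x population cells treated as frequency 0")
    sizes <- panel |>
      dplyr::distinct(.data$population, .data$chromosomes)
    filled <- filled |>
      dplyr::select(-"chromosomes") |>
      dplyr::left_join(sizes, by = "population") |>
      dplyr::mutate(frequency = dplyr::coalesce(.data$frequency, 0))
  }
  filled
}

#' Load gene regions from a TSV
#'
#' @param path TSV with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return A tibble of gene models.
#' @export
load_gene_models <- function(path) {
  gm <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gm)))
  if (any(gm$start > gm$end)) stop("gene start must be <= end")
  gm
}
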