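#' Genomic regions of the six carnitine acyltransferase genes
#'
#' Coordinates (GRCh37, 1-based inclusive) of the longest isoform of each
#' gene. These define the regions within which variants are assigned to
#' genes, after adding a flanking margin (default 2 kb each side).
#'
#' @return A tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
carn_genes <- function() {
  tibble::tribble(
    ~gene,    ~chrom,  ~start,     ~end,
    "CPT1A",  "chr11", 68522088L,  68609399L,
    "CPT1B",  "chr22", 51007290L,  51017096L,
    "CPT1C",  "chr19", 50194365L,  50216988L,
    "CPT2",   "chr1",  53662101L,  53679869L,
    "CRAT",   "chr9",  131857073L, 131873070L,
    "CROT",   "chr7",  86974951L,  86989425L
  )
}

#' Coding variants of the carnitine acyltransferase genes
#'
#' The coding variants observed in the 100-individual Nunavik Inuit cohort
#' together with the six rare missense variants seen in the 286 CHB+JPT
#' (1KGP Asian) comparison cohort, their derived-allele frequencies in each
#' population, reference-panel frequencies (CHB-JPT, CEU, YRI) and in-silico
#' deleteriousness scores. Frequencies are derived-allele frequencies
#' oriented against the reference genome. Genomic positions are synthetic
#' placements inside the true gene regions (per-base positions are not part
#' of the published summary data); relative spacing preserves the reported
#' LD-block spans (the ~8 kb CPT1B block and ~1 kb CPT2 block).
#'
#' `freq_inuit` is `NA` for the three synonymous variants, whose cohort
#' frequencies were not published; they are excluded from simulated cohorts.
#'
#' @return A tibble, one row per variant, with annotation columns (see
#'   [as_variant_table()]) plus `freq_inuit`, `freq_asian`, `freq_chbjpt`,
#'   `freq_ceu`, `freq_yri`.
#' @export
carn_variants <- function() {
  tibble::tribble(
    ~variant,          ~gene,   ~chrom,  ~pos,       ~ref, ~alt, ~rsid,
      ~consequence, ~mutationtaster, ~polyphen2,
      ~freq_inuit, ~freq_asian, ~freq_chbjpt, ~freq_ceu, ~freq_yri,
    "CPT1A:p.V616V",   "CPT1A", "chr11", 68524200L,  "C", "T", NA,
      "synonymous", NA,       NA,    NA,     NA,     NA,    NA,    NA,
    "CPT1A:p.P479L",   "CPT1A", "chr11", 68527222L,  "C", "T", "rs80356779",
      "missense",   0.997899, 1,     0.955,  0,      0,     0,     0,
    "CPT1A:p.F417F",   "CPT1A", "chr11", 68529500L,  "G", "A", "rs2228502",
      "synonymous", NA,       NA,    NA,     NA,     NA,    NA,    NA,
    "CPT1A:p.I491T",   "CPT1A", "chr11", 68527000L,  "T", "C", NA,
      "missense",   NA,       0,     0,      0.0035, 0.0035, 0,    0,
    "CPT1B:p.E531K",   "CPT1B", "chr22", 51008800L,  "G", "A", "rs470117",
      "missense",   0.606166, 0.303, 0.305,  0.483,  0.483, 0.465, 0.088,
    "CPT1B:p.S427C",   "CPT1B", "chr22", 51012500L,  "C", "G", "rs8142477",
      "missense",   0,        0,     0.675,  0.517,  0.517, 0.933, 0.258,
    "CPT1B:p.I66V",    "CPT1B", "chr22", 51016800L,  "A", "G", "rs3213445",
      "missense",   0.251908, 0,     0.175,  0.358,  0.358, 0.049, 0.102,
    "CPT1B:p.C659W",   "CPT1B", "chr22", 51008000L,  "C", "G", NA,
      "missense",   NA,       1,     0,      0.0035, 0.0035, 0,    0,
    "CPT1C:p.T265M",   "CPT1C", "chr19", 50202000L,  "C", "T", NA,
      "missense",   0.999717, 0.998, 0.005,  0,      0,     0,     0,
    "CPT1C:p.Q97H",    "CPT1C", "chr19", 50197000L,  "G", "C", NA,
      "missense",   NA,       0.08,  0,      0.0035, 0.0035, 0,    0,
    "CPT1C:p.R514Q",   "CPT1C", "chr19", 50210000L,  "G", "A", NA,
      "missense",   NA,       1,     0,      0.0035, 0.0035, 0,    0,
    "CPT2:p.S122F",    "CPT2",  "chr1",  53665000L,  "C", "T", NA,
      "missense",   NA,       0.018, 0,      0.006,  0.006, 0,     0,
    "CPT2:p.F352C",    "CPT2",  "chr1",  53668000L,  "T", "G", "rs2229291",
      "missense",   0.999596, 0.999, 0.28,   0.20,   0.20,  0,     0.013,
    "CPT2:p.V368I",    "CPT2",  "chr1",  53669000L,  "G", "A", "rs1799821",
      "missense",   0.06145,  0.001, 0.525,  0.775,  0.775, 0.549, 0.252,
    "CPT2:p.R477W",    "CPT2",  "chr1",  53676000L,  "C", "T", NA,
      "missense",   0.997459, 1,     0.03,   0,      0,     0,     0,
    "CRAT:p.A603P",    "CRAT",  "chr9",  131859000L, "G", "C", "rs17459086",
      "missense",   0.993409, 0.013, 0.09,   0.07,   0.07,  0.017, 0.008,
    "CRAT:p.A575A",    "CRAT",  "chr9",  131860000L, "C", "T", "rs375414636",
      "synonymous", NA,       NA,    NA,     NA,     NA,    NA,    NA,
    "CRAT:p.V411M",    "CRAT",  "chr9",  131863000L, "G", "A", NA,
      "missense",   NA,       0.803, 0,      0.0035, 0.0035, 0,    0,
    "CRAT:p.S78F",     "CRAT",  "chr9",  131870000L, "C", "T", NA,
      "missense",   0.999657, 0.906, 0.025,  0,      0,     0,     0
  )
}

#' Reference-panel allele frequencies for the study variants
#'
#' Long-format reference panel built from the published per-population
#' derived-allele frequencies: CHB-JPT (286 individuals), CEU (178) and
#' YRI (250). Used by [classify_rare()].
#'
#' @return A tibble with columns `variant`, `population`, `frequency`,
#'   `chromosomes`.
#' @export
carn_refpanel <- function() {
  v <- carn_variants()
  v <- v[!is.na(v$freq_chbjpt) | !is.na(v$freq_ceu) | !is.na(v$freq_yri), ]
  sizes <- c("CHB-JPT" = 2L * 286L, "CEU" = 2L * 178L, "YRI" = 2L * 250L)
  cols <- c("CHB-JPT" = "freq_chbjpt", "CEU" = "freq_ceu", "YRI" = "freq_yri")
  purrr::map_dfr(names(sizes), function(pop) {
    tibble::tibble(
      variant = v$variant,
      population = pop,
      frequency = v[[cols[[pop]]]],
      chromosomes = sizes[[pop]]
    )
  })
}

#' The four CPT2 missense-site haplotypes
#'
#' The published haplotype structure over the three CPT2 missense sites
#' (p.F352C, p.V368I, p.R477W): T-G-C (45%), T-A-C (24%), G-A-C (28%) and
#' T-G-T (3%). Marginal allele frequencies reproduce the per-site cohort
#' frequencies (28%, 52%, 3%).
#'
#' @return A named numeric vector of haplotype frequencies; names are
#'   allele strings over the three sites in genomic order
#'   (p.S122F excluded; sites p.F352C, p.V368I, p.R477W).
#' @export
cpt2_haplotypes <- function() {
  c("TGC" = 0.45, "TAC" = 0.24, "GAC" = 0.28, "TGT" = 0.03)
}
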