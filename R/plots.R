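#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-gene burdens for the two cohorts
#'
#' @param object A `burden_result` from [burden_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.burden_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("gene", "burden_a", "burden_b")],
    cols = c("burden_a", "burden_b"), names_to = "cohort",
    values_to = "burden",
    names_transform = list(cohort = ~ ifelse(. == "burden_a", "study",
                                             "comparison")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$burden,
                                     fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "rare missense alleles / person",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-variant FST estimates
#'
#' @param object An `fst_result` from [fst_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fst_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[!is.na(df$fst), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variant, y = .data$fst,
                                   colour = .data$estimator)) +
    ggplot2::geom_point() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(F[ST]), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an MDS ancestry projection
#'
#' @param object An `mds_coords` tibble from [ibs_mds()].
#' @param labels Optional named vector of cluster labels for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mds_coords <- function(object, labels = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(labels)) {
    df$cluster <- labels[df$individual]
  } else {
    df$cluster <- "cohort"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$MDS1, y = .data$MDS2,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}

#' Frequency-versus-deleteriousness scatterplot
#'
#' The standard view of variant impact: derived-allele frequency against
#' the deleteriousness score, one panel colour per population.
#'
#' @param table A [score_frequency_table()] result.
#' @return A ggplot.
#' @export
plot_score_frequency <- function(table) {
  ggplot2::ggplot(table, ggplot2::aes(x = .data$score,
                                      y = .data$frequency,
                                      colour = .data$population)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(x = "deleteriousness score",
                  y = "derived-allele frequency", colour = NULL) +
    ggplot2::theme_minimal()
}
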