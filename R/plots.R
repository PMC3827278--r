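#' Plot MAF spectra
#'
#' Side-by-side minor-allele-frequency histograms per taxon; an intermediate
#' frequency excess in the array-design (focal) taxon relative to the others
#' is the classic ascertainment-bias signature.
#'
#' @param spectra tibble from [maf_spectrum()] (rows for several taxa may be
#'   bound together).
#' @return a ggplot object.
#' @export
plot_maf_spectra <- function(spectra) {
  ggplot2::ggplot(spectra, ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                                        y = .data$count)) +
    ggplot2::geom_col(width = NULL, fill = "grey35") +
    ggplot2::facet_wrap(~taxon, scales = "free_y") +
    ggplot2::labs(x = "minor allele frequency", y = "SNPs") +
    ggplot2::theme_minimal()
}

#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, species_map = NULL, ...) {
  df <- tidy(object)
  if (!is.null(species_map)) {
    df <- dplyr::left_join(df, species_map, by = "sample_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2, colour = .data$taxon))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  expl <- object$explained
  p + ggplot2::geom_point() +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * expl[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * expl[2])) +
    ggplot2::theme_minimal()
}

#' @method autoplot mds_result
#' @export
autoplot.mds_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2, label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "MDS axis 1", y = "MDS axis 2") +
    ggplot2::theme_minimal()
}

#' @method autoplot replicate_experiment
#' @export
autoplot.replicate_experiment <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("rf_genotype", "rf_intensity"),
                        names_to = "route", values_to = "rf") |>
    dplyr::mutate(route = sub("^rf_", "", .data$route))
  ggplot2::ggplot(df, ggplot2::aes(.data$route, .data$rf)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0.08, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "topology distance to true tree") +
    ggplot2::theme_minimal()
}
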