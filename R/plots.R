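#' Plot a rarefaction curve
#'
#' Mean detected allele count against sample size with a +/- 1 SD ribbon.
#'
#' @param object A `rarefaction_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample_size,
                                       y = .data$mean_alleles)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_alleles - .data$sd_alleles,
      ymax = .data$mean_alleles + .data$sd_alleles
    ), fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$locus)) +
    ggplot2::labs(x = "Individuals sampled", y = "Distinct alleles detected") +
    ggplot2::theme_minimal()
}

#' Plot the MPAF distribution of a catalog
#'
#' Histogram of mean per-amplicon frequencies, filled by validation status;
#' the bimodality (true alleles near their expected per-amplicon frequency,
#' artefacts piled up near zero) motivates the MPAF threshold, drawn as a
#' dashed line.
#'
#' @param catalog Catalog tibble from [validate_alleles()].
#' @param mpaf_threshold Threshold to mark.
#' @return A ggplot.
#' @export
plot_mpaf <- function(catalog, mpaf_threshold = 0.05) {
  fill <- if ("status" %in% names(catalog)) "status" else NULL
  p <- ggplot2::ggplot(catalog, ggplot2::aes(x = .data$mpaf))
  p <- if (is.null(fill)) {
    p + ggplot2::geom_histogram(bins = 40)
  } else {
    p + ggplot2::geom_histogram(ggplot2::aes(fill = .data$status), bins = 40)
  }
  p +
    ggplot2::geom_vline(xintercept = mpaf_threshold, linetype = "dashed") +
    ggplot2::facet_wrap(ggplot2::vars(.data$locus), scales = "free_y") +
    ggplot2::labs(x = "Mean per-amplicon frequency (MPAF)", y = "Variants") +
    ggplot2::theme_minimal()
}
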