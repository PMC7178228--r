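#' Plot a per-gene allele-frequency landscape
#'
#' Bar chart of relative allele frequencies per gene with the
#' continuity-corrected 95% confidence intervals as error bars; the
#' inferred wildtype row is drawn alongside the detected alleles.
#'
#' @param landscape A `gene_landscape` tibble.
#' @param genes Optional subset of genes to draw.
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, genes = NULL) {
  stopifnot(inherits(landscape, "gene_landscape"))
  df <- if (is.null(genes)) landscape else {
    dplyr::filter(landscape, .data$gene %in% genes)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$allele, y = .data$frequency,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.25, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "relative allele frequency", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot gene_landscape
#' @export
autoplot.gene_landscape <- function(object, ...) plot_landscape(object, ...)

#' Plot minor-allele-frequency bin composition
#'
#' Stacked counts of variants per classification group and MAF bin — the
#' bin-distribution view of a cohort summary.
#'
#' @param summary Output of [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_maf_bins <- function(summary) {
  df <- dplyr::filter(summary, .data$maf_bin != "total")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n_variants,
                                   fill = .data$maf_bin)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "variants", fill = "MAF bin") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
#' @rdname gene_landscape
#' @method tidy gene_landscape
#' @param x A `gene_landscape`.
#' @param ... Unused.
tidy.gene_landscape <- function(x, ...) tibble::as_tibble(x)

#' @export
#' @rdname gene_landscape
#' @method glance gene_landscape
glance.gene_landscape <- function(x, ...) {
  x |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_alleles = dplyr::n() - 1L,
      an = .data$an[1],
      wildtype_freq = .data$frequency[.data$category == "wildtype"][1],
      overflow = any(.data$overflow),
      .groups = "drop"
    )
}
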