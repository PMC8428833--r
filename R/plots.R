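#' Plot rarefaction curves
#'
#' Mean pan and core gene counts by subsample size, with min/max envelopes
#' over iterations.
#'
#' @param object A [pan_core_curves()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rarefaction_curves <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble(size = object$size, genome = "pan", mean = object$pan_mean,
           min = object$pan_min, max = object$pan_max),
    tibble(size = object$size, genome = "core", mean = object$core_mean,
           min = object$core_min, max = object$core_max)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$size, y = .data$mean,
                                     colour = .data$genome,
                                     fill = .data$genome)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Accessions sampled", y = "Gene count",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot PAV PCA scores
#'
#' @param object A [pav_pca()] result.
#' @param clades Optional tibble `accession_id`, `clade` to colour points.
#' @param ... Unused.
#' @return A ggplot of the first two components.
#' @export
autoplot.pav_pca <- function(object, clades = NULL, ...) {
  df <- object$scores
  if (!is.null(clades)) df <- left_join(df, clades, by = "accession_id")
  pv <- 100 * object$explained$prop_variance
  aes <- if (!is.null(clades)) {
    ggplot2::aes(x = .data$PC1, y = .data$PC2, colour = .data$clade)
  } else {
    ggplot2::aes(x = .data$PC1, y = .data$PC2)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", pv[1]),
                  y = sprintf("PC2 (%.1f%%)", pv[2])) +
    ggplot2::theme_minimal()
}

#' Plot gene-category composition
#'
#' @param category_table A [categorize_genes()] result.
#' @return A ggplot bar chart of category counts.
#' @export
plot_category_summary <- function(category_table) {
  sm <- classification_summary(category_table)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$pct)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "Genes") +
    ggplot2::theme_minimal()
}

#' Plot a novel-sequence accumulation curve
#'
#' @param curve An [accumulation_curve()] result.
#' @return A ggplot of cumulative novel bp vs accessions sampled.
#' @export
plot_accumulation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$size, y = .data$mean_bp)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_bp,
                                      ymax = .data$max_bp),
                         alpha = 0.25) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Accessions sampled",
                  y = "Cumulative novel sequence (bp)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
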