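#' Ternary plot of relative homoeolog expression
#'
#' Each point is one triad in one condition, placed in the barycentric
#' triangle (A bottom-left, B bottom-right, D top) and coloured by bias
#' category.
#'
#' @param assign Assignment tibble from [classify_triads()].
#' @param genotype,stage Optional filters.
#' @return A ggplot object.
#' @export
plot_ternary <- function(assign, genotype = NULL, stage = NULL) {
  df <- filter(assign, !is.na(.data$rel_A))
  if (!is.null(genotype)) df <- filter(df, .data$genotype == !!genotype)
  if (!is.null(stage)) df <- filter(df, .data$stage == !!stage)
  df <- ternary_coordinates(df)
  tri <- tibble(x = c(0, 1, 0.5, 0), y = c(0, 0, sqrt(3) / 2, 0))
  lab <- tibble(x = c(-0.03, 1.03, 0.5), y = c(-0.03, -0.03, sqrt(3) / 2 + 0.04),
                text = c("A", "B", "D"))
  ggplot2::ggplot(df, ggplot2::aes(.data$tern_x, .data$tern_y)) +
    ggplot2::geom_path(data = tri, ggplot2::aes(.data$x, .data$y),
                       inherit.aes = FALSE, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$category),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(.data$x, .data$y, label = .data$text),
                       inherit.aes = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "category")
}

#' Stacked bars of bias-category proportions per condition
#'
#' @param proportions Output of [category_proportions()].
#' @return A ggplot object.
#' @export
plot_category_proportions <- function(proportions) {
  ggplot2::ggplot(proportions,
                  ggplot2::aes(.data$stage, .data$proportion, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$genotype)) +
    ggplot2::labs(x = NULL, y = "proportion of triads") +
    ggplot2::theme_minimal()
}

#' Genome plot of smoothed fold change and called hotspot regions
#'
#' @param scan Output of [scan_hotspots()].
#' @return A ggplot object.
#' @export
plot_hotspots <- function(scan) {
  gg <- ggplot2::ggplot(scan$positions,
                        ggplot2::aes(.data$position / 1e6, .data$smoothed)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mbp)", y = "smoothed log2FC") +
    ggplot2::theme_minimal()
  if (nrow(scan$regions) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = scan$regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      inherit.aes = FALSE, alpha = 0.2
    ) +
      ggplot2::scale_fill_manual(values = c(up = "red", down = "blue"))
  }
  gg
}

#' Cross-validation curve of an NSC model
#'
#' Mean cross-validated accuracy against the shrinkage threshold, with the
#' number of surviving genes as a secondary hue; the selected threshold is
#' marked.
#'
#' @param object An `"nsc_model"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nsc_model
#' @export
autoplot.nsc_model <- function(object, ...) {
  ggplot2::ggplot(object$cv, ggplot2::aes(.data$delta, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$n_genes)) +
    ggplot2::geom_vline(xintercept = object$delta, linetype = 2) +
    ggplot2::labs(x = "shrinkage threshold", y = "mean CV accuracy",
                  colour = "genes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
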