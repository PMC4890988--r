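# ggplot2 views of the result objects.

#' Plot a pathway analysis
#'
#' Dot plot of the top pathways ranked by permutation p-value, on the
#' -log10 scale (zero p-values are plotted at the resolution limit
#' `1 / (n_perm + 1)`), colored by significance.
#'
#' @param object A `pathway_analysis` object.
#' @param n_top Number of pathways to show (default 25).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pathway_analysis
#' @export
autoplot.pathway_analysis <- function(object, n_top = 25, ...) {
  df <- head(object$results, n_top)
  df$neglog_p <- -log10(pmax(df$p_perm, 1 / (object$n_perm + 1)))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$neglog_p,
    y = stats::reorder(.data$pathway_id, .data$neglog_p),
    color = .data$significant
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = expression(-log[10] ~ italic(P)[permutation]),
      y = NULL,
      color = sprintf("q < %g", object$q_threshold),
      title = sprintf("Pathway associations (%s mode)", object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a mode comparison
#'
#' Bar chart of the set-algebra categories of significant pathways across
#' the GWAS, expression and integrated analyses.
#'
#' @param object A `mode_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mode_comparison
#' @export
autoplot.mode_comparison <- function(object, ...) {
  df <- filter(count(object$membership, .data$category),
               .data$category != "none")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$category, .data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "Significant pathways",
      title = sprintf("Mode overlap at q < %g", object$q_threshold)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter plot of the two gene-level evidence sources
#'
#' Plots -log10 GWAS gene p-values against -log10 expression p-values
#' for genes scored by both sources, colored by the combined Fisher
#' p-value.
#'
#' @param gene_scores Gene score table from [build_integrated_scores()].
#' @param p_highlight Combined p-value threshold used for coloring
#'   (default 1e-4).
#' @return A ggplot object.
#' @export
plot_gene_scores <- function(gene_scores, p_highlight = 1e-4) {
  df <- filter(gene_scores, .data$evidence == "both")
  df$combined_signal <- df$p_combined < p_highlight
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_gwas), y = -log10(.data$p_expr),
    color = .data$combined_signal
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(
      x = expression(-log[10] ~ italic(P)["GWAS"]),
      y = expression(-log[10] ~ italic(P)["expression"]),
      color = sprintf("combined p < %g", p_highlight)
    ) +
    ggplot2::theme_minimal()
}
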