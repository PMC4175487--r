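#' Heatmap of the male/female phenotype expression ratios
#'
#' Tile plot of log2 male/female ratios per gene and factor; red marks
#' higher expression in the male phenotype, blue in the female phenotype.
#' Asterisks flag a significant main effect of the factor and plus signs a
#' significant interaction involving it.
#'
#' @param object A [ratio_matrix()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.fcg_ratio_matrix <- function(object, ...) {
  labels <- c(
    sex_chromosome = "XY-/XX", gonadal_sex = "testes/ovaries",
    hormone = "testosterone/blank"
  )
  dat <- object |>
    mutate(
      flag = paste0(
        ifelse(.data$main_effect, "*", ""),
        ifelse(.data$interaction, "+", "")
      ),
      factor = factor(labels[.data$factor], levels = unname(labels)),
      gene = factor(.data$gene, levels = rev(unique(.data$gene)))
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$factor, y = .data$gene)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$log2_ratio)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$flag), size = 3) +
    ggplot2::scale_fill_gradient2(
      low = "#2166AC", mid = "white", high = "#B2182B", midpoint = 0,
      name = "log2 male/female"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Circle-layout plot of a co-expression network
#'
#' Nodes on a circle sized by weighted degree; edges drawn for weights
#' above `min_weight`, red for positive and blue for negative correlation,
#' line width proportional to |r|^3.
#'
#' @param object A `"coexpr_network"`.
#' @param min_weight Smallest edge weight drawn (default 0.05).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.coexpr_network <- function(object, min_weight = 0.05, ...) {
  n <- length(object$genes)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  nodes <- tibble(
    gene = object$genes,
    x = cos(theta), y = sin(theta),
    degree = unname(weighted_degrees(object))
  )
  edges <- tidy(object) |>
    filter(.data$weight >= min_weight) |>
    left_join(select(nodes, "gene", x0 = "x", y0 = "y"),
      by = c(gene_i = "gene")
    ) |>
    left_join(select(nodes, "gene", x1 = "x", y1 = "y"),
      by = c(gene_j = "gene")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$weight, colour = .data$sign
      ),
      alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree)
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y, label = .data$gene),
      size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c("+" = "#B2182B", "-" = "#2166AC", "0" = "grey70")
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 2)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = object$group)
}

#' Null distribution of a permutation network comparison
#'
#' Histogram of permuted property differences with the observed difference
#' marked.
#'
#' @param object A `"network_comparison"`.
#' @param property Which property to show; default the first compared.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.network_comparison <- function(object,
                                        property = object$table$property[1],
                                        ...) {
  nulls <- tibble(delta = object$null_delta[, property])
  obs <- object$table$delta[object$table$property == property]
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::geom_vline(xintercept = obs, colour = "#B2182B") +
    ggplot2::labs(
      x = paste("permuted difference in", property),
      y = "count",
      title = paste0(
        object$labels[1], " - ", object$labels[2], " (p = ",
        signif(object$table$p[object$table$property == property], 3), ")"
      )
    ) +
    ggplot2::theme_minimal()
}
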