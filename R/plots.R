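#' Stacked per-species gene counts for a group of domain subfamilies
#'
#' The standard comparative view of a gene family: one bar per species,
#' stacked by subfamily (domain accession), with the largest subfamily at
#' the bottom of the stack and the smallest at the top.
#'
#' @param matrix A [build_count_matrix()] result.
#' @param domains Optional character vector restricting to a subfamily group
#'   (defaults to all domains in the matrix).
#' @return A ggplot object.
#' @export
plot_domain_counts <- function(matrix, domains = NULL) {
  df <- as_tibble(matrix)
  if (!is.null(domains)) df <- filter(df, .data$domain_acc %in% domains)
  order_tbl <- df |>
    group_by(.data$domain_acc) |>
    summarise(total = sum(.data$n_genes), .groups = "drop") |>
    arrange(dplyr::desc(.data$total))
  df <- mutate(df, domain_acc = factor(.data$domain_acc,
                                       levels = rev(order_tbl$domain_acc)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_id, y = .data$n_genes,
                                   fill = .data$domain_acc)) +
    ggplot2::geom_col(position = ggplot2::position_stack(reverse = TRUE)) +
    ggplot2::labs(x = NULL, y = "genes", fill = "subfamily") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of flagged differentially expressed genes
#'
#' Tile heatmap of log2 quantile-normalized counts (plus the policy
#' pseudocount) for the genes flagged by [run_de()], samples in condition
#' order.
#'
#' @param object A [run_de()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_results <- function(object, ...) {
  norm <- attr(object, "normalized")
  conditions <- attr(object, "conditions")
  flagged <- object$gene_id[object$flagged]
  if (is.null(norm) || length(flagged) == 0) {
    abort("no flagged genes (or no attached normalized matrix) to plot")
  }
  df <- norm |>
    filter(.data$gene_id %in% flagged) |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "norm_count") |>
    mutate(sample_id = factor(.data$sample_id, levels = conditions$sample_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$gene_id,
                                   fill = log2(.data$norm_count + 0.5))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2 norm count") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked per-species conservation-category counts
#'
#' @param object A [summarize_partition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ortho_summary <- function(object, ...) {
  df <- tidy(object) |>
    mutate(category = factor(.data$category, levels = gene_categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_id, y = .data$n_genes,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
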