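#' Heatmap of a pairwise distance matrix
#'
#' @param object An `skt_dist`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skt_dist
#' @export
autoplot.skt_dist <- function(object, ...) {
  df <- tidy(object)
  df <- dplyr::bind_rows(
    df,
    dplyr::rename(df, item1 = "item2", item2 = "item1"),
    tibble::tibble(item1 = object$labels, item2 = object$labels,
                   distance = 0, flag = "ok")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item1, y = .data$item2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "distance\n(subs/site)") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste0("Pairwise ", object$model, " distances")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Bar chart of a record summary
#'
#' @param object An `skt_summary` from [summarize_records()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skt_summary
#' @export
autoplot.skt_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$level, y = .data$percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = object$dimension[[1]], y = "% of records") +
    ggplot2::theme_minimal()
}

#' Confusion-matrix tile plot for a recovery experiment
#'
#' @param object An `skt_recovery` from [recovery_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot skt_recovery
#' @export
autoplot.skt_recovery <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$true_category, y = .data$category,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "count") +
    ggplot2::labs(x = "true category", y = "inferred category") +
    ggplot2::theme_minimal()
}

#' Haplotype frequency bar chart
#'
#' @param haps An `skt_haplotypes` table from [collapse_haplotypes()].
#' @return A ggplot object.
#' @export
plot_haplotype_frequencies <- function(haps) {
  df <- tibble::tibble(label = haps$label,
                       n = lengths(haps$members))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "darkgreen") +
    ggplot2::labs(x = "haplotype", y = "individuals") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
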