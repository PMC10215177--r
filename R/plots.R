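#' Plot per-feature AT/GC skews
#'
#' Diverging bar chart of AT and GC skew per feature, the usual way
#' strand-asymmetry profiles of mitogenomes are shown.
#'
#' @param object A `mito_composition` from [genome_composition()].
#' @param classes Feature classes to show (default PCGs).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_composition <- function(object, classes = "PCG", ...) {
  df <- as_tibble(object) |>
    filter(.data$name != "Total", .data$class %in% classes) |>
    tidyr::pivot_longer(c("at_skew", "gc_skew"), names_to = "skew",
                        values_to = "value") |>
    mutate(skew = dplyr::recode(.data$skew, at_skew = "AT skew",
                                gc_skew = "GC skew"),
           name = factor(.data$name, unique(.data$name)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$value,
                                   fill = .data$skew)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "skew", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot relative synonymous codon usage
#'
#' RSCU bars per codon, faceted by amino acid, with the RSCU = 1
#' no-preference line.
#'
#' @param object An `rscu_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rscu_table <- function(object, ...) {
  df <- as_tibble(object) |> filter(.data$aa != "Stop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data$rscu)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(~aa, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Heatmap of a pairwise distance matrix
#'
#' @param object A `mito_dist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_dist <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$taxon1, y = .data$taxon2,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$distance)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0(object$estimator, " distance")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
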