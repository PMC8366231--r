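#' Plot per-category distributions of the LDL measures
#'
#' Density curves of each measure split by morphological category,
#' mirroring the distribution panels used to compare networks: one facet
#' per measure, free x scales.
#'
#' @param measures A measure tibble from [ldl_measures()].
#' @param lexicon The lexicon (to recover each word's category).
#' @param which Measures to plot.
#' @return A ggplot object.
#' @export
plot_measure_distributions <- function(measures, lexicon,
                                       which = c("mean_word_support",
                                                 "path_entropies",
                                                 "semantic_density",
                                                 "semantic_vector_length")) {
  df <- measures |>
    dplyr::inner_join(lexicon[, c("word_id", "category")], by = "word_id") |>
    dplyr::filter(!is.na(.data$category)) |>
    tidyr::pivot_longer(dplyr::all_of(which),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   colour = .data$category,
                                   fill = .data$category)) +
    ggplot2::geom_density(alpha = 0.25) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free") +
    ggplot2::labs(x = NULL, y = "density", colour = "category",
                  fill = "category") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.duration_fit <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ldl_network <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("comprehension_rank", "production_rank"),
                        names_to = "direction", values_to = "rank")
  df$direction <- sub("_rank$", "", df$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_bar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$direction)) +
    ggplot2::labs(x = "rank of own target", y = "words") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ldl_relimp <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lmg,
                                       y = stats::reorder(.data$term,
                                                          .data$lmg))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "lmg share of explained variance", y = NULL) +
    ggplot2::theme_minimal()
}
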