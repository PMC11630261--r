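#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a metagene profile
#'
#' Mean signal along the common TSS-TTS axis with flank/body zone shading.
#'
#' @param object A [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_signal)) +
    ggplot2::geom_line(linewidth = 0.7, colour = "#2c6e9b") +
    ggplot2::geom_vline(xintercept = range(df$bin[df$zone == "body"]) + c(-0.5, 0.5),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "position (TSS → TTS, flanks fixed, body scaled)",
                  y = "mean signal",
                  title = sprintf("Metagene profile (%d genes)", attr(object, "n_genes"))) +
    ggplot2::theme_minimal()
}

#' Emission heatmap of a fitted chromatin-state HMM
#'
#' @param object A `bernoulli_hmm`.
#' @param ... Unused.
#' @return A ggplot tile map of per-state emission probabilities.
#' @export
autoplot.bernoulli_hmm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mark, y = factor(.data$state),
                                   fill = .data$emission)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "chromatin state", fill = "emission",
                  title = sprintf("Emission probabilities (K = %d)", object$K)) +
    ggplot2::theme_minimal()
}

#' Bar plot of a peak set's feature distribution
#'
#' @param dist A [feature_distribution()] tibble.
#' @return A ggplot.
#' @export
plot_feature_distribution <- function(dist) {
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$feature, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c6e9b") +
    ggplot2::labs(x = NULL, y = "fraction of peaks") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Bar plot of concordance class sizes
#'
#' @param report A [concordance()] report.
#' @return A ggplot.
#' @export
plot_concordance <- function(report) {
  df <- report$classes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n,
                                   fill = .data$de_direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#b2182b", down = "#2166ac")) +
    ggplot2::labs(x = NULL, y = "genes", fill = "expression") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
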