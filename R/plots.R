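#' Coefficient profiles along the regularization path
#'
#' One line per gene that is ever selected, on a log-lambda axis.
#'
#' @param object A `blasso_path`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blasso_path <- function(object, ...) {
  long <- tidy(object)
  ever <- long |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::filter(any(.data$beta != 0)) |>
    dplyr::ungroup()
  ggplot2::ggplot(ever, ggplot2::aes(x = log(.data$lambda), y = .data$beta,
                                     group = .data$gene_symbol)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = expression(log(lambda)), y = "coefficient",
                  title = "Regularization path") +
    ggplot2::theme_minimal()
}

#' Distribution of fold AUCs per repetition
#'
#' @param object A `blasso_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.blasso_eval <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = factor(.data$repetition), y = .data$auc)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "repetition", y = "test AUC",
                  title = paste0("Cross-validated AUC (", object$model, ")")) +
    ggplot2::theme_minimal()
}

#' Citation-count distribution
#'
#' @param object A `citation_table`.
#' @param ... Unused.
#' @return A ggplot object (log10 count axis).
#' @export
autoplot.citation_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_citations)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "citations per gene (log scale)", y = "genes",
                  title = paste0("Citation distribution (",
                                 attr(object, "mode"), ")")) +
    ggplot2::theme_minimal()
}

#' Penalty factor as a function of the exponent
#'
#' Shows `gamma = (1/(cites+1))^epsilon` curves for a set of citation
#' counts over a grid of exponents: the smaller the exponent, the flatter
#' the prior.
#'
#' @param cites Citation counts to draw curves for.
#' @param epsilons Grid of exponents in (0, 1].
#' @return A ggplot object.
#' @export
plot_gamma_curves <- function(cites = c(1, 10, 100, 1000, 10000),
                              epsilons = default_epsilon_grid()) {
  grid <- tidyr::expand_grid(cites = cites, epsilon = epsilons) |>
    dplyr::mutate(gamma = gamma_factor(.data$cites, 1)^.data$epsilon)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$epsilon, y = .data$gamma,
                                     colour = factor(.data$cites))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(epsilon), y = expression(gamma),
                  colour = "citations") +
    ggplot2::theme_minimal()
}
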