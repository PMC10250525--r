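#' Accuracy heatmap over categories and variables
#'
#' Tile plot of the probability of recovering the true number of
#' components, by number of ordinal categories (x) and number of
#' variables (y), with cell labels rounded to two decimals. Feed it a
#' [summarize_cells()] table grouped by `p` and `n_categories`.
#'
#' @param summary Tibble with columns `p`, `n_categories`, `accuracy`.
#' @return A ggplot object.
#' @export
plot_accuracy_heatmap <- function(summary) {
  df <- dplyr::mutate(summary, cat = cat_label(.data$n_categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cat, y = factor(.data$p),
                                   fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$accuracy)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "orange",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "number of ordinal categories", y = "number of variables p",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Parameter-error heatmap over categories and variables
#'
#' @param summary Tibble with columns `p`, `n_categories` and one of the
#'   `mae_*` columns.
#' @param what Which error to display, default `"mae_means"`. Cells with
#'   no correctly recovered repetition are blank.
#' @return A ggplot object.
#' @export
plot_parameter_errors <- function(summary, what = "mae_means") {
  df <- dplyr::mutate(summary, cat = cat_label(.data$n_categories),
                      value = .data[[what]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cat, y = factor(.data$p),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$value), "", sprintf("%.2f", .data$value))),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 na.value = "grey90") +
    ggplot2::labs(x = "number of ordinal categories", y = "number of variables p",
                  fill = what) +
    ggplot2::theme_minimal()
}

#' Boxplots of the selected number of components
#'
#' Distribution of `k_hat` as a function of the number of ordinal
#' categories, faceted by the number of variables — the diagnostic view
#' of the under/over/correct-estimation trajectory as categories grow.
#'
#' @param results Repetition-level tibble from [run_grid()].
#' @return A ggplot object.
#' @export
plot_khat_distribution <- function(results) {
  df <- dplyr::mutate(results, cat = cat_label(.data$n_categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cat, y = .data$k_hat)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~p, labeller = ggplot2::label_both) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$k_true),
                        linetype = "dashed", color = "red") +
    ggplot2::labs(x = "number of ordinal categories",
                  y = "selected number of components") +
    ggplot2::theme_minimal()
}

cat_label <- function(n_categories) {
  factor(ifelse(is.finite(n_categories), as.character(n_categories), "cont"),
         levels = c(as.character(sort(unique(
           n_categories[is.finite(n_categories)]))), "cont"))
}

#' @export
autoplot.gmm_selection <- function(object, ...) {
  df <- dplyr::filter(object$table, !.data$failed)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_hat, linetype = "dotted") +
    ggplot2::labs(x = "number of components k", y = "BIC (larger is better)") +
    ggplot2::theme_minimal()
}
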