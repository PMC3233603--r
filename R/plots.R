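#' Contact-map plot of ranked pair scores
#'
#' Top pairs by DI in the upper triangle, by MI in the lower triangle —
#' the standard visual comparison of the global and local scores.
#'
#' @param object A `score_table`.
#' @param n_pairs Number of top pairs per score (default `L`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.score_table <- function(object, n_pairs = NULL, ...) {
  n_pairs <- n_pairs %||% object$L
  tab <- tidy(object)
  di_top <- tab |> arrange(desc(.data$di)) |> slice_head(n = n_pairs) |>
    mutate(score = "DI", x = .data$j, y = .data$i)
  mi_top <- tab |> arrange(desc(.data$mi)) |> slice_head(n = n_pairs) |>
    mutate(score = "MI", x = .data$i, y = .data$j)
  df <- bind_rows(di_top, mi_top)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$score)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue",
                  title = sprintf("top %d pairs (DI above, MI below diagonal)",
                                  n_pairs)) +
    ggplot2::theme_minimal()
}

#' Predicted-vs-observed contact map
#'
#' @param predicted Ranked tibble (`eic_set` or tidied scores).
#' @param observed A `contact_map`.
#' @param n_c Number of top predictions to draw.
#' @return A ggplot object.
#' @export
plot_contact_comparison <- function(predicted, observed, n_c = 50L) {
  pred <- top_predicted(predicted, n_c) |> mutate(set = "predicted")
  obs <- as_tibble(observed) |> mutate(set = "observed")
  df <- bind_rows(obs[, c("i", "j", "set")], pred[, c("i", "j", "set")])
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, colour = .data$set,
                                   shape = .data$set)) +
    ggplot2::geom_point(size = 1.6, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(observed = "grey60",
                                            predicted = "red")) +
    ggplot2::scale_shape_manual(values = c(observed = 16, predicted = 8)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue") +
    ggplot2::theme_minimal()
}

#' True-positive-rate curve of an evaluation report
#'
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object), -"n_c",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$n_c, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of constraints N_C", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
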