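#' Plot prediction ratios against the 2-fold acceptance window
#'
#' Dot plot of predicted/observed ratios per drug, on a log scale, with
#' reference lines at 0.5, 1 and 2 marking the fold-error acceptance window.
#' Mirrors the ratio figures of the reference analysis (simple allometry vs
#' Rule of Exponents; mouse exponent 1.0 vs exponent averaging).
#'
#' @param predictions Evaluated prediction tibble (rows without a ratio are
#'   dropped).
#' @param colour_by Column mapped to colour/shape; defaults to `strategy`.
#' @return A ggplot object.
#' @examples
#' d3 <- dplyr::filter(adc_clearance_data(), n_animal_species >= 3)
#' dplyr::bind_rows(
#'   scale_three_species(d3, strategy = "sa"),
#'   scale_three_species(d3, strategy = "roe")
#' ) |> plot_prediction_ratios()
#' @export
plot_prediction_ratios <- function(predictions, colour_by = "strategy") {
  df <- dplyr::filter(predictions, !is.na(.data$ratio)) |>
    dplyr::mutate(label = paste0(.data$drug, " (", .data$analyte, ")"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$label, y = .data$ratio,
    colour = .data[[colour_by]], shape = .data[[colour_by]]
  )) +
    ggplot2::geom_hline(yintercept = c(0.5, 2), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_log10(breaks = c(0.1, 0.25, 0.5, 1, 2, 4, 10)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Predicted / observed human clearance",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}
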